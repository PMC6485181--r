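#' Power-analysis specification
#'
#' Design of a bootstrap power/sample-size estimation run for a biomarker
#' endpoint: the model family, the two-sided significance level, the target
#' power, the candidate sample sizes and the number of bootstrap
#' replicates.
#'
#' @param model `"prop_hazards_tte"` (Cox model of a time-to-event outcome
#'   on the biomarker) or `"linear_regression"` (least squares of a
#'   continuous outcome on the biomarker).
#' @param alpha two-sided significance level, `0 < alpha < target_power`.
#' @param target_power required power in `(0, 1)`.
#' @param n_grid increasing vector of candidate sample sizes.
#' @param B bootstrap replicates per grid point (at least 100 for
#'   reporting).
#' @param seed integer seed; the whole run is deterministic given it.
#' @return object of class `power_spec`.
#' @export
power_spec <- function(model = c("prop_hazards_tte", "linear_regression"),
                       alpha = 0.05, target_power = 0.80,
                       n_grid = seq(20, 200, by = 20), B = 500,
                       seed = NULL) {
  model <- match.arg(model)
  if (!(alpha > 0 && alpha < target_power && target_power < 1))
    stop("need 0 < alpha < target_power < 1", call. = FALSE)
  if (length(n_grid) == 0L || any(n_grid < 2) || is.unsorted(n_grid,
                                                            strictly = TRUE))
    stop("'n_grid' must be a non-empty increasing vector of sizes >= 2",
         call. = FALSE)
  if (B < 100) warning("B < 100 replicates: power estimates will be noisy")
  structure(list(model = model, alpha = alpha, target_power = target_power,
                 n_grid = as.integer(n_grid), B = as.integer(B),
                 resample_unit = "patient", seed = seed),
            class = "power_spec")
}

fit_significant <- function(dat, model, alpha) {
  # returns TRUE/FALSE for a two-sided Wald test of the biomarker
  # coefficient, or NA when the fit did not converge / is degenerate
  if (stats::sd(dat$biomarker) < 1e-12) return(NA)
  if (model == "prop_hazards_tte") {
    if (!any(dat$event)) return(NA)
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(survival::Surv(time, event) ~ biomarker, data = dat),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit)) return(NA)
    co <- summary(fit)$coefficients
    se <- co[1, "se(coef)"]
    if (!is.finite(se) || se > 50) return(NA)  # monotone-likelihood blowup
    p <- co[1, "Pr(>|z|)"]
  } else {
    fit <- tryCatch(stats::lm(response ~ biomarker, data = dat),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA)
    co <- summary(fit)$coefficients
    if (nrow(co) < 2L || !is.finite(co[2, 4])) return(NA)
    p <- co[2, 4]
  }
  is.finite(p) && p < alpha
}

boot_power_impl <- function(pilot, spec, n) {
  B <- spec$B
  sig <- logical(B)
  redraws <- 0L
  max_attempts <- 10L * B
  attempts <- 0L
  b <- 1L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("bootstrap failure: too many non-converged resamples",
           call. = FALSE)
    idx <- sample.int(nrow(pilot), n, replace = TRUE)
    res <- fit_significant(pilot[idx, , drop = FALSE], spec$model,
                           spec$alpha)
    if (is.na(res)) { redraws <- redraws + 1L; next }
    sig[b] <- res
    b <- b + 1L
  }
  p <- mean(sig)
  list(power = p, mc_se = sqrt(p * (1 - p) / B), n = as.integer(n),
       B = B, redraws = redraws)
}

#' Bootstrap power at a single sample size
#'
#' Resamples `n` patients with replacement from the pilot dataset `B`
#' times, fits the specified model to each resample and counts the
#' fraction in which the biomarker coefficient is significant at the
#' spec's two-sided alpha (Wald test). Non-converged or degenerate fits
#' (all-censored resamples, zero-variance biomarker, diverging hazard
#' estimates) are redrawn, counted in `redraws`, and capped at `10 * B`
#' attempts.
#'
#' @param pilot pilot data.frame: `biomarker` plus `time`/`event`
#'   (proportional hazards) or `response` (linear regression).
#' @param spec a [power_spec()].
#' @param n resample size.
#' @return list `power`, `mc_se` (binomial Monte-Carlo standard error
#'   `sqrt(p(1-p)/B)`), `n`, `B`, `redraws`.
#' @export
bootstrap_power <- function(pilot, spec, n) {
  stopifnot(inherits(spec, "power_spec"))
  if (nrow(pilot) < 2L) stop("pilot must have >= 2 subjects", call. = FALSE)
  need <- if (spec$model == "prop_hazards_tte") c("time", "event") else
    "response"
  if (!all(c("biomarker", need) %in% names(pilot)))
    stop(sprintf("pilot lacks the columns required by model '%s'",
                 spec$model), call. = FALSE)
  with_seed(spec$seed, boot_power_impl(pilot, spec, n))
}

#' Minimal sample size reaching the target power
#'
#' Evaluates [bootstrap_power()] along the spec's grid, stopping early
#' once the target is met at a grid point and confirmed at the next one.
#' The minimal n is the first grid point whose estimate reaches the
#' target; when no grid point does, the result reports "grid exhausted"
#' rather than raising an error.
#'
#' @param pilot pilot dataset (see [bootstrap_power()]).
#' @param spec a [power_spec()].
#' @return object of class `power_result`: `table` (per-n power and MC
#'   SE), `minimal_n` (integer or `NA`), `status` (`"met"` or
#'   `"grid_exhausted"`), `spec`.
#' @export
sample_size_search <- function(pilot, spec) {
  stopifnot(inherits(spec, "power_spec"))
  rows <- list()
  with_seed(spec$seed, {
    consecutive <- 0L
    for (i in seq_along(spec$n_grid)) {
      n <- spec$n_grid[i]
      est <- boot_power_impl(pilot, spec, n)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, power = est$power, mc_se = est$mc_se, redraws = est$redraws)
      consecutive <- if (est$power >= spec$target_power) consecutive + 1L
        else 0L
      if (consecutive >= 2L) break  # met and confirmed at the next point
    }
  })
  tab <- do.call(rbind, rows)
  met <- tab$n[tab$power >= spec$target_power]
  minimal_n <- if (length(met) > 0L) as.integer(min(met)) else NA_integer_
  structure(list(table = tab, minimal_n = minimal_n,
                 status = if (is.na(minimal_n)) "grid_exhausted" else "met",
                 spec = spec),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  model_lab <- c(prop_hazards_tte = "Proportional Hazards",
                 linear_regression = "Linear Regression")[x$spec$model]
  cat("Bootstrapped power calculation\n")
  cat(sprintf("  Statistical model: %s\n", model_lab))
  cat(sprintf("  Percent power:     %g    alpha-level: %g    replicates: %d\n",
              100 * x$spec$target_power, x$spec$alpha, x$spec$B))
  print(x$table, row.names = FALSE)
  if (x$status == "met") {
    cat(sprintf("  Estimate of patients required: %d\n", x$minimal_n))
  } else {
    cat("  Target power not reached on the grid (grid exhausted)\n")
  }
  invisible(x)
}

#' Closed-form required event count for a proportional-hazards covariate
#'
#' Schoenfeld-type formula: the number of events needed so a two-sided
#' level-`alpha` Wald test of a log hazard ratio `beta` per unit of a
#' covariate with SD `sigma_x` attains the given power:
#' `ceiling((z[1 - alpha/2] + z[power])^2 / (beta^2 sigma_x^2))`, at least
#' one event.
#'
#' @param beta non-zero log hazard ratio per covariate unit.
#' @param sigma_x covariate SD.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer event count.
#' @export
closed_form_cox_events <- function(beta, sigma_x = 1, alpha, power) {
  if (beta == 0) stop("beta = 0: infinite event requirement", call. = FALSE)
  check_pos(sigma_x, "sigma_x"); check_prob(alpha, "alpha")
  check_prob(power, "power")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  max(1L, as.integer(ceiling(z^2 / (beta^2 * sigma_x^2))))
}

#' Closed-form required n for a simple linear regression slope
#'
#' Normal-approximation sample size for a two-sided level-`alpha` test of
#' slope `slope` with predictor SD `sigma_x` and residual SD
#' `sigma_resid`:
#' `ceiling((z[1 - alpha/2] + z[power])^2 sigma_resid^2 /
#' (slope^2 sigma_x^2)) + 2` (the +2 recovers the intercept and residual
#' degrees of freedom).
#'
#' @param slope non-zero regression slope.
#' @param sigma_x predictor SD.
#' @param sigma_resid residual SD.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @return integer sample size (minimum 3).
#' @export
closed_form_linear_n <- function(slope, sigma_x = 1, sigma_resid = 1,
                                 alpha, power) {
  if (slope == 0) stop("slope = 0: infinite sample-size requirement",
                       call. = FALSE)
  check_pos(sigma_x, "sigma_x")
  check_pos(sigma_resid, "sigma_resid", strict = FALSE)
  check_prob(alpha, "alpha"); check_prob(power, "power")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(z^2 * sigma_resid^2 / (slope^2 * sigma_x^2))) + 2L
}
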