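#' Chi-squared comparison of two proportions
#'
#' Pearson chi-squared test on the 2x2 table (df = 1), without continuity
#' correction, for comparing the fraction affected in an enrolled cohort
#' against a reference population.
#'
#' @param cohort_successes,cohort_n affected count and total in the cohort.
#' @param ref_successes,ref_n affected count and total in the reference.
#' @return list `statistic`, `p_value`, `cohort_prop`, `ref_prop`.
#' @export
compare_binary <- function(cohort_successes, cohort_n, ref_successes, ref_n) {
  check_pos(c(cohort_successes, ref_successes), "successes", strict = FALSE)
  check_pos(c(cohort_n, ref_n), "n")
  if (cohort_successes > cohort_n || ref_successes > ref_n)
    stop("successes exceed n", call. = FALSE)
  tab <- rbind(c(cohort_successes, cohort_n - cohort_successes),
               c(ref_successes, ref_n - ref_successes))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)", call. = FALSE)
  if (cohort_successes / cohort_n == ref_successes / ref_n) {
    # identical proportions: chi-squared is exactly 0
    return(list(statistic = 0, p_value = 1,
                cohort_prop = cohort_successes / cohort_n,
                ref_prop = ref_successes / ref_n))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       cohort_prop = cohort_successes / cohort_n,
       ref_prop = ref_successes / ref_n)
}

#' Welch t-test comparison of two continuous samples
#'
#' Two-sided Welch two-sample t-test. When both groups are constant with
#' equal means the comparison is declared null (`t = 0`, `p = 1`) by
#' convention rather than erroring.
#'
#' @param cohort,reference numeric vectors (each `n >= 2`, finite).
#' @return list `statistic`, `p_value`, `cohort_mean`, `ref_mean`.
#' @export
compare_continuous <- function(cohort, reference) {
  cohort <- cohort[is.finite(cohort)]
  reference <- reference[is.finite(reference)]
  if (length(cohort) < 2L || length(reference) < 2L)
    stop("each group needs >= 2 finite values", call. = FALSE)
  if (stats::sd(cohort) == 0 && stats::sd(reference) == 0) {
    if (mean(cohort) == mean(reference)) {
      return(list(statistic = 0, p_value = 1, cohort_mean = mean(cohort),
                  ref_mean = mean(reference)))
    }
    stop("both groups constant with different means: t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(cohort, reference)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       cohort_mean = mean(cohort), ref_mean = mean(reference))
}

#' Quasi-Poisson comparison of two count samples
#'
#' Quasi-Poisson regression of the count on a cohort indicator; the
#' reported p-value is the two-sided test of the indicator coefficient.
#'
#' @param cohort,reference non-negative integer count vectors.
#' @return list `statistic` (t value), `p_value`, `rate_ratio`.
#' @export
compare_counts <- function(cohort, reference) {
  check_pos(cohort, "cohort", strict = FALSE)
  check_pos(reference, "reference", strict = FALSE)
  d <- data.frame(y = c(cohort, reference),
                  g = rep(c(1, 0), c(length(cohort), length(reference))))
  fit <- stats::glm(y ~ g, family = stats::quasipoisson(), data = d)
  co <- summary(fit)$coefficients
  list(statistic = unname(co["g", "t value"]),
       p_value = unname(co["g", "Pr(>|t|)"]),
       rate_ratio = unname(exp(co["g", "Estimate"])))
}

#' Cohort-representativeness comparison report
#'
#' Compares an enrolled cohort with a reference population characteristic
#' by characteristic, choosing the test by type: binary characteristics by
#' Pearson chi-squared (no continuity correction), continuous by Welch
#' t-test, counts by quasi-Poisson regression. With `adjust_for`,
#' regression-adjusted p-values are reported instead: each characteristic
#' is modeled on a cohort indicator plus the adjustment covariates
#' (logistic for binary, linear for continuous, quasi-Poisson for counts).
#'
#' @param cohort,reference data.frames with the characteristic columns
#'   (and any adjustment covariates).
#' @param characteristics named character vector mapping column name to
#'   type (`"binary"`, `"continuous"` or `"count"`).
#' @param adjust_for optional character vector of covariate columns for
#'   the adjusted-regression mode.
#' @return data.frame of class `comparison_report`: `characteristic`,
#'   `type`, `cohort_summary`, `reference_summary`, `test`, `statistic`,
#'   `p_value`, `adjusted`.
#' @export
compare_cohorts <- function(cohort, reference, characteristics,
                            adjust_for = NULL) {
  stopifnot(is.character(characteristics), !is.null(names(characteristics)))
  adjusted <- !is.null(adjust_for)
  rows <- lapply(names(characteristics), function(nm) {
    ty <- match.arg(characteristics[[nm]], c("binary", "continuous", "count"))
    xc <- cohort[[nm]]; xr <- reference[[nm]]
    if (is.null(xc) || is.null(xr))
      stop(sprintf("characteristic '%s' missing from data", nm),
           call. = FALSE)
    summ <- function(x) {
      switch(ty,
             binary = sprintf("%d (%.3g)", sum(x), mean(x)),
             continuous = sprintf("%.3g (%.3g)", mean(x), stats::sd(x)),
             count = sprintf("%.3g (%.3g)", mean(x), stats::sd(x)))
    }
    if (adjusted) {
      d <- rbind(
        cbind(data.frame(.y = as.numeric(xc), .cohort = 1),
              cohort[, adjust_for, drop = FALSE]),
        cbind(data.frame(.y = as.numeric(xr), .cohort = 0),
              reference[, adjust_for, drop = FALSE]))
      fam <- switch(ty, binary = stats::binomial(),
                    continuous = stats::gaussian(),
                    count = stats::quasipoisson())
      fml <- stats::as.formula(paste(".y ~ .cohort +",
                                     paste(adjust_for, collapse = " + ")))
      co <- summary(stats::glm(fml, family = fam, data = d))$coefficients
      stat <- unname(co[".cohort", 3]); p <- unname(co[".cohort", 4])
      test <- paste0("adjusted_",
                     switch(ty, binary = "logistic", continuous = "linear",
                            count = "quasipoisson"))
    } else {
      res <- switch(ty,
        binary = compare_binary(sum(xc), length(xc), sum(xr), length(xr)),
        continuous = compare_continuous(xc, xr),
        count = compare_counts(xc, xr))
      stat <- res$statistic; p <- res$p_value
      test <- switch(ty, binary = "chi_squared", continuous = "welch_t",
                     count = "quasipoisson")
    }
    data.frame(characteristic = nm, type = ty, cohort_summary = summ(xc),
               reference_summary = summ(xr), test = test, statistic = stat,
               p_value = p, adjusted = adjusted, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_report", class(out))
  out
}

#' Meteorological season of a date
#'
#' Dec-Feb Winter, Mar-May Spring, Jun-Aug Summer, Sep-Nov Fall. Returned
#' as a factor with Summer as the reference level (first).
#'
#' @param dates Date vector.
#' @return factor with levels Summer, Fall, Winter, Spring.
#' @export
season_of <- function(dates) {
  m <- as.integer(format(as.Date(dates), "%m"))
  s <- c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
         "Summer", "Summer", "Fall", "Fall", "Fall", "Winter")[m]
  factor(s, levels = c("Summer", "Fall", "Winter", "Spring"))
}

#' Seasonal effects on enrollment characteristics
#'
#' One regression per characteristic of the characteristic on enrollment
#' season (Summer as reference): linear for continuous, logistic for
#' binary, quasi-Poisson for counts. Bonferroni correction is applied
#' across the `m` characteristics tested: a seasonal contrast is declared
#' significant only when its raw p-value is at most `family_alpha / m`.
#'
#' @param cohort data.frame with an enrollment-date column and the
#'   characteristic columns.
#' @param characteristics named character vector mapping column name to
#'   type (as in [compare_cohorts()]).
#' @param date_col name of the enrollment-date column.
#' @param family_alpha family-wise significance level.
#' @return data.frame of class `seasonal_report`: one row per
#'   characteristic x non-Summer season with `estimate`, `p_value`,
#'   `model`, `significant_bonferroni`; attributes `m` and `family_alpha`.
#' @export
seasonal_effects <- function(cohort, characteristics,
                             date_col = "enrollment_date",
                             family_alpha = 0.05) {
  check_prob(family_alpha, "family_alpha")
  season <- season_of(cohort[[date_col]])
  if (length(unique(as.character(season))) < 2L)
    stop("seasonal analysis needs >= 2 seasons represented", call. = FALSE)
  season <- droplevels(season)
  m <- length(characteristics)
  rows <- lapply(names(characteristics), function(nm) {
    ty <- match.arg(characteristics[[nm]], c("binary", "continuous", "count"))
    y <- as.numeric(cohort[[nm]])
    fam <- switch(ty, continuous = stats::gaussian(),
                  binary = stats::binomial(), count = stats::quasipoisson())
    model_name <- switch(ty, continuous = "linear", binary = "logistic",
                         count = "quasipoisson")
    fit <- stats::glm(y ~ season, family = fam)
    co <- summary(fit)$coefficients
    season_rows <- grep("^season", rownames(co), value = TRUE)
    do.call(rbind, lapply(season_rows, function(rn) {
      data.frame(characteristic = nm,
                 season = sub("^season", "", rn),
                 estimate = unname(co[rn, 1]),
                 p_value = unname(co[rn, 4]),
                 model = model_name, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$significant_bonferroni <- !is.na(out$p_value) &
    out$p_value <= family_alpha / m
  attr(out, "m") <- m
  attr(out, "family_alpha") <- family_alpha
  class(out) <- c("seasonal_report", class(out))
  out
}

#' @export
print.seasonal_report <- function(x, ...) {
  cat(sprintf(
    "Seasonal enrollment effects (reference: Summer; Bonferroni over m = %d)\n",
    attr(x, "m")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (any(x$significant_bonferroni)) {
    cat("Some seasonal differences remain significant after Bonferroni correction.\n")
  } else {
    cat("No seasonal differences remain significant after Bonferroni correction.\n")
  }
  invisible(x)
}

#' Paired shipping-effect analysis
#'
#' Quality-control analysis of split samples processed immediately versus
#' after overnight shipping: ordinary least squares of the shipped
#' measurement on the immediate one (slope, intercept and two-sided slope
#' p-value), per-pair elevation factors (shipped / immediate) with their
#' mean, a normal-approximation 95% confidence interval for the mean
#' (clipped below at 0), and the maximum factor. Pairs with non-positive
#' immediate values have an undefined factor and are excluded with a
#' warning.
#'
#' @param pairs data.frame with columns `immediate` and `shipped`.
#' @return object of class `shipping_analysis`.
#' @export
paired_shipping_analysis <- function(pairs) {
  stopifnot(all(c("immediate", "shipped") %in% names(pairs)))
  bad <- !is.finite(pairs$immediate) | pairs$immediate <= 0
  if (any(bad)) {
    warning(sprintf("%d pair(s) with non-positive immediate value excluded",
                    sum(bad)), call. = FALSE)
    pairs <- pairs[!bad, , drop = FALSE]
  }
  n <- nrow(pairs)
  if (n < 3L) stop("need >= 3 usable pairs for inference", call. = FALSE)
  fit <- stats::lm(shipped ~ immediate, data = pairs)
  # noiseless pair sets are legitimate inputs: keep summary() quiet about
  # the perfect fit
  co <- suppressWarnings(summary(fit))$coefficients
  factors <- pairs$shipped / pairs$immediate
  mf <- mean(factors)
  half <- stats::qnorm(0.975) * stats::sd(factors) / sqrt(n)
  structure(list(
    n = n,
    slope = unname(co["immediate", 1]),
    intercept = unname(co["(Intercept)", 1]),
    p_value = unname(co["immediate", 4]),
    factors = factors,
    mean_factor = mf,
    ci_mean_factor = c(max(0, mf - half), mf + half),
    max_factor = max(factors)
  ), class = "shipping_analysis")
}

#' @export
print.shipping_analysis <- function(x, ...) {
  cat("Paired shipping analysis (shipped ~ immediate)\n")
  cat(sprintf("  n pairs: %d\n", x$n))
  cat(sprintf("  coefficient = %.3g, intercept = %.3g, p = %.3g\n",
              x$slope, x$intercept, x$p_value))
  cat(sprintf("  mean elevation factor %.3g, 95%% CI = %.3g-%.3g; max %.3g\n",
              x$mean_factor, x$ci_mean_factor[1], x$ci_mean_factor[2],
              x$max_factor))
  invisible(x)
}
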