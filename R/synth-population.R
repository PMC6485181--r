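#' Truncated-normal sampler
#'
#' Draws from a normal distribution restricted to `[lower, upper)` by
#' rejection, which is exact (no boundary-atom artifacts from clamping).
#' Used for the age, lung-function and weight marginals of the synthetic
#' cohort generator.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the parent normal; `sd > 0`.
#' @param lower,upper truncation bounds (either may be infinite).
#' @return numeric vector of length `n`, all values in `[lower, upper)`.
#' @export
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  check_pos(sd, "sd")
  if (lower >= upper) stop("'lower' must be < 'upper'", call. = FALSE)
  out <- numeric(0)
  accept <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (accept <= 0) stop("truncation region has zero mass", call. = FALSE)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / max(accept, 1e-3)) + 10L
    x <- stats::rnorm(m, mean, sd)
    out <- c(out, x[x >= lower & x < upper])
  }
  out[seq_len(n)]
}

#' Synthetic population configuration
#'
#' Bundles the marginal distributions and process rates used by
#' [generate_population()] and [generate_visits()]. Defaults emulate a
#' multicenter cystic-fibrosis cohort of sputum-producing patients aged 12
#' and over: age about N(27, 12) truncated at 12 years, FEV1 percent
#' predicted about N(80, 23) truncated to (0, 150], 46% male, prior-year
#' exacerbation counts that are overdispersed with mean 1 (SD 1.2), common
#' airway-infection prevalences, a 10% clinic no-show rate and a 53%
#' consent (recruitment) rate.
#'
#' Two home-elevation presets are provided because cohort descriptions of
#' the same region differ: `"registry"` (mean 1305 m, SD 442) and
#' `"summary"` (mean 328 m, SD 112). Neither is privileged; pick one.
#'
#' @param n_centers number of participating centers.
#' @param adult_pool,pediatric_pool per-center pool sizes (scalar or length
#'   `n_centers`). Defaults approximate 696 adult and 154 pediatric eligible
#'   patients spread over 9 centers.
#' @param age_mean,age_sd,age_min age marginal (years); ages below `age_min`
#'   are excluded by truncation.
#' @param fev1_mean,fev1_sd FEV1 percent-predicted marginal, truncated to
#'   (0, 150].
#' @param male_fraction probability a patient is male.
#' @param weight_mean,weight_sd body-weight marginal (kg), truncated > 25.
#' @param exac_mean,exac_sd prior-year pulmonary-exacerbation count moments;
#'   counts are negative binomial, so `exac_sd^2 > exac_mean` is required.
#' @param infection_prevalence named probabilities of each airway infection.
#' @param elevation_preset `"registry"` or `"summary"` (see above), ignored
#'   when `elevation_mean`/`elevation_sd` are given explicitly.
#' @param elevation_mean,elevation_sd optional explicit elevation marginal (m).
#' @param exclusion_rates named probabilities for `transplant`,
#'   `immunosuppressed` and `vulnerable` status; any of these makes a patient
#'   ineligible.
#' @param no_show_rate probability a scheduled clinic visit is missed.
#' @param consent_rate probability an approached patient consents.
#' @param season_shift optional named list of per-season additive shifts for
#'   continuous covariates, e.g. `list(age_at_baseline = c(Fall = 8.7))`;
#'   applied by downstream helpers, not by [generate_population()] itself.
#' @param seed integer seed; every generator accepting this config is
#'   deterministic given the seed.
#' @return an object of class `population_config` (a validated list).
#' @export
population_config <- function(n_centers = 9,
                              adult_pool = c(78, 78, 78, 77, 77, 77, 77, 77, 77),
                              pediatric_pool = c(18, 17, 17, 17, 17, 17, 17, 17, 17),
                              age_mean = 27, age_sd = 12, age_min = 12,
                              fev1_mean = 80, fev1_sd = 23,
                              male_fraction = 0.46,
                              weight_mean = 62, weight_sd = 14,
                              exac_mean = 1, exac_sd = 1.2,
                              infection_prevalence = c(
                                mssa = 0.59, mrsa = 0.29, pseudomonas = 0.74,
                                b_cepacia = 0.044, s_maltophilia = 0.23,
                                achromobacter = 0.096, candida = 0.15,
                                aspergillus = 0.23, mac = 0.082,
                                m_abscessus = 0.052),
                              elevation_preset = c("registry", "summary"),
                              elevation_mean = NULL, elevation_sd = NULL,
                              exclusion_rates = c(transplant = 0.02,
                                                  immunosuppressed = 0.01,
                                                  vulnerable = 0.02),
                              no_show_rate = 0.10,
                              consent_rate = 0.53,
                              season_shift = NULL,
                              seed = NULL) {
  check_pos(n_centers, "n_centers")
  check_pos(adult_pool, "adult_pool", strict = FALSE)
  check_pos(pediatric_pool, "pediatric_pool", strict = FALSE)
  if (any(adult_pool != floor(adult_pool)) || any(pediatric_pool != floor(pediatric_pool)))
    stop("pool sizes must be integers", call. = FALSE)
  check_pos(age_sd, "age_sd"); check_pos(fev1_sd, "fev1_sd")
  check_pos(weight_sd, "weight_sd")
  if (!is.finite(age_mean)) stop("'age_mean' must be finite", call. = FALSE)
  if (!is.finite(fev1_mean)) stop("'fev1_mean' must be finite", call. = FALSE)
  check_prob(male_fraction, "male_fraction")
  check_pos(exac_mean, "exac_mean", strict = FALSE)
  if (exac_sd^2 <= exac_mean)
    stop("'exac_sd' must exceed sqrt(exac_mean) (overdispersed counts)", call. = FALSE)
  check_prob(infection_prevalence, "infection_prevalence")
  check_prob(exclusion_rates, "exclusion_rates")
  check_prob(no_show_rate, "no_show_rate")
  check_prob(consent_rate, "consent_rate")

  preset <- match.arg(elevation_preset)
  if (is.null(elevation_mean)) {
    elevation_mean <- if (preset == "registry") 1305 else 328
    elevation_sd <- if (preset == "registry") 442 else 112
  }
  check_pos(elevation_sd, "elevation_sd")

  adult_pool <- as.integer(rep_len(adult_pool, n_centers))
  pediatric_pool <- as.integer(rep_len(pediatric_pool, n_centers))

  structure(list(
    n_centers = as.integer(n_centers),
    adult_pool = adult_pool, pediatric_pool = pediatric_pool,
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    fev1_mean = fev1_mean, fev1_sd = fev1_sd,
    male_fraction = male_fraction,
    weight_mean = weight_mean, weight_sd = weight_sd,
    exac_mean = exac_mean, exac_sd = exac_sd,
    infection_prevalence = infection_prevalence,
    elevation_mean = elevation_mean, elevation_sd = elevation_sd,
    exclusion_rates = exclusion_rates,
    no_show_rate = no_show_rate, consent_rate = consent_rate,
    season_shift = season_shift,
    seed = seed
  ), class = "population_config")
}

#' Generate a synthetic multicenter patient population
#'
#' Draws one patient table from the marginals in `config`. Pediatric ages
#' come from the configured normal truncated to `[age_min, 18)` and adult
#' ages from the same normal truncated to `[18, Inf)`, so per-block pool
#' sizes and the age/block invariant hold simultaneously. Covariates are
#' drawn independently. Eligibility is false for any patient with a
#' transplant, immunosuppression or vulnerable-status flag.
#'
#' @param config a [population_config()].
#' @param seed overrides `config$seed` when given.
#' @return a data.frame with one row per patient: `patient_id`, `center_id`,
#'   `block` ("adult"/"pediatric"), `block_key`, `age_at_baseline`, `sex`,
#'   `fev1pp`, `weight_kg`, `prior_year_exacerbations`, one logical
#'   `inf_<name>` column per infection, `home_elevation_m`, the three
#'   exclusion flags, and `eligible`.
#' @export
generate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "population_config"))
  seed <- seed %||% config$seed
  with_seed(seed, {
    rows <- list()
    for (ci in seq_len(config$n_centers)) {
      for (blk in c("adult", "pediatric")) {
        n <- if (blk == "adult") config$adult_pool[ci] else config$pediatric_pool[ci]
        if (n == 0L) next
        age <- if (blk == "adult") {
          rnorm_trunc(n, config$age_mean, config$age_sd, lower = 18)
        } else {
          rnorm_trunc(n, config$age_mean, config$age_sd,
                      lower = config$age_min, upper = 18)
        }
        size <- config$exac_mean^2 / (config$exac_sd^2 - config$exac_mean)
        d <- data.frame(
          patient_id = sprintf("C%02d-%s-%04d", ci,
                               if (blk == "adult") "A" else "P", seq_len(n)),
          center_id = sprintf("C%02d", ci),
          block = blk,
          age_at_baseline = age,
          sex = ifelse(stats::runif(n) < config$male_fraction, "male", "female"),
          fev1pp = rnorm_trunc(n, config$fev1_mean, config$fev1_sd,
                               lower = .Machine$double.eps, upper = 150 + 1e-9),
          weight_kg = rnorm_trunc(n, config$weight_mean, config$weight_sd, lower = 25),
          prior_year_exacerbations = stats::rnbinom(n, size = size,
                                                    mu = config$exac_mean),
          home_elevation_m = rnorm_trunc(n, config$elevation_mean,
                                         config$elevation_sd, lower = 0),
          stringsAsFactors = FALSE
        )
        for (inf in names(config$infection_prevalence)) {
          d[[paste0("inf_", inf)]] <-
            stats::runif(n) < config$infection_prevalence[[inf]]
        }
        for (ex in names(config$exclusion_rates)) {
          d[[ex]] <- stats::runif(n) < config$exclusion_rates[[ex]]
        }
        rows[[length(rows) + 1L]] <- d
      }
    }
    if (length(rows) == 0L) return(empty_population())
    out <- do.call(rbind, rows)
    out$block_key <- paste(out$center_id, out$block, sep = ":")
    out$eligible <- !(out$transplant | out$immunosuppressed | out$vulnerable)
    rownames(out) <- NULL
    out
  })
}

empty_population <- function() {
  data.frame(patient_id = character(), center_id = character(),
             block = character(), age_at_baseline = numeric(),
             sex = character(), fev1pp = numeric(), weight_kg = numeric(),
             prior_year_exacerbations = integer(),
             home_elevation_m = numeric(), transplant = logical(),
             immunosuppressed = logical(), vulnerable = logical(),
             block_key = character(), eligible = logical(),
             stringsAsFactors = FALSE)
}

#' Generate clinic-visit streams
#'
#' Each patient gets visits on a fixed grid of `visit_interval_days` with a
#' uniformly random phase and a +/- `jitter_days` jitter per visit,
#' emulating routine quarterly clinic care. Every scheduled visit
#' independently no-shows with probability `no_show_rate`.
#'
#' @param patients data.frame with a `patient_id` column (as from
#'   [generate_population()]).
#' @param horizon_days length of the observation window.
#' @param visit_interval_days nominal spacing between visits (default 91,
#'   i.e. quarterly).
#' @param no_show_rate probability in `[0, 1]` that a visit is missed.
#' @param start_date calendar date of day 0.
#' @param jitter_days half-width of per-visit uniform jitter.
#' @param seed integer seed.
#' @return data.frame with `patient_id`, `visit_date`, `showed`,
#'   `approached`, `consented` (the last two are `FALSE` placeholders filled
#'   in by [simulate_enrollment()]), ordered by date then patient id.
#' @export
generate_visits <- function(patients, horizon_days, visit_interval_days = 91,
                            no_show_rate = 0.10,
                            start_date = as.Date("2014-12-08"),
                            jitter_days = 7, seed = NULL) {
  check_prob(no_show_rate, "no_show_rate")
  check_pos(horizon_days, "horizon_days")
  check_pos(visit_interval_days, "visit_interval_days")
  if (nrow(patients) == 0L) {
    return(data.frame(patient_id = character(), visit_date = as.Date(character()),
                      showed = logical(), approached = logical(),
                      consented = logical(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    n <- nrow(patients)
    phase <- stats::runif(n, 0, visit_interval_days)
    per <- lapply(seq_len(n), function(i) {
      days <- seq(phase[i], horizon_days, by = visit_interval_days)
      days <- days + stats::runif(length(days), -jitter_days, jitter_days)
      days <- sort(days[days >= 0 & days <= horizon_days])
      if (length(days) == 0L) return(NULL)
      data.frame(patient_id = patients$patient_id[i],
                 visit_date = start_date + round(days),
                 showed = stats::runif(length(days)) >= no_show_rate,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per)
    if (is.null(out)) {
      out <- data.frame(patient_id = character(),
                        visit_date = as.Date(character()), showed = logical())
    }
    out$approached <- FALSE
    out$consented <- FALSE
    out <- out[order(out$visit_date, out$patient_id), ]
    rownames(out) <- NULL
    out
  })
}

#' Generate a homogeneous-Poisson exacerbation process
#'
#' Event times for each patient follow a homogeneous Poisson process with
#' the given annual rate, so the expected count over the horizon is
#' `annual_rate * horizon_days / 365.25` per patient.
#'
#' @param patient_ids character vector of patient ids (one process each).
#' @param annual_rate events per patient-year, `>= 0`.
#' @param horizon_days observation window length.
#' @param start_date calendar date of day 0.
#' @param seed integer seed.
#' @return data.frame `patient_id`, `onset_day` (continuous days from start,
#'   strictly increasing within patient), `onset_date`.
#' @export
generate_exacerbation_process <- function(patient_ids, annual_rate, horizon_days,
                                          start_date = as.Date("2014-12-08"),
                                          seed = NULL) {
  if (!is.numeric(annual_rate) || annual_rate < 0 || !is.finite(annual_rate))
    stop("'annual_rate' must be a finite non-negative rate", call. = FALSE)
  check_pos(horizon_days, "horizon_days")
  with_seed(seed, {
    daily <- annual_rate / 365.25
    per <- lapply(patient_ids, function(id) {
      if (daily == 0) return(NULL)
      t <- 0; times <- numeric(0)
      repeat {
        t <- t + stats::rexp(1, rate = daily)
        if (t > horizon_days) break
        times <- c(times, t)
      }
      if (length(times) == 0L) return(NULL)
      data.frame(patient_id = id, onset_day = times,
                 onset_date = start_date + floor(times),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per)
    if (is.null(out)) {
      out <- data.frame(patient_id = character(), onset_day = numeric(),
                        onset_date = as.Date(character()),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate a pilot time-to-event biomarker dataset
#'
#' Biomarker values are normal with SD `sigma_x`; survival times are
#' exponential with hazard `exp(beta * biomarker)` (baseline hazard 1), so
#' `beta` is the log hazard ratio per unit of biomarker. Administrative
#' censoring at a single cutoff chosen so the expected censored fraction
#' equals `censor_fraction`.
#'
#' @param n number of subjects, `>= 2`.
#' @param beta log hazard ratio per biomarker unit.
#' @param censor_fraction target expected censored fraction in `[0, 1)`.
#' @param sigma_x biomarker SD (default 1, i.e. beta is per-SD).
#' @param seed integer seed.
#' @return data.frame `biomarker`, `time`, `event` with attribute
#'   `generator` recording the generating parameters.
#' @export
generate_pilot_tte <- function(n, beta, censor_fraction = 0, sigma_x = 1,
                               seed = NULL) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  if (!is.numeric(censor_fraction) || censor_fraction < 0 || censor_fraction >= 1)
    stop("'censor_fraction' must be in [0, 1)", call. = FALSE)
  check_pos(sigma_x, "sigma_x")
  with_seed(seed, {
    x <- stats::rnorm(n, 0, sigma_x)
    haz <- exp(beta * x)
    time <- stats::rexp(n, rate = haz)
    event <- rep(TRUE, n)
    if (censor_fraction > 0) {
      # administrative cutoff c solving mean_i P(T_i > c) = censor_fraction
      f <- function(cc) mean(exp(-haz * cc)) - censor_fraction
      cut <- stats::uniroot(f, lower = 1e-12, upper = 1e8, tol = 1e-10)$root
      event <- time <= cut
      time <- pmin(time, cut)
    }
    out <- data.frame(biomarker = x, time = time, event = event)
    attr(out, "generator") <- list(model = "prop_hazards_tte", beta = beta,
                                   sigma_x = sigma_x,
                                   censor_fraction = censor_fraction)
    out
  })
}

#' Generate a pilot continuous-outcome biomarker dataset
#'
#' Linear model `response = slope * biomarker + e`, `e ~ N(0, sigma_resid)`,
#' biomarker normal with SD `sigma_x`.
#'
#' @param n number of subjects, `>= 2`.
#' @param slope regression slope per biomarker unit.
#' @param sigma_x biomarker SD.
#' @param sigma_resid residual SD.
#' @param seed integer seed.
#' @return data.frame `biomarker`, `response` with a `generator` attribute.
#' @export
generate_pilot_linear <- function(n, slope, sigma_x = 1, sigma_resid = 1,
                                  seed = NULL) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  check_pos(sigma_x, "sigma_x"); check_pos(sigma_resid, "sigma_resid")
  with_seed(seed, {
    x <- stats::rnorm(n, 0, sigma_x)
    y <- slope * x + stats::rnorm(n, 0, sigma_resid)
    out <- data.frame(biomarker = x, response = y)
    attr(out, "generator") <- list(model = "linear_regression", slope = slope,
                                   sigma_x = sigma_x, sigma_resid = sigma_resid)
    out
  })
}

#' Generate paired immediate-vs-shipped biomarker measurements
#'
#' Emulates a shipping-control experiment: each sample is split, half
#' processed immediately and half after overnight shipping. Shipped values
#' follow `slope * immediate + intercept + noise`. Immediate values are
#' log-normal (positive by construction).
#'
#' @param n number of pairs, `>= 2`.
#' @param slope,intercept linear shipping effect.
#' @param noise_sd SD of additive measurement noise (0 for a noiseless pair
#'   set).
#' @param immediate_meanlog,immediate_sdlog log-normal parameters of the
#'   immediately-processed values.
#' @param seed integer seed.
#' @return data.frame `immediate`, `shipped`.
#' @export
generate_shipping_pairs <- function(n, slope = 1.15, intercept = 5.19,
                                    noise_sd = 1, immediate_meanlog = 3,
                                    immediate_sdlog = 0.6, seed = NULL) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  check_pos(noise_sd, "noise_sd", strict = FALSE)
  with_seed(seed, {
    immediate <- stats::rlnorm(n, immediate_meanlog, immediate_sdlog)
    shipped <- slope * immediate + intercept +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    data.frame(immediate = immediate, shipped = shipped)
  })
}
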