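test_that("config validation rejects out-of-range values by name", {
  expect_error(population_config(no_show_rate = 1.3), "no_show_rate")
  expect_error(population_config(age_sd = -1), "age_sd")
  expect_error(population_config(adult_pool = -5), "adult_pool")
  expect_error(population_config(male_fraction = 2), "male_fraction")
  # counts must be overdispersed for the negative-binomial model
  expect_error(population_config(exac_mean = 1, exac_sd = 0.5), "exac_sd")
})

test_that("all-zero pools give an empty population", {
  cfg <- population_config(n_centers = 2, adult_pool = 0, pediatric_pool = 0,
                           seed = 1)
  p <- generate_population(cfg)
  expect_equal(nrow(p), 0L)
  expect_true(all(c("patient_id", "block_key", "eligible") %in% names(p)))
})

test_that("generators are deterministic given the seed", {
  cfg <- population_config(n_centers = 2, adult_pool = 30, pediatric_pool = 10,
                           seed = 42)
  expect_identical(generate_population(cfg), generate_population(cfg))
  p <- generate_population(cfg)
  expect_identical(generate_visits(p, 200, seed = 7),
                   generate_visits(p, 200, seed = 7))
  expect_identical(generate_pilot_tte(50, 0.5, 0.2, seed = 3),
                   generate_pilot_tte(50, 0.5, 0.2, seed = 3))
  expect_identical(generate_shipping_pairs(7, seed = 5),
                   generate_shipping_pairs(7, seed = 5))
  expect_identical(
    generate_exacerbation_process(p$patient_id, 1, 365, seed = 9),
    generate_exacerbation_process(p$patient_id, 1, 365, seed = 9))
})

test_that("truncated-normal sampler matches a numerical-integration oracle", {
  # oracle: E[X | X >= a] by numerical integration of the truncated density
  trunc_mean <- function(mean, sd, lower, upper = Inf) {
    mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
    stats::integrate(function(x) x * stats::dnorm(x, mean, sd) / mass,
                     lower, upper)$value
  }
  set.seed(11)
  x <- rnorm_trunc(10000, 27, 12, lower = 12)
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - trunc_mean(27, 12, 12)), 3 * se)
  expect_true(all(x >= 12))

  # block-wise marginals of the population generator
  cfg <- population_config(n_centers = 1, adult_pool = 10000,
                           pediatric_pool = 10000, seed = 13)
  p <- generate_population(cfg)
  ad <- p$age_at_baseline[p$block == "adult"]
  pe <- p$age_at_baseline[p$block == "pediatric"]
  expect_lt(abs(mean(ad) - trunc_mean(27, 12, 18)),
            3 * stats::sd(ad) / sqrt(length(ad)))
  expect_lt(abs(mean(pe) - trunc_mean(27, 12, 12, 18)),
            3 * stats::sd(pe) / sqrt(length(pe)))
  expect_true(all(pe >= 12 & pe < 18))
  expect_true(all(ad >= 18))
  # lung function within its truncated range and near its target
  expect_true(all(p$fev1pp > 0 & p$fev1pp <= 150))
  expect_lt(abs(mean(p$fev1pp) - trunc_mean(80, 23, 0, 150)),
            3 * stats::sd(p$fev1pp) / sqrt(nrow(p)))
})

test_that("population moments track the configured marginals", {
  cfg <- population_config(n_centers = 1, adult_pool = 10000,
                           pediatric_pool = 0, seed = 17)
  p <- generate_population(cfg)
  n <- nrow(p)
  expect_lt(abs(mean(p$sex == "male") - 0.46), 3 * sqrt(0.46 * 0.54 / n))
  expect_lt(abs(mean(p$prior_year_exacerbations) - 1),
            3 * 1.2 / sqrt(n))
  expect_lt(abs(mean(p$inf_pseudomonas) - 0.74), 3 * sqrt(0.74 * 0.26 / n))
  # eligibility excludes flagged patients, and only them
  expect_identical(p$eligible,
                   !(p$transplant | p$immunosuppressed | p$vulnerable))
})

test_that("elevation presets expose both reported marginals", {
  a <- population_config(elevation_preset = "registry")
  b <- population_config(elevation_preset = "summary")
  expect_equal(c(a$elevation_mean, a$elevation_sd), c(1305, 442))
  expect_equal(c(b$elevation_mean, b$elevation_sd), c(328, 112))
})

test_that("visit no-show process hits the configured rate", {
  p <- tiny_population(3000, 0, seed = 19)
  v0 <- generate_visits(p, 365, no_show_rate = 0, seed = 1)
  expect_true(all(v0$showed))
  v1 <- generate_visits(p, 365, no_show_rate = 1, seed = 1)
  expect_false(any(v1$showed))
  v <- generate_visits(p, 365, no_show_rate = 0.10, seed = 2)
  expect_gt(nrow(v), 10000)
  se <- sqrt(0.9 * 0.1 / nrow(v))
  expect_lt(abs(mean(v$showed) - 0.9), 3 * se)
  expect_error(generate_visits(p, 365, no_show_rate = -0.1), "no_show_rate")
})

test_that("exacerbation process is Poisson with the stated mean", {
  expect_equal(nrow(generate_exacerbation_process("a", 0, 365, seed = 1)), 0L)
  expect_error(generate_exacerbation_process("a", -1, 365), "annual_rate")
  ids <- sprintf("p%05d", 1:10000)
  ev <- generate_exacerbation_process(ids, 1.0, 365.25, seed = 23)
  expect_lt(abs(nrow(ev) - 10000), 3 * sqrt(10000))
  # strictly increasing onset times within each patient
  ord <- tapply(ev$onset_day, ev$patient_id,
                function(x) all(diff(x) > 0))
  expect_true(all(ord))
})

test_that("time-to-event pilot recovers the generating hazard ratio", {
  d <- generate_pilot_tte(5000, beta = 0.5, censor_fraction = 0, seed = 29)
  expect_true(all(d$time > 0))
  expect_true(all(d$event))
  fit <- survival::coxph(survival::Surv(time, event) ~ biomarker, data = d)
  est <- unname(coef(fit))
  se <- sqrt(diag(vcov(fit)))[1]
  expect_lt(abs(est - 0.5), 3 * se)

  # null effect: fitted hazard ratio near 1
  d0 <- generate_pilot_tte(5000, beta = 0, censor_fraction = 0, seed = 31)
  fit0 <- survival::coxph(survival::Surv(time, event) ~ biomarker, data = d0)
  expect_lt(abs(unname(coef(fit0))), 3 * sqrt(diag(vcov(fit0)))[1])

  # administrative censoring achieves the requested fraction in expectation
  dc <- generate_pilot_tte(5000, beta = 0.5, censor_fraction = 0.3, seed = 37)
  expect_lt(abs(mean(!dc$event) - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
  expect_error(generate_pilot_tte(100, 0.5, censor_fraction = 1),
               "censor_fraction")
  expect_error(generate_pilot_tte(1, 0.5), "n")
})

test_that("shipping-pair generator honors its linear model", {
  idp <- generate_shipping_pairs(20, slope = 1, intercept = 0, noise_sd = 0,
                                 seed = 41)
  expect_equal(idp$shipped, idp$immediate)
  expect_true(all(idp$immediate > 0))
  p7 <- generate_shipping_pairs(7, slope = 1.15, intercept = 5.19,
                                noise_sd = 0, seed = 43)
  expect_equal(nrow(p7), 7L)
  # closed-form least squares on noiseless pairs recovers the constants
  fit <- lm(shipped ~ immediate, data = p7)
  expect_equal(unname(coef(fit)), c(5.19, 1.15), tolerance = 1e-10)
  expect_error(generate_shipping_pairs(1), "n")
})
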