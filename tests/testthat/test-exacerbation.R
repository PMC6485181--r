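test_that("sign criteria honor their thresholds on both sides", {
  sgn <- function(...) evaluate_signs(clinical_assessment(...))

  # lung function: relative drop, exactly 10% counts
  expect_true("fev1_drop" %in% sgn(fev1_pp = 70, baseline_fev1_pp = 80))
  expect_true("fev1_drop" %in% sgn(fev1_pp = 72, baseline_fev1_pp = 80))
  expect_false("fev1_drop" %in% sgn(fev1_pp = 72.1, baseline_fev1_pp = 80))
  expect_true("fvc_drop" %in% sgn(fvc_pp = 81, baseline_fvc_pp = 90))
  # percentage-point mode
  s <- evaluate_signs(clinical_assessment(fev1_pp = 72, baseline_fev1_pp = 80),
                      fev_drop_relative = FALSE)
  expect_false("fev1_drop" %in% s)

  # temperature: strictly greater than 38.4
  expect_false("fever_over_38.4C" %in% sgn(temperature_C = 38.4))
  expect_true("fever_over_38.4C" %in% sgn(temperature_C = 38.5))

  # hemoptysis: strictly greater than 100 ml
  expect_false("hemoptysis_over_100ml" %in% sgn(hemoptysis_ml = 100))
  expect_true("hemoptysis_over_100ml" %in% sgn(hemoptysis_ml = 100.1))

  # hypoxemia despite usual oxygen
  expect_true("hypoxemia" %in% sgn(sao2 = 89.9))
  expect_false("hypoxemia" %in% sgn(sao2 = 90))
  expect_true("hypoxemia" %in% sgn(pao2 = 59))
  expect_false("hypoxemia" %in% sgn(pao2 = 60))
  expect_false("hypoxemia" %in% sgn(sao2 = 85, on_usual_oxygen = FALSE))

  # adolescent desaturation: >= 5 point drop, ages [12, 18) only
  expect_true("adolescent_desaturation" %in%
                sgn(age_years = 15, sao2 = 92, baseline_sao2 = 97))
  expect_false("adolescent_desaturation" %in%
                 sgn(age_years = 15, sao2 = 92.1, baseline_sao2 = 97))
  expect_false("adolescent_desaturation" %in%
                 sgn(age_years = 18, sao2 = 92, baseline_sao2 = 97))
  expect_false("adolescent_desaturation" %in%
                 sgn(age_years = 11, sao2 = 92, baseline_sao2 = 97))

  expect_true("increased_o2_requirement" %in%
                sgn(increased_o2_requirement = TRUE))

  # weight loss: >= 5% of baseline over at most 93 days
  wl <- function(w, bw, days) {
    "weight_loss_5pct" %in% sgn(
      date = as.Date("2015-06-01"), weight_kg = w, baseline_weight_kg = bw,
      baseline_weight_date = as.Date("2015-06-01") - days)
  }
  expect_true(wl(56.5, 60, 90))    # 5.83% over 90 days
  expect_true(wl(57, 60, 93))      # exactly 5% at the interval limit
  expect_false(wl(57.1, 60, 90))   # 4.83%
  expect_false(wl(56.5, 60, 94))   # window exceeded

  expect_error(clinical_assessment(temperature_C = 50), "temperature_C")
  expect_error(clinical_assessment(fev1_pp = 0), "fev1_pp")
  expect_error(clinical_assessment(weight_kg = -1), "weight_kg")
})

test_that("criteria with missing inputs are reported unevaluated", {
  s <- evaluate_signs(clinical_assessment(temperature_C = 39))
  expect_true("fever_over_38.4C" %in% s)
  expect_true(all(c("fev1_drop", "hypoxemia", "weight_loss_5pct") %in%
                    attr(s, "unevaluated")))
  expect_false("fever_over_38.4C" %in% attr(s, "unevaluated"))
})

test_that("classifier agrees with an exhaustive truth-table oracle", {
  # independently coded decision rule at the presence/absence level
  oracle <- function(has_sym, has_sign, vent, override) {
    if (!is.null(override) && override == "force_not") {
      if (has_sym || has_sign || vent) "mild" else "stable"
    } else if (!is.null(override) && override == "force_exacerbation") {
      "exacerbation"
    } else if (vent) {
      "exacerbation"
    } else if (has_sym && has_sign) {
      "exacerbation"
    } else if (has_sym || has_sign) {
      "mild"
    } else {
      "stable"
    }
  }
  for (has_sym in c(FALSE, TRUE)) {
    for (has_sign in c(FALSE, TRUE)) {
      for (vent in c(FALSE, TRUE)) {
        for (ov in list(NULL, "force_exacerbation", "force_not")) {
          call <- classify_exacerbation(
            assessment_case(has_sym, has_sign, vent, ov))
          expect_identical(
            call$verdict, oracle(has_sym, has_sign, vent, ov),
            info = sprintf("sym=%s sign=%s vent=%s ov=%s", has_sym,
                           has_sign, vent,
                           if (is.null(ov)) "none" else ov))
          expect_identical(call$override_applied, !is.null(ov))
        }
      }
    }
  }
  expect_error(clinical_assessment(
    pi_override = c("force_exacerbation", "force_not")), "contradictory")
})

test_that("adding a symptom or sign never demotes the verdict", {
  rank <- c(stable = 1, mild = 2, exacerbation = 3)
  base_cases <- list(
    clinical_assessment(),
    clinical_assessment(symptoms = "fatigue"),
    clinical_assessment(temperature_C = 39),
    clinical_assessment(symptoms = "cough", temperature_C = 39))
  for (a in base_cases) {
    v0 <- rank[classify_exacerbation(a)$verdict]
    a_sym <- a; a_sym$symptoms <- unique(c(a$symptoms, "chills"))
    a_sgn <- a; a_sgn$hemoptysis_ml <- 150
    expect_gte(rank[classify_exacerbation(a_sym)$verdict], v0)
    expect_gte(rank[classify_exacerbation(a_sgn)$verdict], v0)
  }
})

test_that("clinical stability mirrors the classifier with mild adjudication", {
  stable <- is_clinically_stable(clinical_assessment())
  expect_true(stable)
  ex <- is_clinically_stable(
    clinical_assessment(symptoms = "cough", temperature_C = 39))
  expect_false(ex)
  expect_false(attr(ex, "adjudicate"))
  mild <- is_clinically_stable(clinical_assessment(symptoms = "fatigue"))
  expect_false(mild)
  expect_true(attr(mild, "adjudicate"))
  mild_ok <- is_clinically_stable(clinical_assessment(symptoms = "fatigue"),
                                  mild_blocks = FALSE)
  expect_true(mild_ok)
})

test_that("prior history keeps the five latest strictly-prior events", {
  enr <- as.Date("2015-06-01")
  ev <- as.Date("2015-06-01") - c(400, 300, 200, 100, 50, 25, 10)
  got <- prior_exacerbation_history(ev, enr)
  # oracle: filter strictly before, sort descending, take 5
  oracle <- head(sort(ev[ev < enr], decreasing = TRUE), 5)
  expect_identical(got, oracle)
  expect_length(got, 5L)
  expect_length(prior_exacerbation_history(as.Date(character()), enr), 0L)
  expect_length(prior_exacerbation_history(enr, enr), 0L)  # same-day excluded
})

test_that("collection windows follow the protocol calendar", {
  enr <- as.Date("2015-01-15"); end <- as.Date("2016-01-15")
  w <- collection_windows(enr, as.Date("2015-03-01"), end)
  ex <- w[w$context == "exacerbation", ]
  expect_equal(ex$window_start, as.Date("2015-03-01"))
  expect_equal(ex$window_end, as.Date("2015-03-03"))      # within 48 h
  cv <- w[w$context == "convalescent", ]
  expect_equal(cv$window_start, as.Date("2015-03-29"))    # +28 days
  expect_equal(cv$window_end, as.Date("2015-05-24"))      # +84 days
  expect_equal(w$context[1], "enrollment")
  expect_equal(w$context[nrow(w)], "end_of_study")

  w2 <- collection_windows(enr, as.Date(c("2015-03-01", "2015-07-01")), end)
  expect_equal(sum(w2$context == "additional"), 1L)

  w0 <- collection_windows(enr, as.Date(character()), end)
  expect_identical(w0$context, c("enrollment", "end_of_study"))
  expect_error(collection_windows(enr, enr - 5, end), "before enrollment")
})

test_that("assessment tables classify row-wise through the CSV schema", {
  df <- data.frame(
    patient_id = c("a", "b", "c"), date = "2015-02-01",
    cough = c(1, 0, 0), fatigue = c(0, 1, 0),
    fev1_pp = c(70, NA, NA), baseline_fev1_pp = c(80, NA, NA),
    stringsAsFactors = FALSE)
  calls <- classify_assessments(df)
  expect_identical(calls$verdict, c("exacerbation", "mild", "stable"))
})
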