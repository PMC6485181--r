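#' Symptom vocabulary of the pulmonary-exacerbation definition
#'
#' The nine protocol symptoms. An exacerbation requires at least one
#' symptom together with at least one objective sign.
#'
#' @export
EXACERBATION_SYMPTOMS <- c(
  "increased_sputum", "cough", "dyspnea", "chest_pain_or_tightness",
  "hemoptysis", "fever", "chills", "arthralgias", "fatigue")

#' Construct a clinical assessment
#'
#' One clinic encounter: reported symptoms plus the objective measurements
#' the sign criteria need, with the patient's baselines for the relative
#' criteria. Missing measurements are allowed; criteria that cannot be
#' evaluated are skipped and reported as unevaluated rather than treated as
#' absent.
#'
#' @param patient_id,date identifiers (date used for the weight-loss
#'   interval).
#' @param symptoms character subset of [EXACERBATION_SYMPTOMS].
#' @param fev1_pp,fvc_pp current spirometry, percent predicted, in
#'   `(0, 150]`.
#' @param temperature_C body temperature, plausible range `[30, 45]`.
#' @param hemoptysis_ml witnessed hemoptysis volume per episode.
#' @param sao2,pao2 oxygen saturation (%) and arterial oxygen tension
#'   (mmHg).
#' @param on_usual_oxygen `TRUE` when the oxygenation measurements were
#'   taken on the patient's usual supplemental oxygen (including none).
#' @param increased_o2_requirement increased supplemental-oxygen need.
#' @param weight_kg current weight.
#' @param mechanical_ventilation respiratory arrest/failure requiring
#'   mechanical ventilation (qualifies regardless of other criteria).
#' @param baseline_fev1_pp,baseline_fvc_pp,baseline_sao2 baselines for the
#'   relative criteria.
#' @param baseline_weight_kg,baseline_weight_date baseline weight and its
#'   measurement date (weight loss counts only over <= 93 days).
#' @param age_years patient age (adolescent desaturation applies for ages
#'   in `[12, 18)`).
#' @param pi_override optional site-PI adjudication:
#'   `"force_exacerbation"` or `"force_not"`.
#' @return object of class `clinical_assessment`.
#' @export
clinical_assessment <- function(patient_id = NA_character_, date = Sys.Date(),
                                symptoms = character(),
                                fev1_pp = NA_real_, fvc_pp = NA_real_,
                                temperature_C = NA_real_,
                                hemoptysis_ml = NA_real_,
                                sao2 = NA_real_, pao2 = NA_real_,
                                on_usual_oxygen = TRUE,
                                increased_o2_requirement = FALSE,
                                weight_kg = NA_real_,
                                mechanical_ventilation = FALSE,
                                baseline_fev1_pp = NA_real_,
                                baseline_fvc_pp = NA_real_,
                                baseline_sao2 = NA_real_,
                                baseline_weight_kg = NA_real_,
                                baseline_weight_date = as.Date(NA),
                                age_years = NA_real_,
                                pi_override = NULL) {
  symptoms <- as.character(symptoms)
  bad <- setdiff(symptoms, EXACERBATION_SYMPTOMS)
  if (length(bad) > 0L)
    stop("unknown symptoms: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(pi_override)) {
    if (length(pi_override) > 1L)
      stop("contradictory double override", call. = FALSE)
    pi_override <- match.arg(pi_override, c("force_exacerbation", "force_not"))
  }
  for (v in c("fev1_pp", "fvc_pp", "baseline_fev1_pp", "baseline_fvc_pp")) {
    val <- get(v)
    if (!is.na(val) && (val <= 0 || val > 150))
      stop(sprintf("'%s' must be in (0, 150]", v), call. = FALSE)
  }
  if (!is.na(temperature_C) && (temperature_C < 30 || temperature_C > 45))
    stop("'temperature_C' outside plausible range [30, 45]", call. = FALSE)
  for (v in c("hemoptysis_ml", "sao2", "pao2", "weight_kg",
              "baseline_weight_kg", "baseline_sao2", "age_years")) {
    val <- get(v)
    if (!is.na(val) && val < 0)
      stop(sprintf("'%s' must be non-negative", v), call. = FALSE)
  }
  structure(list(
    patient_id = patient_id, date = as.Date(date), symptoms = symptoms,
    fev1_pp = fev1_pp, fvc_pp = fvc_pp, temperature_C = temperature_C,
    hemoptysis_ml = hemoptysis_ml, sao2 = sao2, pao2 = pao2,
    on_usual_oxygen = isTRUE(on_usual_oxygen),
    increased_o2_requirement = isTRUE(increased_o2_requirement),
    weight_kg = weight_kg,
    mechanical_ventilation = isTRUE(mechanical_ventilation),
    baseline_fev1_pp = baseline_fev1_pp, baseline_fvc_pp = baseline_fvc_pp,
    baseline_sao2 = baseline_sao2,
    baseline_weight_kg = baseline_weight_kg,
    baseline_weight_date = as.Date(baseline_weight_date),
    age_years = age_years, pi_override = pi_override
  ), class = "clinical_assessment")
}

#' Evaluate the objective sign criteria
#'
#' Checks each objective finding of the exacerbation definition against
#' the assessment:
#' \itemize{
#'   \item relative drop of at least 10% from baseline in FEV1 or FVC
#'     (exactly 10% counts; configurable to an absolute percentage-point
#'     drop via `fev_drop_relative = FALSE`);
#'   \item temperature strictly above 38.4 C;
#'   \item witnessed hemoptysis strictly above 100 ml per episode;
#'   \item SaO2 below 90% or PaO2 below 60 mmHg despite usual oxygen;
#'   \item for adolescents (age 12 to <18), an SaO2 drop of at least 5
#'     percentage points from baseline;
#'   \item increased supplemental-oxygen requirement;
#'   \item unplanned weight loss of at least 5% of baseline over at most 3
#'     months (93 days).
#' }
#' Criteria whose inputs are missing are skipped and listed in the
#' `unevaluated` attribute.
#'
#' @param assessment a [clinical_assessment()].
#' @param fev_drop_relative interpret the 10% lung-function drop relative
#'   to baseline (default) rather than as 10 percentage points.
#' @return character vector of sign names met, with attribute
#'   `unevaluated`.
#' @export
evaluate_signs <- function(assessment, fev_drop_relative = TRUE) {
  stopifnot(inherits(assessment, "clinical_assessment"))
  a <- assessment
  met <- character(0); unev <- character(0)

  drop_ok <- function(cur, base) {
    if (fev_drop_relative) (base - cur) / base >= 0.10 else base - cur >= 10
  }
  if (!is.na(a$fev1_pp) && !is.na(a$baseline_fev1_pp)) {
    if (drop_ok(a$fev1_pp, a$baseline_fev1_pp)) met <- c(met, "fev1_drop")
  } else unev <- c(unev, "fev1_drop")
  if (!is.na(a$fvc_pp) && !is.na(a$baseline_fvc_pp)) {
    if (drop_ok(a$fvc_pp, a$baseline_fvc_pp)) met <- c(met, "fvc_drop")
  } else unev <- c(unev, "fvc_drop")

  if (!is.na(a$temperature_C)) {
    if (a$temperature_C > 38.4) met <- c(met, "fever_over_38.4C")
  } else unev <- c(unev, "fever_over_38.4C")

  if (!is.na(a$hemoptysis_ml)) {
    if (a$hemoptysis_ml > 100) met <- c(met, "hemoptysis_over_100ml")
  } else unev <- c(unev, "hemoptysis_over_100ml")

  if (!is.na(a$sao2) || !is.na(a$pao2)) {
    hypox <- (!is.na(a$sao2) && a$sao2 < 90) ||
      (!is.na(a$pao2) && a$pao2 < 60)
    if (hypox && a$on_usual_oxygen) met <- c(met, "hypoxemia")
  } else unev <- c(unev, "hypoxemia")

  if (!is.na(a$age_years) && !is.na(a$sao2) && !is.na(a$baseline_sao2)) {
    if (a$age_years >= 12 && a$age_years < 18 &&
        a$baseline_sao2 - a$sao2 >= 5) {
      met <- c(met, "adolescent_desaturation")
    }
  } else unev <- c(unev, "adolescent_desaturation")

  if (a$increased_o2_requirement) met <- c(met, "increased_o2_requirement")

  if (!is.na(a$weight_kg) && !is.na(a$baseline_weight_kg) &&
      !is.na(a$baseline_weight_date)) {
    days <- as.numeric(a$date - a$baseline_weight_date)
    if (days >= 0 && days <= 93 &&
        (a$baseline_weight_kg - a$weight_kg) / a$baseline_weight_kg >= 0.05) {
      met <- c(met, "weight_loss_5pct")
    }
  } else unev <- c(unev, "weight_loss_5pct")

  structure(met, unevaluated = unev)
}

#' Classify an assessment as stable, mild or exacerbation
#'
#' A pulmonary exacerbation is the presence of at least one symptom and at
#' least one objective sign; respiratory arrest or failure requiring
#' mechanical ventilation qualifies regardless of other criteria, and the
#' site PI may force the call either way for borderline cases
#' (`force_not` takes precedence, including over ventilation). A "mild
#' exacerbation" is a one-sided presentation -- symptoms without signs, or
#' signs without symptoms -- capturing patients who are unstable without
#' meeting the full definition. Everything else is stable.
#'
#' @inheritParams evaluate_signs
#' @return object of class `exacerbation_call`: `verdict` ("stable",
#'   "mild" or "exacerbation"), `symptoms_met`, `signs_met`,
#'   `unevaluated`, `override_applied`.
#' @export
classify_exacerbation <- function(assessment, fev_drop_relative = TRUE) {
  stopifnot(inherits(assessment, "clinical_assessment"))
  signs <- evaluate_signs(assessment, fev_drop_relative = fev_drop_relative)
  symptoms <- assessment$symptoms
  has_sym <- length(symptoms) > 0L
  has_sign <- length(signs) > 0L
  ov <- assessment$pi_override

  if (!is.null(ov) && ov == "force_not") {
    verdict <- if (has_sym || has_sign || assessment$mechanical_ventilation)
      "mild" else "stable"
    override <- TRUE
  } else if (!is.null(ov) && ov == "force_exacerbation") {
    verdict <- "exacerbation"; override <- TRUE
  } else if (assessment$mechanical_ventilation ||
             (has_sym && has_sign)) {
    verdict <- "exacerbation"; override <- FALSE
  } else if (has_sym || has_sign) {
    verdict <- "mild"; override <- FALSE
  } else {
    verdict <- "stable"; override <- FALSE
  }

  structure(list(verdict = verdict,
                 symptoms_met = symptoms,
                 signs_met = as.character(signs),
                 unevaluated = attr(signs, "unevaluated"),
                 override_applied = override),
            class = "exacerbation_call")
}

#' @export
print.exacerbation_call <- function(x, ...) {
  cat(sprintf("Exacerbation call: %s\n", toupper(x$verdict)))
  cat(sprintf("  symptoms met: %s\n",
              if (length(x$symptoms_met)) paste(x$symptoms_met, collapse = ", ")
              else "none"))
  cat(sprintf("  signs met:    %s\n",
              if (length(x$signs_met)) paste(x$signs_met, collapse = ", ")
              else "none"))
  if (x$override_applied) cat("  (site-PI override applied)\n")
  invisible(x)
}

#' Is the patient clinically stable?
#'
#' Clinical stability is the absence of a pulmonary exacerbation. By
#' default a mild call also blocks enrollment and is flagged for site-PI
#' adjudication (`attr(., "adjudicate")`); set `mild_blocks = FALSE` to
#' count mild presentations as stable.
#'
#' @inheritParams evaluate_signs
#' @param mild_blocks should a mild call count as not stable?
#' @return logical with attribute `adjudicate` (`TRUE` for blocked mild
#'   calls).
#' @export
is_clinically_stable <- function(assessment, mild_blocks = TRUE,
                                 fev_drop_relative = TRUE) {
  call <- classify_exacerbation(assessment,
                                fev_drop_relative = fev_drop_relative)
  if (call$verdict == "exacerbation") return(structure(FALSE, adjudicate = FALSE))
  if (call$verdict == "mild" && mild_blocks)
    return(structure(FALSE, adjudicate = TRUE))
  structure(TRUE, adjudicate = FALSE)
}

#' Prior exacerbation history for enrollment
#'
#' The dates of up to the five most recent exacerbations strictly before
#' the enrollment date, newest first, used to adjust for duration of
#' clinical stability before sample collection.
#'
#' @param event_dates vector of exacerbation onset dates.
#' @param enrollment_date enrollment date; events on/after it are excluded.
#' @param n_max maximum history length (default 5).
#' @return Date vector, sorted descending, length `<= n_max`.
#' @export
prior_exacerbation_history <- function(event_dates, enrollment_date,
                                       n_max = 5) {
  event_dates <- as.Date(event_dates)
  enrollment_date <- as.Date(enrollment_date)
  prior <- event_dates[!is.na(event_dates) & event_dates < enrollment_date]
  prior <- sort(prior, decreasing = TRUE)
  utils::head(prior, n_max)
}

#' Protocol sample-collection windows
#'
#' Builds the due-window schedule for a participant: the enrollment sample
#' (day 0), a sample within 48 hours of the first post-enrollment
#' exacerbation diagnosis, a convalescent sample 4-12 weeks (28-84 days)
#' after that onset, 48-hour windows for any additional exacerbations, and
#' an end-of-study sample.
#'
#' @param enrollment_date enrollment date.
#' @param exacerbation_onsets ordered onset dates of post-enrollment
#'   exacerbations (may be empty).
#' @param study_end_date end-of-study date.
#' @return data.frame `context`, `window_start`, `window_end` (both
#'   inclusive calendar dates; the 48-h windows close 2 days after onset).
#' @export
collection_windows <- function(enrollment_date, exacerbation_onsets,
                               study_end_date) {
  enrollment_date <- as.Date(enrollment_date)
  study_end_date <- as.Date(study_end_date)
  onsets <- sort(as.Date(exacerbation_onsets))
  if (length(onsets) > 0L && any(onsets < enrollment_date))
    stop("exacerbation onset before enrollment", call. = FALSE)
  rows <- list(data.frame(context = "enrollment",
                          window_start = enrollment_date,
                          window_end = enrollment_date,
                          stringsAsFactors = FALSE))
  if (length(onsets) > 0L) {
    first <- onsets[1L]
    rows <- c(rows, list(
      data.frame(context = "exacerbation", window_start = first,
                 window_end = first + 2, stringsAsFactors = FALSE),
      data.frame(context = "convalescent", window_start = first + 28,
                 window_end = first + 84, stringsAsFactors = FALSE)))
    for (on in as.list(onsets[-1L])) {
      rows <- c(rows, list(
        data.frame(context = "additional", window_start = on,
                   window_end = on + 2, stringsAsFactors = FALSE)))
    }
  }
  rows <- c(rows, list(data.frame(context = "end_of_study",
                                  window_start = study_end_date,
                                  window_end = study_end_date,
                                  stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
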