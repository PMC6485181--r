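# CSV interfaces: documented column schemas for the tables the toolkit
# reads and writes. Dates are ISO-8601; symptom columns are 0/1 or
# TRUE/FALSE; blanks are missing.

#' Read a clinical-assessments table
#'
#' One row per encounter. Symptom columns (named as in
#' [EXACERBATION_SYMPTOMS]) are logical/0-1; measurement columns are
#' numeric and blanks mean missing. Recognized measurement columns:
#' `fev1_pp`, `fvc_pp`, `temperature_C`, `hemoptysis_ml`, `sao2`, `pao2`,
#' `on_usual_oxygen`, `increased_o2_requirement`, `weight_kg`,
#' `mechanical_ventilation`, `baseline_fev1_pp`, `baseline_fvc_pp`,
#' `baseline_sao2`, `baseline_weight_kg`, `baseline_weight_date`,
#' `age_years`, `pi_override`.
#'
#' @param path CSV file path.
#' @return data.frame of assessments.
#' @export
read_assessments <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

row_to_assessment <- function(row) {
  sym <- intersect(EXACERBATION_SYMPTOMS, names(row))
  present <- sym[vapply(sym, function(s) isTRUE(row[[s]] == 1) ||
                          isTRUE(as.logical(row[[s]])), logical(1))]
  num <- function(nm) if (nm %in% names(row) && !is.na(row[[nm]]))
    as.numeric(row[[nm]]) else NA_real_
  lgl <- function(nm, default) if (nm %in% names(row) && !is.na(row[[nm]]))
    as.logical(row[[nm]]) else default
  ov <- if ("pi_override" %in% names(row) && !is.na(row[["pi_override"]]) &&
            nzchar(row[["pi_override"]])) row[["pi_override"]] else NULL
  clinical_assessment(
    patient_id = if ("patient_id" %in% names(row))
      as.character(row[["patient_id"]]) else NA_character_,
    date = if ("date" %in% names(row) && !is.na(row[["date"]]))
      as.Date(row[["date"]]) else Sys.Date(),
    symptoms = present,
    fev1_pp = num("fev1_pp"), fvc_pp = num("fvc_pp"),
    temperature_C = num("temperature_C"),
    hemoptysis_ml = num("hemoptysis_ml"),
    sao2 = num("sao2"), pao2 = num("pao2"),
    on_usual_oxygen = lgl("on_usual_oxygen", TRUE),
    increased_o2_requirement = lgl("increased_o2_requirement", FALSE),
    weight_kg = num("weight_kg"),
    mechanical_ventilation = lgl("mechanical_ventilation", FALSE),
    baseline_fev1_pp = num("baseline_fev1_pp"),
    baseline_fvc_pp = num("baseline_fvc_pp"),
    baseline_sao2 = num("baseline_sao2"),
    baseline_weight_kg = num("baseline_weight_kg"),
    baseline_weight_date = if ("baseline_weight_date" %in% names(row) &&
                               !is.na(row[["baseline_weight_date"]]))
      as.Date(row[["baseline_weight_date"]]) else as.Date(NA),
    age_years = num("age_years"),
    pi_override = ov)
}

#' Classify every row of an assessments table
#'
#' Applies [classify_exacerbation()] row-wise to a table read with
#' [read_assessments()].
#'
#' @param assessments data.frame of assessments.
#' @param fev_drop_relative see [evaluate_signs()].
#' @return data.frame `patient_id`, `date`, `verdict`, `n_symptoms`,
#'   `n_signs`, `override_applied`.
#' @export
classify_assessments <- function(assessments, fev_drop_relative = TRUE) {
  rows <- lapply(seq_len(nrow(assessments)), function(i) {
    a <- row_to_assessment(assessments[i, , drop = FALSE])
    call <- classify_exacerbation(a, fev_drop_relative = fev_drop_relative)
    data.frame(patient_id = a$patient_id, date = a$date,
               verdict = call$verdict,
               n_symptoms = length(call$symptoms_met),
               n_signs = length(call$signs_met),
               override_applied = call$override_applied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the synthetic-study tables to a directory
#'
#' Convenience writer used by the command-line interface: patients.csv,
#' visits.csv, events.csv, pilot.csv and pairs.csv with the column
#' schemas produced by the corresponding generators.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [population_config()].
#' @param horizon_days visit/event horizon.
#' @param annual_exacerbation_rate events per patient-year for the event
#'   process.
#' @param seed integer seed.
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_study <- function(out_dir, config = population_config(),
                                  horizon_days = 365,
                                  annual_exacerbation_rate = 1,
                                  seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  patients <- generate_population(config, seed = seed)
  visits <- generate_visits(patients, horizon_days = horizon_days,
                            no_show_rate = config$no_show_rate,
                            seed = seed + 1)
  events <- generate_exacerbation_process(patients$patient_id,
                                          annual_exacerbation_rate,
                                          horizon_days, seed = seed + 2)
  pilot <- generate_pilot_tte(200, beta = 0.5, censor_fraction = 0.2,
                              seed = seed + 3)
  pairs <- generate_shipping_pairs(7, noise_sd = 2, seed = seed + 4)
  paths <- c(patients = file.path(out_dir, "patients.csv"),
             visits = file.path(out_dir, "visits.csv"),
             events = file.path(out_dir, "events.csv"),
             pilot = file.path(out_dir, "pilot.csv"),
             pairs = file.path(out_dir, "pairs.csv"))
  utils::write.csv(patients, paths["patients"], row.names = FALSE)
  utils::write.csv(visits, paths["visits"], row.names = FALSE)
  utils::write.csv(events, paths["events"], row.names = FALSE)
  utils::write.csv(pilot, paths["pilot"], row.names = FALSE)
  utils::write.csv(pairs, paths["pairs"], row.names = FALSE)
  invisible(paths)
}
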