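# Shared small fixtures built in code.

tiny_population <- function(n_adult = 200, n_ped = 50, seed = 1) {
  cfg <- population_config(n_centers = 1, adult_pool = n_adult,
                           pediatric_pool = n_ped, seed = seed)
  generate_population(cfg)
}

# a fully compliant processing record starting at 10:00
compliant_sample <- function(sample_id = "S1", participant_id = "P-001",
                             sample_number = 1L) {
  t0 <- as.POSIXct("2015-03-01 10:00:00", tz = "UTC")
  sample_record(sample_id, participant_id,
                collection_start = t0,
                collection_end = t0 + 15 * 60,
                transport_start = t0 + 20 * 60,
                processing_start = t0 + 45 * 60,
                processing_end = t0 + 120 * 60,
                sample_number = sample_number)
}

# assessment with a given number of present symptoms and a fever sign toggle
assessment_case <- function(has_symptom, has_sign, vent = FALSE,
                            override = NULL) {
  clinical_assessment(
    symptoms = if (has_symptom) "cough" else character(),
    temperature_C = if (has_sign) 39.0 else 37.0,
    mechanical_ventilation = vent,
    pi_override = override)
}
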