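#' Construct a sputum sample processing record
#'
#' Timestamps of a sample's collection, transport and processing plus the
#' protocol metadata. Timestamps must be non-decreasing in the order
#' collection_start, collection_end, transport_start, processing_start,
#' processing_end. A compliant sample is centrifuged 20 min at 2800 g at
#' 4 C and yields the four fractions L (lipid), SA (aqueous, buffer
#' diluted), SB (aqueous, protease-inhibitor diluted) and P (pellet).
#'
#' @param sample_id sample identifier.
#' @param participant_id participant study ID.
#' @param collection_start,collection_end,processing_start,processing_end
#'   POSIXct timestamps; `transport_start` optional.
#' @param transport_start optional POSIXct timestamp.
#' @param sputum_weight_g sample weight in grams.
#' @param context protocol collection context.
#' @param centrifugation list `minutes`, `g_force`, `temperature_C`.
#' @param fractions fractions produced, subset of L, SA, SB, P.
#' @param sample_number per-participant sample number.
#' @return object of class `sample_record`.
#' @export
sample_record <- function(sample_id, participant_id,
                          collection_start, collection_end,
                          processing_start, processing_end,
                          transport_start = NULL,
                          sputum_weight_g = NA_real_,
                          context = c("enrollment", "exacerbation",
                                      "convalescent", "additional",
                                      "end_of_study"),
                          centrifugation = list(minutes = 20, g_force = 2800,
                                                temperature_C = 4),
                          fractions = c("L", "SA", "SB", "P"),
                          sample_number = 1L) {
  context <- match.arg(context)
  if (length(setdiff(fractions, c("L", "SA", "SB", "P"))) > 0L)
    stop("fractions must be a subset of L, SA, SB, P", call. = FALSE)
  ts <- c(collection_start = as.POSIXct(collection_start),
          collection_end = as.POSIXct(collection_end),
          transport_start = if (is.null(transport_start)) NULL else
            as.POSIXct(transport_start),
          processing_start = as.POSIXct(processing_start),
          processing_end = as.POSIXct(processing_end))
  if (is.unsorted(as.numeric(ts)))
    stop("timestamps out of order (must be non-decreasing)", call. = FALSE)
  structure(list(sample_id = sample_id, participant_id = participant_id,
                 collection_start = as.POSIXct(collection_start),
                 collection_end = as.POSIXct(collection_end),
                 transport_start = if (is.null(transport_start)) NULL else
                   as.POSIXct(transport_start),
                 processing_start = as.POSIXct(processing_start),
                 processing_end = as.POSIXct(processing_end),
                 sputum_weight_g = sputum_weight_g, context = context,
                 centrifugation = centrifugation, fractions = fractions,
                 sample_number = as.integer(sample_number)),
            class = "sample_record")
}

#' Validate sputum processing timing
#'
#' Protocol limits: sputum collection at most 20 minutes; at most 60
#' minutes from start of collection to initiation of laboratory
#' processing (collection plus 40 minutes of iced transport); at most 3
#' hours from initiation to completion of processing. Returns the list of
#' violated limits, empty for a compliant sample.
#'
#' @param sample a [sample_record()].
#' @return character vector of violations (possibly empty), from
#'   `"collection_over_20min"`, `"initiation_over_60min"`,
#'   `"processing_over_3h"`.
#' @export
validate_timing <- function(sample) {
  stopifnot(inherits(sample, "sample_record"))
  mins <- function(a, b) as.numeric(difftime(b, a, units = "mins"))
  out <- character(0)
  if (mins(sample$collection_start, sample$collection_end) > 20)
    out <- c(out, "collection_over_20min")
  if (mins(sample$collection_start, sample$processing_start) > 60)
    out <- c(out, "initiation_over_60min")
  if (mins(sample$processing_start, sample$processing_end) > 180)
    out <- c(out, "processing_over_3h")
  out
}

#' Generate aliquot labels for a processed sample
#'
#' Default plan: one lipid (L) aliquot, two buffer-diluted aqueous (SA),
#' two protease-inhibitor-diluted aqueous (SB) and one pellet (P).
#' Labels render every component as
#' `<participantID>_<YYYYMMDD>_<fraction>_<sample#>_<aliquot#>` and are
#' unique; aliquot numbering restarts at 1 within each fraction.
#'
#' @param sample a [sample_record()].
#' @param plan named integer vector of aliquot counts per fraction.
#' @param collection_date date used in the label (defaults to the
#'   collection start date).
#' @return data.frame `label`, `participant_id`, `collection_date`,
#'   `fraction`, `sample_number`, `aliquot_number`, `diluent`,
#'   `storage_temp_C`.
#' @export
make_labels <- function(sample, plan = c(L = 1L, SA = 2L, SB = 2L, P = 1L),
                        collection_date = NULL) {
  stopifnot(inherits(sample, "sample_record"))
  if (length(plan) == 0L) stop("empty fraction plan", call. = FALSE)
  if (is.null(names(plan)) ||
      length(setdiff(names(plan), c("L", "SA", "SB", "P"))) > 0L)
    stop("plan names must be fractions L, SA, SB, P", call. = FALSE)
  if (any(plan < 1)) stop("aliquot counts must be >= 1", call. = FALSE)
  collection_date <- as.Date(collection_date %||%
                               as.Date(sample$collection_start))
  diluent <- c(L = "none", SA = "HBSS_buffer", SB = "protease_inhibitor",
               P = "none")
  rows <- lapply(names(plan), function(fr) {
    data.frame(
      participant_id = sample$participant_id,
      collection_date = collection_date,
      fraction = fr,
      sample_number = sample$sample_number,
      aliquot_number = seq_len(plan[[fr]]),
      diluent = diluent[[fr]],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$label <- sprintf("%s_%s_%s_%d_%d", out$participant_id,
                       format(out$collection_date, "%Y%m%d"), out$fraction,
                       out$sample_number, out$aliquot_number)
  out$storage_temp_C <- -70
  out <- out[, c("label", "participant_id", "collection_date", "fraction",
                 "sample_number", "aliquot_number", "diluent",
                 "storage_temp_C")]
  rownames(out) <- NULL
  out
}

#' Parse an aliquot label back into its components
#'
#' Inverse of the label rendering in [make_labels()]:
#' `parse_label(render(x))` recovers every component.
#'
#' @param label character vector of labels.
#' @return data.frame `participant_id`, `collection_date`, `fraction`,
#'   `sample_number`, `aliquot_number`.
#' @export
parse_label <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 5L
  if (any(bad)) stop("malformed label(s)", call. = FALSE)
  do.call(rbind, lapply(parts, function(p) {
    k <- length(p)
    data.frame(
      participant_id = paste(p[seq_len(k - 4L)], collapse = "_"),
      collection_date = as.Date(p[k - 3L], format = "%Y%m%d"),
      fraction = p[k - 2L],
      sample_number = as.integer(p[k - 1L]),
      aliquot_number = as.integer(p[k]),
      stringsAsFactors = FALSE)
  }))
}

#' Assign aliquots to split-batch shipments
#'
#' Distributes aliquots over `n_shipments` so that no shipment contains
#' every aliquot of any sample: losing any single shipment leaves at
#' least one aliquot of each multi-aliquot sample. Within that
#' constraint, shipment sizes are kept balanced (within one where
#' feasible) by always assigning to the least-loaded shipments. Samples
#' with a single aliquot cannot satisfy the invariant and are flagged
#' with a warning.
#'
#' @param aliquots data.frame as from [make_labels()], or at least
#'   `label` plus a sample identity (`participant_id` + `sample_number`).
#' @param n_shipments number of shipments, `>= 2`.
#' @return `aliquots` with a `shipment_id` column (`"S1"`, `"S2"`, ...).
#' @export
assign_split_batches <- function(aliquots, n_shipments = 2) {
  if (n_shipments < 2) stop("'n_shipments' must be >= 2", call. = FALSE)
  n_shipments <- as.integer(n_shipments)
  key <- paste(aliquots$participant_id, aliquots$sample_number, sep = "#")
  sizes <- table(key)
  singles <- names(sizes)[sizes == 1L]
  if (length(singles) > 0L) {
    warning(sprintf(
      "%d sample(s) with a single aliquot cannot be split across shipments",
      length(singles)), call. = FALSE)
  }
  load <- integer(n_shipments)
  ship <- integer(nrow(aliquots))
  for (s in unique(key)) {
    idx <- which(key == s)
    m <- length(idx)
    # fill the least-loaded shipments first, cycling when m > n_shipments;
    # distinct shipments for the first min(m, n) aliquots guarantee the split
    ord <- order(load, seq_along(load))
    assign_to <- rep(ord, length.out = m)
    ship[idx] <- assign_to
    tb <- tabulate(assign_to, nbins = n_shipments)
    load <- load + tb
  }
  aliquots$shipment_id <- paste0("S", ship)
  aliquots
}

#' Sputum sample quality control
#'
#' Flags oral contamination (at least 5 squamous epithelial cells per
#' low-power field) and low count adequacy (fewer than 200 cells counted;
#' the protocol expects 200-500). The cell differential must sum to 1.
#'
#' @param squamous_per_lpf squamous epithelial cells per low-power field.
#' @param cells_counted total cells counted.
#' @param differential named numeric fractions (e.g. `neutrophil`,
#'   `lymphocyte`, `eosinophil`, `other`) summing to 1.
#' @param tol tolerance for the differential sum check.
#' @return object of class `qc_result`: `squamous_per_lpf`,
#'   `oral_contamination`, `cells_counted`, `count_adequacy`
#'   (`"adequate"`/`"low"`), `differential`.
#' @export
qc_sample <- function(squamous_per_lpf, cells_counted, differential,
                      tol = 1e-6) {
  check_pos(squamous_per_lpf, "squamous_per_lpf", strict = FALSE)
  check_pos(cells_counted, "cells_counted", strict = FALSE)
  if (any(differential < 0) || any(differential > 1))
    stop("differential fractions must be in [0, 1]", call. = FALSE)
  if (abs(sum(differential) - 1) > tol)
    stop("differential does not sum to 1 within tolerance", call. = FALSE)
  structure(list(
    squamous_per_lpf = squamous_per_lpf,
    oral_contamination = squamous_per_lpf >= 5,
    cells_counted = cells_counted,
    count_adequacy = if (cells_counted < 200) "low" else "adequate",
    differential = differential
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Sputum sample QC\n")
  cat(sprintf("  squamous cells/LPF: %g -> %s\n", x$squamous_per_lpf,
              if (x$oral_contamination) "ORAL CONTAMINATION" else "clean"))
  cat(sprintf("  cells counted: %g (%s)\n", x$cells_counted,
              x$count_adequacy))
  invisible(x)
}
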