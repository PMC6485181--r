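#' Assign random letters to patients
#'
#' Gives every potentially eligible patient an i.i.d. uniform letter of the
#' alphabet (index 0-25, 0 = "A"), one adult and one pediatric block per
#' center. The letter is the only token recruitment decisions may depend
#' on, which is what conceals inclusion from clinic staff: whether a
#' patient is approached is determined by their pre-assigned letter and the
#' block's threshold, never by their characteristics.
#'
#' @param patients data.frame with `patient_id` and `block_key` columns.
#' @param seed integer seed.
#' @return data.frame `patient_id`, `block_key`, `letter` (integer 0-25),
#'   `letter_char`.
#' @export
assign_letters <- function(patients, seed = NULL) {
  if (nrow(patients) == 0L) {
    return(data.frame(patient_id = character(), block_key = character(),
                      letter = integer(), letter_char = character(),
                      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in 'patients'", call. = FALSE)
  with_seed(seed, {
    letter <- sample.int(26L, nrow(patients), replace = TRUE) - 1L
    data.frame(patient_id = patients$patient_id,
               block_key = patients$block_key,
               letter = letter,
               letter_char = LETTERS[letter + 1L],
               stringsAsFactors = FALSE)
  })
}

#' Smallest threshold meeting an enrollment target
#'
#' The threshold index `k` is the number of flagged letters (0 = none,
#' 26 = all); a patient is flagged when their letter index is strictly
#' earlier than `k`, so the threshold letter itself (`LETTERS[k + 1]`) is
#' not flagged. Expected enrollment from a pool of `N` patients is
#' `(k/26) * N * consent_rate * show_rate`; this returns the smallest `k`
#' in 0..26 whose expectation reaches `target_enrollment`, scanning all
#' values of `k` directly.
#'
#' When even `k = 26` falls short the function returns 26 with attribute
#' `insufficient = TRUE` and a warning: the pool cannot meet the target.
#'
#' @param pool_size number of patients available, `>= 0`.
#' @param target_enrollment enrollment target, `>= 0`.
#' @param consent_rate probability an approached patient consents (planning
#'   value 0.53).
#' @param show_rate probability a patient attends clinic (planning value
#'   0.90, i.e. a 10% no-show rate).
#' @return integer `k` in 0..26 with attribute `insufficient`.
#' @export
required_threshold <- function(pool_size, target_enrollment, consent_rate,
                               show_rate) {
  check_pos(pool_size, "pool_size", strict = FALSE)
  check_pos(target_enrollment, "target_enrollment", strict = FALSE)
  check_prob(consent_rate, "consent_rate")
  check_prob(show_rate, "show_rate")
  if (target_enrollment > 0 && (consent_rate == 0 || show_rate == 0))
    stop("infeasible: zero consent or show rate with a positive target",
         call. = FALSE)
  expected <- (0:26) / 26 * pool_size * consent_rate * show_rate
  ok <- which(expected >= target_enrollment)
  if (length(ok) == 0L) {
    warning("insufficient pool: even k = 26 does not reach the target",
            call. = FALSE)
    return(structure(26L, insufficient = TRUE))
  }
  structure(as.integer(ok[1L] - 1L), insufficient = FALSE)
}

#' Is a letter flagged under a threshold?
#'
#' Strict earlier-than rule: letter index `< k`. With `k = 0` nothing is
#' flagged; with `k = 26` every letter is.
#'
#' @param letter integer letter index/indices in 0..25.
#' @param threshold_index integer `k` in 0..26 (recycled).
#' @return logical vector.
#' @export
is_flagged <- function(letter, threshold_index) {
  if (any(letter < 0 | letter > 25) || anyNA(letter))
    stop("'letter' must be in 0..25", call. = FALSE)
  if (any(threshold_index < 0 | threshold_index > 26) || anyNA(threshold_index))
    stop("'threshold_index' must be in 0..26", call. = FALSE)
  letter < threshold_index
}

#' Per-block threshold state
#'
#' The decision record that makes inclusion replayable: the threshold index
#' in force, the planning consent/show rates and their current estimates,
#' the block's pool and enrollment target, and the adjustment history.
#'
#' @param block_key block identifier (`center:block`).
#' @param pool_size eligible patients in the block.
#' @param target_total enrollment target for the block.
#' @param consent_rate,show_rate planning-stage rates used for the initial
#'   threshold and as the shrinkage prior during re-estimation.
#' @param effective_from date the initial threshold takes effect.
#' @param k optional explicit initial threshold; when `NULL` it is computed
#'   with [required_threshold()].
#' @return object of class `threshold_state`.
#' @export
threshold_state <- function(block_key, pool_size, target_total,
                            consent_rate = 0.53, show_rate = 0.90,
                            effective_from = as.Date("2014-12-08"),
                            k = NULL) {
  if (is.null(k)) {
    k <- suppressWarnings(
      required_threshold(pool_size, target_total, consent_rate, show_rate))
  }
  stopifnot(k >= 0, k <= 26)
  structure(list(
    block_key = block_key,
    k = as.integer(k),
    pool_size = as.integer(pool_size),
    target_total = target_total,
    consent_rate_plan = consent_rate, show_rate_plan = show_rate,
    consent_rate_estimate = consent_rate, show_rate_estimate = show_rate,
    target_remaining = target_total,
    effective_from = as.Date(effective_from),
    history = data.frame(
      effective_from = as.Date(effective_from), k = as.integer(k),
      rationale = "planned", consent_rate_estimate = consent_rate,
      show_rate_estimate = show_rate, n_enrolled = 0, prorata_target = 0,
      insufficient = isTRUE(attr(k, "insufficient")),
      stringsAsFactors = FALSE)
  ), class = "threshold_state")
}

#' Initial per-block threshold states for a study
#'
#' Builds one [threshold_state()] per block, splitting the study-wide
#' enrollment target across blocks in proportion to their eligible pool
#' sizes and computing each block's initial threshold with
#' [required_threshold()].
#'
#' @param patients patient table with `block_key` and `eligible`.
#' @param target_total study-wide enrollment target.
#' @param consent_rate,show_rate planning-stage rates.
#' @param effective_from date the initial thresholds take effect.
#' @return named list of `threshold_state`, keyed by `block_key`.
#' @export
initial_states <- function(patients, target_total, consent_rate = 0.53,
                           show_rate = 0.90,
                           effective_from = as.Date("2014-12-08")) {
  pools <- tapply(patients$eligible, patients$block_key, sum)
  total <- sum(pools)
  if (total == 0) stop("no eligible patients", call. = FALSE)
  out <- lapply(names(pools), function(b) {
    suppressWarnings(threshold_state(
      b, pool_size = pools[[b]],
      target_total = target_total * pools[[b]] / total,
      consent_rate = consent_rate, show_rate = show_rate,
      effective_from = effective_from))
  })
  stats::setNames(out, names(pools))
}

#' Review schedule for enrollment-speed adjustments
#'
#' End of study month 1, then quarterly beginning with study month 3
#' (months 3, 6, 9, ...), up to the horizon.
#'
#' @param start_date study start.
#' @param horizon_days study length in days.
#' @return vector of review dates.
#' @export
review_dates <- function(start_date, horizon_days) {
  start_date <- as.Date(start_date)
  end <- start_date + horizon_days
  first <- seq(start_date, by = "1 month", length.out = 2L)[2L]
  quarterly <- seq(seq(start_date, by = "3 months", length.out = 2L)[2L],
                   end, by = "3 months")
  out <- sort(unique(c(first, quarterly)))
  out[out > start_date & out < end]
}

#' Adjust a block's threshold at a review
#'
#' Re-runs [required_threshold()] with the remaining pool (patients
#' neither enrolled nor declined), the remaining target, and consent/show
#' rates re-estimated from the observed trace (empirical rates shrunk
#' toward the planning values with a weight of 10 pseudo-observations).
#' The speed signal is the comparison of the recomputed threshold with the
#' one in force: when the current threshold would over-deliver -- the
#' projected eventual enrollment, `enrolled + (k/26) * pool_remaining *
#' c * s`, exceeds the target even one letter earlier -- enrollment is too
#' rapid and the threshold moves strictly earlier in the alphabet; when
#' the projection falls short, enrollment is too slow and it moves
#' strictly later; otherwise it is unchanged. Past flag decisions are
#' never revisited and enrolled patients are never un-enrolled.
#'
#' @param state a [threshold_state()].
#' @param observed list of cumulative counts for the block:
#'   `n_seen` (distinct patients with any scheduled visit so far),
#'   `n_scheduled` and `n_shown` (visit counts), `n_approached` (distinct
#'   patients approached), `n_enrolled`, `n_declined`, and optionally
#'   `n_undecided_by_letter` (length-26 counts of undecided patients per
#'   assigned letter). When the letter histogram is given the projection
#'   uses it -- undecided patients are not letter-uniform once earlier
#'   letters have been consumed -- otherwise letters are assumed uniform
#'   as in [required_threshold()]. The histogram is available to the
#'   coordinating statistician who assigned the letters and preserves
#'   concealment: no covariate enters the decision.
#' @param review_date date of the review; must be on/after the state's
#'   `effective_from`.
#' @param shrink_weight pseudo-observation weight of the planning rates in
#'   re-estimation.
#' @return updated `threshold_state` with one more history row.
#' @export
adjust_threshold <- function(state, observed, review_date, shrink_weight = 10) {
  stopifnot(inherits(state, "threshold_state"))
  review_date <- as.Date(review_date)
  if (review_date < state$effective_from)
    stop("review before any observation period", call. = FALSE)
  need <- c("n_seen", "n_scheduled", "n_shown", "n_approached",
            "n_enrolled", "n_declined")
  if (!all(need %in% names(observed)))
    stop("'observed' must contain: ", paste(need, collapse = ", "),
         call. = FALSE)

  w <- shrink_weight
  s_hat <- (observed$n_shown + w * state$show_rate_plan) /
    (observed$n_scheduled + w)
  c_hat <- (observed$n_enrolled + w * state$consent_rate_plan) /
    (observed$n_approached + w)
  s_hat <- min(max(s_hat, 0), 1); c_hat <- min(max(c_hat, 0), 1)

  target_remaining <- max(0, state$target_total - observed$n_enrolled)
  pool_remaining <- max(0L, state$pool_size - observed$n_enrolled -
                          observed$n_declined)
  insufficient <- FALSE
  if (target_remaining == 0) {
    candidate <- 0L
  } else if (!is.null(observed$n_undecided_by_letter)) {
    counts <- observed$n_undecided_by_letter
    stopifnot(length(counts) == 26L)
    # projected additional enrollment with threshold k: consent x show x
    # number of undecided patients whose letter is earlier than k
    projected <- c_hat * s_hat * cumsum(c(0, counts))
    ok <- which(projected >= target_remaining)
    if (length(ok) == 0L) {
      insufficient <- TRUE
      candidate <- 26L
    } else {
      candidate <- as.integer(ok[1L] - 1L)
    }
  } else {
    candidate <- withCallingHandlers(
      required_threshold(pool_remaining, target_remaining, c_hat, s_hat),
      warning = function(wrn) {
        insufficient <<- TRUE
        invokeRestart("muffleWarning")
      })
  }

  prorata <- state$target_total *
    (if (state$pool_size > 0) observed$n_seen / state$pool_size else 0)
  k_old <- state$k
  k_new <- as.integer(candidate)
  rationale <- if (k_new < k_old) "speed_adjustment_earlier"
    else if (k_new > k_old) "speed_adjustment_later"
    else "on_target"

  state$k <- k_new
  state$consent_rate_estimate <- c_hat
  state$show_rate_estimate <- s_hat
  state$target_remaining <- target_remaining
  state$effective_from <- review_date
  state$history <- rbind(state$history, data.frame(
    effective_from = review_date, k = k_new, rationale = rationale,
    consent_rate_estimate = c_hat, show_rate_estimate = s_hat,
    n_enrolled = observed$n_enrolled, prorata_target = prorata,
    insufficient = insufficient, stringsAsFactors = FALSE))
  state
}

#' Simulate randomized enrollment with adaptive speed control
#'
#' Processes clinic visits in date order (ties broken by patient id). At
#' each visit a patient is flagged iff their letter is strictly earlier
#' than the block threshold in force that day. Flagged, eligible,
#' previously undecided patients who show are approached; consent is a
#' Bernoulli draw with the true consent rate. Declining patients are not
#' re-approached; unflagged patients are re-evaluated whenever the
#' threshold moves. Thresholds are adjusted at review dates with
#' [adjust_threshold()]; enrolled patients are never un-enrolled by a
#' threshold decrease.
#'
#' @param patients patient table (needs `patient_id`, `block_key`,
#'   `eligible`).
#' @param letters output of [assign_letters()].
#' @param visits output of [generate_visits()].
#' @param states named list of [threshold_state()] keyed by `block_key`
#'   (a single state is recycled to every block).
#' @param reviews vector of review dates, or `NULL` for a fixed threshold.
#' @param consent_rate true consent probability used for the Bernoulli
#'   draws.
#' @param seed integer seed (consent draws only; flagging is
#'   deterministic).
#' @return object of class `enrollment_trace`: list with `trace` (one row
#'   per visit: flag, approach, consent, enrollment and the threshold in
#'   force), `thresholds` (full adjustment history), `states` (final
#'   states) and `enrolled` (patient ids).
#' @export
simulate_enrollment <- function(patients, letters, visits, states,
                                reviews = NULL, consent_rate = 0.53,
                                seed = NULL) {
  check_prob(consent_rate, "consent_rate")
  if (!all(visits$patient_id %in% patients$patient_id))
    stop("visit references unknown patient", call. = FALSE)
  if (inherits(states, "threshold_state")) {
    blocks <- unique(patients$block_key)
    template <- states
    states <- lapply(blocks, function(b) { template$block_key <- b; template })
    names(states) <- blocks
  }

  lmap <- letters$letter[match(patients$patient_id, letters$patient_id)]
  if (anyNA(lmap)) stop("missing letters for some patients", call. = FALSE)

  v <- visits[order(visits$visit_date, visits$patient_id), , drop = FALSE]
  pidx <- match(v$patient_id, patients$patient_id)
  v$block_key <- patients$block_key[pidx]
  v$letter <- lmap[pidx]
  v$eligible <- patients$eligible[pidx]

  status <- stats::setNames(rep("undecided", nrow(patients)),
                            patients$patient_id)
  seen <- stats::setNames(rep(FALSE, nrow(patients)), patients$patient_id)
  approached_ever <- stats::setNames(rep(FALSE, nrow(patients)),
                                     patients$patient_id)
  counts <- list()  # per block cumulative n_scheduled / n_shown

  reviews <- sort(unique(as.Date(reviews)))
  bounds <- c(min(v$visit_date, as.Date("2100-01-01")) - 1,
              reviews, max(v$visit_date, as.Date("1900-01-01")) + 1)

  out_rows <- vector("list", length(bounds) - 1L)
  with_seed(seed, {
    # one consent uniform per patient (common random numbers): enrollment is
    # then pathwise non-decreasing in the threshold index
    consent_u <- stats::setNames(stats::runif(nrow(patients)),
                                 patients$patient_id)
    for (si in seq_len(length(bounds) - 1L)) {
      seg_start <- bounds[si]; seg_end <- bounds[si + 1L]
      if (si > 1L) {
        review_date <- bounds[si]
        for (b in names(states)) {
          in_block <- patients$block_key == b
          pool_ids <- patients$patient_id[in_block & patients$eligible]
          cb <- counts[[b]] %||% list(n_scheduled = 0L, n_shown = 0L)
          undecided <- pool_ids[status[pool_ids] == "undecided"]
          letter_hist <- tabulate(
            lmap[match(undecided, patients$patient_id)] + 1L, nbins = 26L)
          observed <- list(
            n_seen = sum(seen[pool_ids]),
            n_scheduled = cb$n_scheduled,
            n_shown = cb$n_shown,
            n_approached = sum(approached_ever[pool_ids]),
            n_enrolled = sum(status[pool_ids] == "enrolled"),
            n_declined = sum(status[pool_ids] == "declined"),
            n_undecided_by_letter = letter_hist)
          states[[b]] <- adjust_threshold(states[[b]], observed, review_date)
        }
      }
      seg <- v[v$visit_date >= seg_start & v$visit_date < seg_end, ,
               drop = FALSE]
      if (nrow(seg) == 0L) next
      k_in_force <- vapply(states[seg$block_key],
                           function(s) s$k, integer(1))
      seg$k_in_force <- unname(k_in_force)
      seg$flagged <- seg$letter < seg$k_in_force
      seen[unique(seg$patient_id)] <- TRUE
      for (b in unique(seg$block_key)) {
        m <- seg$block_key == b & seg$eligible
        cb <- counts[[b]] %||% list(n_scheduled = 0L, n_shown = 0L)
        cb$n_scheduled <- cb$n_scheduled + sum(m)
        cb$n_shown <- cb$n_shown + sum(seg$showed[m])
        counts[[b]] <- cb
      }
      # approach each flagged, shown, eligible, undecided patient once
      cand <- which(seg$flagged & seg$showed & seg$eligible &
                      status[seg$patient_id] == "undecided")
      cand <- cand[!duplicated(seg$patient_id[cand])]
      seg$approached <- FALSE
      seg$consented <- FALSE
      seg$enrolled <- FALSE
      if (length(cand) > 0L) {
        consent <- consent_u[seg$patient_id[cand]] < consent_rate
        seg$approached[cand] <- TRUE
        seg$consented[cand] <- consent
        seg$enrolled[cand] <- consent
        ids <- seg$patient_id[cand]
        approached_ever[ids] <- TRUE
        status[ids] <- ifelse(consent, "enrolled", "declined")
      }
      out_rows[[si]] <- seg
    }
  })
  trace <- do.call(rbind, out_rows[!vapply(out_rows, is.null, logical(1))])
  if (is.null(trace)) trace <- v[0, ]
  rownames(trace) <- NULL
  thresholds <- do.call(rbind, lapply(names(states), function(b) {
    h <- states[[b]]$history; h$block_key <- b; h
  }))
  structure(list(trace = trace, thresholds = thresholds, states = states,
                 enrolled = names(status)[status == "enrolled"],
                 status = status),
            class = "enrollment_trace")
}

#' @export
print.enrollment_trace <- function(x, ...) {
  cat("Randomized enrollment trace\n")
  cat(sprintf("  visits processed: %d\n", nrow(x$trace)))
  cat(sprintf("  patients enrolled: %d\n", length(x$enrolled)))
  cat(sprintf("  threshold adjustments: %d\n",
              sum(x$thresholds$rationale != "planned")))
  invisible(x)
}

#' Replay and exchangeability check of a recruitment trace
#'
#' Two diagnostics of concealment-preserving randomization: (a) replay --
#' every recorded flag decision must equal
#' `is_flagged(letter, k in force)`, and every enrollment must have been
#' flagged, shown and consented; (b) exchangeability -- a permutation test
#' per covariate that flagged and unflagged patients differ in mean no more
#' than chance (p-values uniform when letters are independent of
#' covariates, as the design guarantees).
#'
#' @param trace an `enrollment_trace` (or its `trace` data.frame).
#' @param letters output of [assign_letters()].
#' @param patients optional patient table for the balance test.
#' @param covariates covariate columns to test; default: the standard
#'   continuous covariates present in `patients`.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return object of class `randomization_integrity`: `replay_mismatches`
#'   (data.frame of offending rows), `replay_pass`, `balance` (per-covariate
#'   observed mean difference and permutation p), `pass`.
#' @export
check_randomization_integrity <- function(trace, letters, patients = NULL,
                                          covariates = NULL, n_perm = 199,
                                          seed = NULL) {
  tr <- if (inherits(trace, "enrollment_trace")) trace$trace else trace
  if (nrow(tr) == 0L) stop("empty trace", call. = FALSE)
  lmap <- letters$letter[match(tr$patient_id, letters$patient_id)]
  if (anyNA(lmap)) stop("missing letters for traced patients", call. = FALSE)
  expected <- is_flagged(lmap, tr$k_in_force)
  bad_flag <- which(expected != tr$flagged)
  bad_enrol <- which(tr$enrolled & !(tr$flagged & tr$showed & tr$consented))
  mism <- tr[sort(unique(c(bad_flag, bad_enrol))), , drop = FALSE]

  balance <- NULL
  if (!is.null(patients)) {
    if (is.null(covariates)) {
      covariates <- intersect(
        c("age_at_baseline", "fev1pp", "weight_kg",
          "prior_year_exacerbations", "home_elevation_m"),
        names(patients))
    }
    first <- tr[!duplicated(tr$patient_id), c("patient_id", "flagged")]
    p <- patients[match(first$patient_id, patients$patient_id), ,
                  drop = FALSE]
    flag <- first$flagged
    balance <- do.call(rbind, lapply(covariates, function(cv) {
      x <- p[[cv]]
      res <- permutation_balance_test(x, flag, n_perm = n_perm, seed = seed)
      data.frame(covariate = cv, observed_diff = res$observed,
                 p_value = res$p_value, stringsAsFactors = FALSE)
    }))
  }
  structure(list(replay_mismatches = mism,
                 n_mismatches = nrow(mism),
                 replay_pass = nrow(mism) == 0L,
                 balance = balance,
                 pass = nrow(mism) == 0L &&
                   (is.null(balance) || all(balance$p_value > 0.001,
                                            na.rm = TRUE))),
            class = "randomization_integrity")
}

#' Permutation test of covariate balance between two groups
#'
#' Statistic: absolute difference in group means. The p-value
#' `(1 + #{|T_perm| >= |T_obs|}) / (n_perm + 1)` is uniform on a discrete
#' grid under exchangeability.
#'
#' @param x numeric covariate.
#' @param flag logical group label.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `observed` (mean difference) and `p_value`.
#' @export
permutation_balance_test <- function(x, flag, n_perm = 199, seed = NULL) {
  keep <- is.finite(x) & !is.na(flag)
  x <- x[keep]; flag <- flag[keep]
  n1 <- sum(flag); n0 <- sum(!flag)
  if (n1 == 0L || n0 == 0L) return(list(observed = NA_real_,
                                        p_value = NA_real_))
  obs <- mean(x[flag]) - mean(x[!flag])
  tot <- sum(x); n <- length(x)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      s1 <- sum(x[sample.int(n, n1)])
      s1 / n1 - (tot - s1) / n0
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
    list(observed = obs, p_value = p)
  })
}

#' @export
print.randomization_integrity <- function(x, ...) {
  cat("Randomization integrity check\n")
  cat(sprintf("  replay: %s (%d mismatching decisions)\n",
              if (x$replay_pass) "PASS" else "FAIL", x$n_mismatches))
  if (!is.null(x$balance)) {
    cat("  covariate balance (flagged vs unflagged), permutation p:\n")
    for (i in seq_len(nrow(x$balance))) {
      cat(sprintf("    %-26s diff = %8.3f  p = %.3f\n",
                  x$balance$covariate[i], x$balance$observed_diff[i],
                  x$balance$p_value[i]))
    }
  }
  invisible(x)
}
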