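test_that("letter assignment is uniform, independent and collision-tolerant", {
  expect_equal(nrow(assign_letters(tiny_population(0, 0))), 0L)

  p <- tiny_population(26000, 0, seed = 3)
  l <- assign_letters(p, seed = 5)
  expect_true(all(l$letter %in% 0:25))
  gof <- chisq.test(table(factor(l$letter, levels = 0:25)))
  expect_gt(gof$p.value, 0.001)

  # independence between the two blocks of one center
  cfg <- population_config(n_centers = 1, adult_pool = 5000,
                           pediatric_pool = 5000, seed = 7)
  p2 <- generate_population(cfg)
  l2 <- assign_letters(p2, seed = 9)
  la <- l2$letter[l2$block_key == "C01:adult"]
  lp <- l2$letter[l2$block_key == "C01:pediatric"]
  expect_lt(abs(cor(la, lp)), 3 / sqrt(5000))

  dup <- p[c(1, 1), ]
  expect_error(assign_letters(dup), "duplicate")
})

test_that("required_threshold returns the smallest adequate k", {
  # independent oracle: closed-form ceiling instead of the scan
  oracle <- function(N, target, c, s) {
    if (target == 0) return(0L)
    k <- ceiling(26 * target / (N * c * s))
    if (!is.finite(k) || k > 26) 26L else as.integer(k)
  }
  expect_identical(as.integer(required_threshold(100, 0, 0.5, 0.9)), 0L)
  expect_identical(as.integer(required_threshold(100, 20, 0.53, 0.90)), 11L)
  expect_identical(as.integer(required_threshold(100, 100, 1, 1)), 26L)
  set.seed(13)
  for (i in 1:50) {
    N <- sample(10:2000, 1); tg <- sample(0:300, 1)
    c <- runif(1, 0.05, 1); s <- runif(1, 0.05, 1)
    got <- suppressWarnings(required_threshold(N, tg, c, s))
    expect_identical(as.integer(got), oracle(N, tg, c, s))
  }
  expect_warning(required_threshold(10, 100, 0.5, 0.9), "insufficient")
  expect_error(required_threshold(100, 10, 0, 0.9), "infeasible")
})

test_that("flagging is the strict earlier-than rule", {
  expect_false(is_flagged(0, 0))      # 'A' with nothing flagged
  expect_true(is_flagged(2, 11))      # 'C' before threshold letter 'L'
  expect_false(is_flagged(11, 11))    # the threshold letter itself
  expect_true(all(is_flagged(0:25, 26)))
  expect_false(any(is_flagged(0:25, 0)))
  expect_error(is_flagged(26, 5), "letter")
  expect_error(is_flagged(3, 27), "threshold_index")
})

test_that("threshold adjustment recomputes k and obeys the speed rule", {
  st <- threshold_state("b", pool_size = 100, target_total = 20,
                        consent_rate = 0.53, show_rate = 0.90,
                        effective_from = as.Date("2015-01-01"))
  expect_identical(st$k, 11L)

  # nothing observed yet, rates unchanged: fixed point
  obs0 <- list(n_seen = 0, n_scheduled = 0, n_shown = 0, n_approached = 0,
               n_enrolled = 0, n_declined = 0)
  st0 <- adjust_threshold(st, obs0, as.Date("2015-02-01"))
  expect_identical(st0$k, 11L)
  expect_identical(st0$history$rationale[2], "on_target")

  # uniform-letter recompute: pool 80, remaining target 10, rates 0.5 x 0.6
  st1 <- threshold_state("b", pool_size = 100, target_total = 20,
                         consent_rate = 0.5, show_rate = 0.6,
                         effective_from = as.Date("2015-01-01"), k = 9L)
  obs1 <- list(n_seen = 40, n_scheduled = 100, n_shown = 60,
               n_approached = 20, n_enrolled = 10, n_declined = 10)
  st1 <- adjust_threshold(st1, obs1, as.Date("2015-02-01"),
                          shrink_weight = 0)
  expect_identical(st1$k, 11L)  # smallest k with (k/26)*80*0.30 >= 10
  expect_identical(st1$history$rationale[2], "speed_adjustment_later")

  # enrollment far ahead of pace: threshold moves strictly earlier
  st2 <- threshold_state("b", pool_size = 100, target_total = 20,
                         consent_rate = 0.53, show_rate = 0.90,
                         effective_from = as.Date("2015-01-01"))
  obs2 <- list(n_seen = 30, n_scheduled = 35, n_shown = 32,
               n_approached = 16, n_enrolled = 12, n_declined = 4)
  st2 <- adjust_threshold(st2, obs2, as.Date("2015-02-01"))
  expect_lt(st2$k, 11L)
  expect_identical(st2$history$rationale[2], "speed_adjustment_earlier")

  # letter-histogram projection: undecided mass above k forces k later
  st3 <- threshold_state("b", pool_size = 100, target_total = 20,
                         consent_rate = 1, show_rate = 1,
                         effective_from = as.Date("2015-01-01"), k = 5L)
  hist <- integer(26); hist[11:20] <- 8  # letter indices 10..19 (K..T) only
  obs3 <- list(n_seen = 100, n_scheduled = 100, n_shown = 100,
               n_approached = 10, n_enrolled = 10, n_declined = 0,
               n_undecided_by_letter = hist)
  st3 <- adjust_threshold(st3, obs3, as.Date("2015-02-01"),
                          shrink_weight = 0)
  # need 10 more at consent x show = 1; letters up to J hold nobody, so k
  # must reach 12 to cover undecided letters K and L (8 each -> 16 >= 10)
  expect_identical(st3$k, 12L)

  expect_error(adjust_threshold(st, obs0, as.Date("2014-06-01")), "review")
})

test_that("enrollment simulation matches its binomial expectation", {
  p <- tiny_population(1000, 0, seed = 21)
  p$eligible <- TRUE
  v <- generate_visits(p, 365, no_show_rate = 0.10, seed = 22)
  l <- assign_letters(p, seed = 23)

  # k = 0: nothing flagged, nobody enrolled
  st0 <- threshold_state("C01:adult", pool_size = 1000, target_total = 0,
                         k = 0L)
  tr0 <- simulate_enrollment(p, l, v, st0, consent_rate = 0.53, seed = 24)
  expect_length(tr0$enrolled, 0L)

  # saturation: all flagged, everyone shows, everyone consents
  v1 <- generate_visits(p, 365, no_show_rate = 0, seed = 25)
  st26 <- threshold_state("C01:adult", pool_size = 1000, target_total = 1000,
                          k = 26L)
  tr26 <- simulate_enrollment(p, l, v1, st26, consent_rate = 1, seed = 26)
  expect_setequal(tr26$enrolled, unique(v1$patient_id))
  first <- tr26$trace[!duplicated(tr26$trace$patient_id), ]
  expect_true(all(first$enrolled))

  # fixed k = 11: first-visit enrollments ~ Binomial(1000, (11/26)*0.9*0.53)
  st11 <- threshold_state("C01:adult", pool_size = 1000, target_total = 1000,
                          k = 11L)
  tr11 <- simulate_enrollment(p, l, v, st11, consent_rate = 0.53, seed = 27)
  first11 <- tr11$trace[!duplicated(tr11$trace$patient_id), ]
  pr <- (11 / 26) * 0.90 * 0.53
  expect_lt(abs(sum(first11$enrolled) - 1000 * pr),
            3 * sqrt(1000 * pr * (1 - pr)))

  # monotone in k under common random numbers
  ks <- c(0L, 5L, 11L, 20L, 26L)
  en <- vapply(ks, function(k) {
    st <- threshold_state("C01:adult", pool_size = 1000, target_total = 1000,
                          k = k)
    length(simulate_enrollment(p, l, v, st, consent_rate = 0.5,
                               seed = 30)$enrolled)
  }, integer(1))
  expect_true(all(diff(en) >= 0))

  # unknown patient in visits errors
  vbad <- v; vbad$patient_id[1] <- "ghost"
  expect_error(simulate_enrollment(p, l, vbad, st11), "unknown patient")
})

test_that("integrity check replays decisions and detects tampering", {
  p <- tiny_population(300, 0, seed = 31)
  v <- generate_visits(p, 365, seed = 32)
  l <- assign_letters(p, seed = 33)
  st <- threshold_state("C01:adult", pool_size = sum(p$eligible),
                        target_total = 40)
  tr <- simulate_enrollment(p, l, v, st,
                            reviews = review_dates(as.Date("2014-12-08"), 365),
                            consent_rate = 0.53, seed = 34)
  chk <- check_randomization_integrity(tr, l, p, seed = 35)
  expect_true(chk$replay_pass)
  expect_identical(chk$n_mismatches, 0L)
  expect_true(all(chk$balance$p_value > 0.001))

  # adversarially flip one flag decision: exactly one mismatch
  tampered <- tr$trace
  tampered$flagged[5] <- !tampered$flagged[5]
  chk2 <- check_randomization_integrity(tampered, l, seed = 36)
  expect_identical(chk2$n_mismatches, 1L)
  expect_false(chk2$replay_pass)

  expect_error(check_randomization_integrity(tr, l[-1, ], p),
               "missing letters")
})

test_that("empirical flagged fraction follows k/26", {
  p <- tiny_population(10000, 0, seed = 41)
  l <- assign_letters(p, seed = 42)
  for (k in c(5L, 20L)) {
    frac <- mean(is_flagged(l$letter, k))
    pr <- k / 26
    expect_lt(abs(frac - pr), 3 * sqrt(pr * (1 - pr) / 10000))
  }
})
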