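# Timepoint metrics, event detection, threshold selection, FP taxonomy,
# cohort aggregation and cross-validation planning.

test_that("timepoint metrics match hand-computed confusion values", {
  m <- timepoint_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_equal(m$f1_pos, 2 / 3)
  expect_equal(m$f1_neg, 0.8)
  expect_equal(m$macro_f1, (2 / 3 + 0.8) / 2)
  expect_equal(m$weighted_f1, m$macro_f1)   # equal support
  perf <- timepoint_metrics(c(1, 0, 1), c(0.9, 0.1, 0.8))
  for (f in c("sensitivity", "specificity", "precision", "macro_f1",
              "weighted_f1")) {
    expect_equal(perf[[f]], 1)
  }
  expect_error(timepoint_metrics(c(1, 0), c(1)), "equal length")
})

test_that("timepoint metrics agree with a textbook oracle on random data", {
  set.seed(51)
  for (i in 1:8) {
    y <- stats::rbinom(1000, 1, stats::runif(1, 0.2, 0.8))
    p <- stats::runif(1000)
    got <- timepoint_metrics(y, p)
    want <- oracle_metrics(y, as.integer(p >= 0.5))
    for (f in names(want)) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
    }
  }
})

test_that("event detection applies the 25% rule per event", {
  # 8 grid points inside the event, 2 positive: fraction exactly 0.25
  probs <- list(end_times_s = seq(0, 9.5, by = 0.5),
                prob = rep(0, 20))
  probs$prob[c(5, 8)] <- 0.9
  ev <- fog_events(2, 6)                    # grid times 2.0 .. 5.5 inside
  det <- event_detection(ev, probs)
  expect_identical(det$per_event$n_grid, 8L)
  expect_equal(det$per_event$pos_frac, 0.25)
  expect_true(det$per_event$detected)
  expect_identical(det$n_detected, 1L)
  # zero positives: neither detected nor any-positive
  det0 <- event_detection(ev, list(end_times_s = probs$end_times_s,
                                   prob = rep(0, 20)))
  expect_false(det0$per_event$detected)
  expect_identical(det0$n_any_positive, 0L)
  # an event spanning no grid point is flagged and excluded
  tiny <- event_detection(fog_events(2.1, 2.3), probs)
  expect_identical(tiny$n_no_grid, 1L)
  expect_identical(tiny$n_events, 0L)
})

test_that("event detection matches brute force over all 2^6 patterns", {
  ev <- fog_events(1, 4)                    # grid 1.0 .. 3.5: 6 points
  times <- seq(0, 5.5, by = 0.5)
  for (mask in 0:63) {
    bits <- as.integer(intToBits(mask))[1:6]
    prob <- rep(0, length(times))
    prob[times >= 1 & times < 4] <- bits * 0.9
    det <- event_detection(ev, list(end_times_s = times, prob = prob))
    expect_identical(det$per_event$detected, sum(bits) / 6 >= 0.25,
                     label = paste("mask", mask))
    expect_identical(det$per_event$any_positive, sum(bits) > 0)
  }
})

test_that("raising the probability threshold never detects more events", {
  set.seed(52)
  times <- seq(0, 59.5, by = 0.5)
  prob <- stats::runif(length(times))
  ev <- fog_events(c(5, 20, 40), c(12, 28, 50))
  det <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    event_detection(ev, list(end_times_s = times, prob = prob),
                    prob_thresh = th)$n_detected, integer(1))
  expect_true(all(diff(det) <= 0))
})

test_that("Youden-constrained fraction selection matches enumeration", {
  times <- seq(0, 39.5, by = 0.5)
  ev <- fog_events(c(5, 25), c(15, 32))
  set.seed(53)
  prob <- as.numeric(times >= 5 & times < 12) +
    0.3 * (times >= 34)                         # partial hit + late FPs
  prob[times >= 34] <- 0.9                      # contaminate the last gap
  sel <- select_event_threshold(ev, list(end_times_s = times, prob = prob),
                                candidate_fracs = c(0.25, 0.5, 0.75))
  # brute force over candidates
  pos <- prob >= 0.5
  evfrac <- vapply(seq_len(2), function(k) {
    ii <- which(times >= ev$start_s[k] & times < ev$end_s[k])
    mean(pos[ii])
  }, numeric(1))
  bounds <- c(-Inf, 5, 15, 25, 32, Inf)
  gapfrac <- vapply(1:3, function(k) {
    ii <- which(times >= bounds[2 * k - 1] & times < bounds[2 * k])
    mean(pos[ii])
  }, numeric(1))
  best <- NULL
  for (fr in c(0.25, 0.5, 0.75)) {
    sens <- mean(evfrac >= fr)
    spec <- mean(gapfrac < fr)
    if (spec >= 0.5 &&
        (is.null(best) || sens + spec - 1 > best$y + 1e-12)) {
      best <- list(fr = fr, y = sens + spec - 1)
    }
  }
  expect_equal(sel$frac, best$fr)
  # a perfect classifier ties all candidates; the smallest is returned
  perfect <- as.numeric(times >= 5 & times < 15 | times >= 25 & times < 32)
  sel2 <- select_event_threshold(ev, list(end_times_s = times, prob = perfect),
                                 candidate_fracs = c(0.25, 0.5, 0.75))
  expect_equal(sel2$frac, 0.25)
  # all-positive predictions fail the specificity floor
  expect_error(select_event_threshold(
    ev, list(end_times_s = times, prob = rep(1, length(times)))),
    "specificity")
})

test_that("false positives split into early-onset, overextension, isolated", {
  times <- seq(0, 29.5, by = 0.5)
  ev <- fog_events(10, 15)
  y_true <- as.integer(times >= 10 & times < 15)
  y_hat <- integer(length(times))
  y_hat[times >= 8.5 & times < 12] <- 1L       # run through the onset
  y_hat[times >= 14 & times < 16] <- 1L        # run through the offset
  y_hat[times == 25] <- 1L                     # lone FP far away
  tax <- fp_taxonomy(y_true, y_hat, times, ev)
  expect_identical(unname(tax$counts["early_onset"]), 3L)   # 8.5, 9.0, 9.5
  expect_identical(unname(tax$counts["overextension"]), 2L) # 15.0, 15.5
  expect_identical(unname(tax$counts["isolated"]), 1L)
  # a pre-onset run that stops before the event is NOT early-onset
  y_hat2 <- integer(length(times))
  y_hat2[times >= 8.5 & times < 9.5] <- 1L
  tax2 <- fp_taxonomy(y_true, y_hat2, times, ev)
  expect_identical(unname(tax2$counts["early_onset"]), 0L)
  expect_identical(unname(tax2$counts["isolated"]), 2L)
})

test_that("cohort aggregation reproduces the published summary row", {
  rows <- published_trial_rows()
  rep <- aggregate_report(rows)
  s <- rep$summary
  expect_equal(s$total_test_duration_s, 447)
  expect_identical(s$total_freezes, 30)
  expect_equal(s$total_freeze_duration_s, 169.2)
  expect_equal(round(s$pct_frozen), 38)
  expect_equal(round(s$mean_sensitivity, 3), 0.593)
  expect_equal(round(s$mean_specificity, 3), 0.689)
  # the published means (0.666, 0.624) were computed from unrounded
  # per-trial values; the printed rows reproduce them to half a unit in
  # the last printed digit
  expect_equal(s$mean_weighted_f1, 0.666, tolerance = 1e-3)
  expect_equal(s$mean_macro_f1, 0.624, tolerance = 2e-3)
  one <- aggregate_report(rows[1, , drop = FALSE])
  expect_equal(one$summary$mean_weighted_f1, rows$weighted_f1[1])
  expect_equal(one$summary$pct_frozen,
               100 * rows$freeze_duration_s[1] / rows$test_duration_s[1])
})

test_that("cross-validation plans compose training sets by the stated rule", {
  fs <- 250
  mk_trial <- function(participant, module, events, dur = 60, seed = 1) {
    set.seed(seed)
    list(values = matrix(stats::rnorm(dur * fs * 2), dur * fs, 2,
                         dimnames = list(NULL, c("a", "b"))),
         participant = participant, module = module, events = events)
  }
  ev_both <- fog_events(c(20, 45), c(28, 52))    # freeze in both partitions
  ev_early <- fog_events(15, 20)                 # only in the tuning span
  trials <- list(
    P1_phys = mk_trial("P1", "physical", ev_both, seed = 1),
    P1_cog  = mk_trial("P1", "cognitive", ev_both, seed = 2),
    P2_phys = mk_trial("P2", "physical", ev_both, seed = 3),
    P2_cog  = mk_trial("P2", "cognitive", ev_early, seed = 4))
  cf <- manual_cohort_features(trials, fs = fs)
  lp <- plan_lotocv(cf)
  p <- lp$plans$P2_phys
  expect_true(p$eligible)
  expect_setequal(p$training_trials, c("P2_cog", "P1_phys"))
  # all freezes inside the first 40 s make a trial ineligible
  expect_false(lp$plans$P2_cog$eligible)
  expect_match(lp$plans$P2_cog$reason, "testing span")
  # truncation precedes partitioning: spans are truncated around events
  expect_equal(lp$prepared$P1_phys$offset_s, 10)
})
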