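# Timepoint- and event-level evaluation of FOG probability series.

#' Timepoint classification metrics on the 0.5 s prediction grid
#'
#' Strictly aligned comparison of predicted and true FOG state per grid
#' point: confusion counts, sensitivity (recall of the FOG class),
#' specificity, precision, per-class F1, macro F1 (unweighted mean of the
#' two class F1s) and weighted F1 (support-weighted mean).
#'
#' @param y_true Integer 0/1 true labels.
#' @param y_prob Predicted probabilities (or hard 0/1 labels).
#' @param threshold Probability threshold, default 0.5 (predictions at or
#'   above it are FOG).
#' @return A list of metrics; degenerate ratios (0/0) are reported as 0.
#' @export
timepoint_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) {
    stop("y_true and y_prob must have equal length", call. = FALSE)
  }
  y_hat <- as.integer(y_prob >= threshold)
  tp <- sum(y_true == 1 & y_hat == 1)
  tn <- sum(y_true == 0 & y_hat == 0)
  fp <- sum(y_true == 0 & y_hat == 1)
  fn <- sum(y_true == 1 & y_hat == 0)
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  prec <- sdiv(tp, tp + fp)
  npv <- sdiv(tn, tn + fn)
  f1_pos <- sdiv(2 * prec * sens, prec + sens)
  f1_neg <- sdiv(2 * npv * spec, npv + spec)
  n1 <- tp + fn
  n0 <- tn + fp
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       sensitivity = sens, specificity = spec, precision = prec,
       recall = sens, f1_pos = f1_pos, f1_neg = f1_neg,
       macro_f1 = (f1_pos + f1_neg) / 2,
       weighted_f1 = sdiv(n1 * f1_pos + n0 * f1_neg, n1 + n0))
}

# Grid points belonging to an event: end time in [start, end).
.event_grid_idx <- function(times, start_s, end_s) {
  which(times >= start_s & times < end_s)
}

#' Event-level FOG detection
#'
#' A FOG event is detected when at least `frac` of the prediction-grid
#' probabilities falling inside it (grid time in `[start, end)`) are at or
#' above `prob_thresh`. Events containing no grid point are flagged and
#' excluded from the detection denominator. The looser any-positive count
#' is also reported.
#'
#' @param events A `fog_events` table (times on the same clock as `probs`).
#' @param probs A `fog_probs` series (or list with `end_times_s`, `prob`).
#' @param prob_thresh Probability threshold, default 0.5.
#' @param frac Minimum positive fraction per event, default 0.25.
#' @return A list with `per_event` (data.frame), `n_events`, `n_detected`,
#'   `n_any_positive`, `n_no_grid`.
#' @export
event_detection <- function(events, probs, prob_thresh = 0.5, frac = 0.25) {
  per <- lapply(seq_len(nrow(events)), function(k) {
    idx <- .event_grid_idx(probs$end_times_s, events$start_s[k],
                           events$end_s[k])
    if (length(idx) == 0) {
      return(data.frame(event = k, n_grid = 0L, n_pos = 0L,
                        pos_frac = NA_real_, detected = NA,
                        any_positive = NA))
    }
    npos <- sum(probs$prob[idx] >= prob_thresh)
    data.frame(event = k, n_grid = length(idx), n_pos = npos,
               pos_frac = npos / length(idx),
               detected = npos / length(idx) >= frac,
               any_positive = npos > 0)
  })
  per <- do.call(rbind, per)
  usable <- per[!is.na(per$detected), , drop = FALSE]
  list(per_event = per,
       n_events = nrow(usable),
       n_detected = sum(usable$detected),
       n_any_positive = sum(usable$any_positive),
       n_no_grid = sum(is.na(per$detected)))
}

#' Select the event-detection fraction by constrained Youden maximization
#'
#' Event-level sensitivity at a candidate fraction is the share of FOG
#' events detected under that fraction; event-level specificity is the
#' share of non-FOG gap intervals (the spans between consecutive freezes,
#' and before the first / after the last, restricted to the grid) that are
#' NOT falsely detected under the same rule. Among candidates with
#' specificity at or above `min_specificity`, the Youden index
#' (sensitivity + specificity - 1) is maximized; ties go to the smaller
#' fraction.
#'
#' @param events A `fog_events` table.
#' @param probs A `fog_probs` series.
#' @param candidate_fracs Candidate fractions, default `seq(0.05, 0.95,
#'   0.05)`.
#' @param prob_thresh Probability threshold, default 0.5.
#' @param min_specificity Specificity floor, default 0.5.
#' @return A list with `frac` (selected), and a `table` of candidate
#'   sensitivities, specificities and Youden indices.
#' @export
select_event_threshold <- function(events, probs,
                                   candidate_fracs = seq(0.05, 0.95, 0.05),
                                   prob_thresh = 0.5, min_specificity = 0.5) {
  times <- probs$end_times_s
  pos <- probs$prob >= prob_thresh
  ev_idx <- lapply(seq_len(nrow(events)), function(k)
    .event_grid_idx(times, events$start_s[k], events$end_s[k]))
  ev_idx <- ev_idx[vapply(ev_idx, length, integer(1)) > 0]
  bounds <- c(-Inf, as.vector(rbind(events$start_s, events$end_s)), Inf)
  gap_idx <- lapply(seq_len(nrow(events) + 1), function(k) {
    which(times >= bounds[2 * k - 1] & times < bounds[2 * k])
  })
  gap_idx <- gap_idx[vapply(gap_idx, length, integer(1)) > 0]
  if (length(ev_idx) == 0 || length(gap_idx) == 0) {
    stop("need at least one FOG event and one non-FOG gap on the grid",
         call. = FALSE)
  }
  rows <- lapply(candidate_fracs, function(fr) {
    sens <- mean(vapply(ev_idx, function(ii) mean(pos[ii]) >= fr, logical(1)))
    spec <- mean(vapply(gap_idx, function(ii) mean(pos[ii]) < fr, logical(1)))
    data.frame(frac = fr, sensitivity = sens, specificity = spec,
               youden = sens + spec - 1)
  })
  tab <- do.call(rbind, rows)
  ok <- tab[tab$specificity >= min_specificity, , drop = FALSE]
  if (nrow(ok) == 0) {
    best <- tab[which.max(tab$specificity), ]
    stop("no candidate fraction reaches specificity ",
         min_specificity, "; best available: frac=", best$frac,
         " specificity=", round(best$specificity, 3), call. = FALSE)
  }
  sel <- ok[order(-ok$youden, ok$frac), ][1, ]
  list(frac = sel$frac, table = tab)
}

#' Classify false-positive grid predictions relative to FOG events
#'
#' Each false-positive grid point is labelled `early_onset` when it lies
#' within `margin_s` seconds before an event's start and belongs to an
#' unbroken run of positive classifications continuing through the onset
#' (into the event); `overextension` when it lies within `margin_s` after
#' an event's end and its positive run is contiguous with positive
#' predictions inside that event; otherwise `isolated`.
#'
#' @param y_true True 0/1 labels on the grid.
#' @param y_hat Predicted 0/1 labels on the grid.
#' @param times Grid times (seconds).
#' @param events The event table on the same clock.
#' @param margin_s Temporal margin, default 2 s.
#' @return A list with `counts` (named early_onset / overextension /
#'   isolated), `n_fp` and the per-point classification.
#' @export
fp_taxonomy <- function(y_true, y_hat, times, events, margin_s = 2) {
  stopifnot(length(y_true) == length(y_hat), length(times) == length(y_hat))
  run_id <- cumsum(c(1L, diff(y_hat) != 0))
  fp <- which(y_hat == 1 & y_true == 0)
  kind <- rep("isolated", length(fp))
  for (i in seq_along(fp)) {
    g <- fp[i]
    run <- which(run_id == run_id[g])          # unbroken positive run
    for (k in seq_len(nrow(events))) {
      s <- events$start_s[k]; e <- events$end_s[k]
      if (times[g] >= s - margin_s && times[g] < s) {
        # positive run must cover every grid point from g through onset
        first_in <- which(times >= s)[1]
        if (!is.na(first_in) && first_in %in% run &&
            all(seq(g, first_in) %in% run)) {
          kind[i] <- "early_onset"
          break
        }
      }
      if (times[g] >= e && times[g] < e + margin_s) {
        in_ev <- .event_grid_idx(times, s, e)
        last_in <- if (length(in_ev) > 0) in_ev[length(in_ev)] else NA
        if (!is.na(last_in) && last_in %in% run &&
            all(seq(last_in, g) %in% run)) {
          kind[i] <- "overextension"
          break
        }
      }
    }
  }
  counts <- c(early_onset = sum(kind == "early_onset"),
              overextension = sum(kind == "overextension"),
              isolated = sum(kind == "isolated"))
  list(counts = counts, n_fp = length(fp),
       per_point = data.frame(idx = fp, time_s = times[fp], kind = kind))
}

#' Aggregate per-trial evaluations into a cohort report
#'
#' Sums durations and event counts, takes unweighted means of the F1
#' scores, sensitivity and specificity across trials, and recomputes the
#' global frozen fraction as total freeze time over total test time.
#'
#' @param trial_evals A list of per-trial evaluation rows (as produced by
#'   [evaluate_trial()]), or a data.frame of them.
#' @return A list of class `fog_cohort_report` with `per_trial` and
#'   `summary`.
#' @export
aggregate_report <- function(trial_evals) {
  df <- if (is.data.frame(trial_evals)) trial_evals
        else do.call(rbind, lapply(trial_evals, as.data.frame))
  stopifnot(nrow(df) >= 1)
  summary <- list(
    n_trials = nrow(df),
    total_test_duration_s = sum(df$test_duration_s),
    total_freezes = sum(df$n_freezes),
    total_freeze_duration_s = sum(df$freeze_duration_s),
    pct_frozen = 100 * sum(df$freeze_duration_s) / sum(df$test_duration_s),
    mean_weighted_f1 = mean(df$weighted_f1),
    mean_macro_f1 = mean(df$macro_f1),
    mean_sensitivity = mean(df$sensitivity),
    mean_specificity = mean(df$specificity),
    total_detected = if ("n_detected" %in% names(df)) sum(df$n_detected)
                     else NA_integer_,
    total_any_positive = if ("n_any_positive" %in% names(df))
                           sum(df$n_any_positive) else NA_integer_
  )
  structure(list(per_trial = df, summary = summary),
            class = "fog_cohort_report")
}

#' @export
print.fog_cohort_report <- function(x, ...) {
  s <- x$summary
  cat("Cohort report over", s$n_trials, "trials:\n")
  cat(sprintf("  total test %.1f s, %d freezes (%.1f s, %.0f%% frozen)\n",
              s$total_test_duration_s, s$total_freezes,
              s$total_freeze_duration_s, s$pct_frozen))
  cat(sprintf("  mean weighted F1 %.3f | macro F1 %.3f | sens %.3f | spec %.3f\n",
              s$mean_weighted_f1, s$mean_macro_f1, s$mean_sensitivity,
              s$mean_specificity))
  if (!is.na(s$total_detected)) {
    cat(sprintf("  events detected (25%%/0.5 rule): %d / %d\n",
                s$total_detected, s$total_freezes))
  }
  invisible(x)
}
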