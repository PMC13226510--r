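# Leave-one-trial-out cross-validation with per-trial transfer learning.

# Truncate one trial's features around its events and build its labelled
# timeline on the truncated clock.
.prep_trial <- function(fm, events, fs) {
  timeline <- label_timepoints(events, nrow(fm$values), fs)
  tr <- truncate_trial(fm, timeline, events)
  ev_rel <- events
  ev_rel$start_s <- ev_rel$start_s - tr$offset_s
  ev_rel$end_s <- ev_rel$end_s - tr$offset_s
  list(features = tr$features, timeline = tr$timeline,
       offset_s = tr$offset_s, events = ev_rel,
       participant_id = fm$participant_id, module = fm$module,
       duration_s = nrow(tr$features$values) / fs)
}

#' Plan leave-one-trial-out cross-validation
#'
#' One plan per trial. The held-out trial is partitioned into a tuning set
#' (its first `tuning_s` seconds after truncation) and a testing set (the
#' remainder); the training set is every other trial of the same
#' participant plus every other participant's trial of the same module.
#' A plan is eligible only if at least one freeze falls in each partition
#' after processing and truncation.
#'
#' @param cf A [featurize_cohort()] result.
#' @param tuning_s Tuning-span length in seconds, default 40.
#' @return A list of class `fog_lotocv_plan`: `prepared` (truncated trials)
#'   and `plans` (per-trial fold descriptions with eligibility flags).
#' @export
plan_lotocv <- function(cf, tuning_s = 40) {
  stopifnot(inherits(cf, "fog_cohort_features"))
  fs <- cf$fs_hz
  prepared <- lapply(names(cf$features), function(nm)
    .prep_trial(cf$features[[nm]], cf$events[[nm]], fs))
  names(prepared) <- names(cf$features)
  meta <- data.frame(
    trial = names(prepared),
    participant = vapply(prepared, `[[`, "", "participant_id"),
    module = vapply(prepared, `[[`, "", "module"),
    stringsAsFactors = FALSE)
  plans <- lapply(names(prepared), function(nm) {
    pr <- prepared[[nm]]
    n <- length(pr$timeline)
    tun_end <- min(n, round(tuning_s * fs))
    has_tune_fog <- any(pr$timeline[seq_len(tun_end)] == 1)
    has_test_fog <- tun_end < n && any(pr$timeline[(tun_end + 1):n] == 1)
    reason <- NULL
    if (!has_tune_fog) reason <- c(reason, "no freeze in tuning span")
    if (!has_test_fog) reason <- c(reason, "no freeze in testing span")
    training <- meta$trial[
      (meta$participant == pr$participant_id & meta$trial != nm) |
        (meta$participant != pr$participant_id & meta$module == pr$module)]
    list(held_out = nm, participant = pr$participant_id,
         module = pr$module, tuning_s = tuning_s,
         training_trials = training,
         eligible = has_tune_fog && has_test_fog,
         reason = if (is.null(reason)) NA_character_
                  else paste(reason, collapse = "; "))
  })
  names(plans) <- names(prepared)
  structure(list(prepared = prepared, plans = plans, fs_hz = fs),
            class = "fog_lotocv_plan")
}

# Training-grid windows for one prepared trial (whole truncated span).
.trial_training_windows <- function(pr) {
  build_windows(pr$features, pr$timeline, "training")
}

# Model-side feature conditioning. Band-power features (skewed, positive,
# spanning orders of magnitude) are mapped to the log-power scale; every
# feature is then standardized with statistics pooled over the fold's
# training trials only, so the held-out trial never informs the scaling.
.log_power_columns <- function(prepared) {
  lapply(prepared, function(pr) {
    pw <- grepl("\\|pow\\|", colnames(pr$features$values))
    if (any(pw)) {
      pr$features$values[, pw] <- log10(pr$features$values[, pw] + 1e-8)
    }
    pr
  })
}

.standardize_fold <- function(prepared, train_trials, use_trials) {
  pooled <- do.call(rbind, lapply(prepared[train_trials],
                                  function(pr) pr$features$values))
  mu <- colMeans(pooled)
  sd <- apply(pooled, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  out <- prepared[use_trials]
  for (nm in use_trials) {
    out[[nm]]$features$values <-
      sweep(sweep(out[[nm]]$features$values, 2, mu), 2, sd, `/`)
  }
  out
}

#' Evaluate one held-out trial with a given model
#'
#' Predicts the test-span probability series on the 0.5 s grid and
#' computes the per-trial metrics: timepoint confusion metrics at the 0.5
#' probability threshold, event-level detection under the 25%/0.5 rule,
#' and the false-positive taxonomy.
#'
#' @param plan One fold plan from [plan_lotocv()].
#' @param model A trained (normally transfer-tuned) `fog_model`.
#' @param prepared The `prepared` list from the same [plan_lotocv()] call.
#' @param prob_thresh Probability threshold, default 0.5.
#' @param detect_frac Event-detection fraction, default 0.25.
#' @return A list with `row` (per-trial summary fields), `probs`, the
#'   `detection` result and the `taxonomy`.
#' @export
evaluate_trial <- function(plan, model, prepared, prob_thresh = 0.5,
                           detect_frac = 0.25) {
  pr <- prepared[[plan$held_out]]
  fs <- pr$features$fs_hz
  test_ws <- build_windows(pr$features, pr$timeline, "prediction",
                           span_start_s = plan$tuning_s)
  probs <- predict_series(model, test_ws)
  test_start <- plan$tuning_s
  test_end <- length(pr$timeline) / fs
  ev <- pr$events
  overlap <- pmin(ev$end_s, test_end) - pmax(ev$start_s, test_start)
  test_events <- ev[overlap > 0, , drop = FALSE]
  class(test_events) <- class(ev)
  tm <- timepoint_metrics(probs$labels, probs$prob, prob_thresh)
  det <- event_detection(test_events, probs, prob_thresh, detect_frac)
  tax <- fp_taxonomy(probs$labels,
                     as.integer(probs$prob >= prob_thresh),
                     probs$end_times_s, test_events)
  test_duration <- test_end - test_start
  freeze_duration <- sum(pmax(0, overlap))
  row <- list(trial = plan$held_out, participant = plan$participant,
              module = plan$module,
              test_duration_s = test_duration,
              n_freezes = nrow(test_events),
              freeze_duration_s = freeze_duration,
              pct_frozen = 100 * freeze_duration / test_duration,
              weighted_f1 = tm$weighted_f1, macro_f1 = tm$macro_f1,
              sensitivity = tm$sensitivity, specificity = tm$specificity,
              precision = tm$precision,
              n_detected = det$n_detected,
              n_any_positive = det$n_any_positive,
              fp_early = unname(tax$counts["early_onset"]),
              fp_overext = unname(tax$counts["overextension"]),
              fp_isolated = unname(tax$counts["isolated"]))
  list(row = row, probs = probs, detection = det, taxonomy = tax,
       timepoint = tm)
}

#' Run the full cross-validated transfer-learning experiment
#'
#' For every eligible fold: trains a base model on the fold's training
#' trials, transfer-tunes it on the jitter-augmented windows of the
#' held-out trial's opening segment, predicts the test span with both
#' models and evaluates them. Deterministic under `seed`.
#'
#' @param cf A [featurize_cohort()] result.
#' @param seed Integer seed driving model initialization, training and
#'   augmentation.
#' @param spec_args Named list of overrides for [model_spec()].
#' @param train_cfg,tune_cfg Training configurations; seeds inside are
#'   derived from `seed`.
#' @param tuning_s Tuning-span seconds, default 40.
#' @param max_folds Optional cap on the number of eligible folds run.
#' @param folds Optional character vector of held-out trial names to run
#'   (subset of the eligible folds).
#' @param log_power,standardize Model-side feature conditioning: map
#'   band-power features to log power, then standardize every feature with
#'   statistics pooled over the fold's training trials.
#' @return A list of class `fog_lotocv_result`: `report` (tuned cohort
#'   report), `report_base`, `folds` (per-fold details) and `plan`.
#' @export
run_lotocv <- function(cf, seed = 1L, spec_args = list(),
                       train_cfg = NULL, tune_cfg = NULL, tuning_s = 40,
                       max_folds = NULL, folds = NULL, log_power = TRUE,
                       standardize = TRUE) {
  lp <- plan_lotocv(cf, tuning_s = tuning_s)
  eligible <- Filter(function(p) p$eligible, lp$plans)
  if (length(eligible) == 0) stop("no eligible folds", call. = FALSE)
  if (!is.null(folds)) {
    eligible <- eligible[names(eligible) %in% folds]
    if (length(eligible) == 0) stop("no eligible folds selected",
                                    call. = FALSE)
  }
  if (!is.null(max_folds)) eligible <- eligible[seq_len(min(max_folds,
                                                            length(eligible)))]
  scaled <- if (log_power) .log_power_columns(lp$prepared) else lp$prepared
  n_feat <- ncol(lp$prepared[[1]]$features$values)
  if (is.null(train_cfg)) train_cfg <- train_config(seed = seed)
  if (is.null(tune_cfg)) tune_cfg <- tune_config(seed = seed + 1L)
  folds <- list()
  rows_tuned <- list()
  rows_base <- list()
  for (k in seq_along(eligible)) {
    plan <- eligible[[k]]
    fold_prep <- if (standardize) {
      .standardize_fold(scaled, plan$training_trials,
                        c(plan$training_trials, plan$held_out))
    } else {
      scaled[c(plan$training_trials, plan$held_out)]
    }
    train_ws <- concat_windows(lapply(fold_prep[plan$training_trials],
                                      .trial_training_windows))
    sp <- do.call(model_spec,
                  c(list(n_features = n_feat,
                         seed = .trial_seed(seed, k, 1L)), spec_args))
    base_fit <- train_base(build_model(sp), train_ws, train_cfg)
    pr <- fold_prep[[plan$held_out]]
    tune_raw <- build_windows(pr$features, pr$timeline, "training",
                              span_start_s = 0, span_end_s = plan$tuning_s)
    # hold out the tail of the raw tuning span as the early-stopping
    # monitor; augment only the remainder
    n_tune <- n_windows(tune_raw)
    n_val <- min(n_tune - 2L, max(4L, floor(0.15 * n_tune)))
    tune_val <- .subset_windows(tune_raw, (n_tune - n_val + 1L):n_tune)
    tune_train <- .subset_windows(tune_raw, seq_len(n_tune - n_val))
    tune_ws <- augment_jitter(tune_train, seed = .trial_seed(seed, k, 2L))
    tuned_fit <- transfer_tune(base_fit$model, tune_ws, tune_cfg,
                               val_ws = tune_val)
    ev_tuned <- evaluate_trial(plan, tuned_fit$model, fold_prep)
    ev_base <- evaluate_trial(plan, base_fit$model, fold_prep)
    rows_tuned[[plan$held_out]] <- ev_tuned$row
    rows_base[[plan$held_out]] <- ev_base$row
    folds[[plan$held_out]] <- list(
      plan = plan, tuned = ev_tuned, base = ev_base,
      base_history = base_fit$history, tune_history = tuned_fit$history,
      train_label_balance = mean(train_ws$labels),
      tuning_end_times_s = range(tune_raw$end_times_s),
      test_grid_range_s = range(ev_tuned$probs$end_times_s))
  }
  structure(list(report = aggregate_report(rows_tuned),
                 report_base = aggregate_report(rows_base),
                 folds = folds, plan = lp, seed = seed),
            class = "fog_lotocv_result")
}

#' @export
print.fog_lotocv_result <- function(x, ...) {
  cat("LOTOCV with transfer learning over", length(x$folds),
      "eligible folds (seed", x$seed, ")\n")
  cat(sprintf("  tuned: weighted F1 %.3f | base: weighted F1 %.3f\n",
              x$report$summary$mean_weighted_f1,
              x$report_base$summary$mean_weighted_f1))
  print(x$report)
  invisible(x)
}
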