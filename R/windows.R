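# Windowed labelling: per-timepoint FOG labels, trial truncation, 3 s / 0.5 s
# window grids, class weights and jitter augmentation.
#
# Time convention: sample i (1-based) sits at t = (i-1)/fs; event intervals
# are half-open [start, end). A training-grid window "ending at" time t
# covers [t - 3, t) and is labelled by its final sample (the one just before
# t); a prediction-grid window at time g classifies the sample at g, using
# the 3 s of data up to and including it.

#' Per-timepoint binary FOG labels
#'
#' @param events A [fog_events()] table.
#' @param n_samples Number of samples in the trial.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of 0/1 labels, one per sample; sample i is 1 iff
#'   `(i-1)/fs` lies in some event's `[start, end)`.
#' @export
label_timepoints <- function(events, n_samples, fs) {
  tt <- (seq_len(n_samples) - 1) / fs
  lab <- integer(n_samples)
  for (k in seq_len(nrow(events))) {
    lab[tt >= events$start_s[k] & tt < events$end_s[k]] <- 1L
  }
  lab
}

#' Truncate a trial around its FOG events
#'
#' Keeps at most `pad_s` seconds of non-freeze data before the first freeze
#' and after the final freeze (to mitigate class imbalance); trials without
#' events are returned unchanged and flagged. No FOG-labelled sample is
#' ever removed.
#'
#' @param features A `fog_features` object (or plain matrix).
#' @param timeline Per-sample labels from [label_timepoints()].
#' @param events The trial's event table.
#' @param pad_s Seconds of non-freeze context kept on each side, default 10.
#' @return A list with `features`, `timeline` (both sliced consistently),
#'   `offset_s` (seconds removed from the start) and `truncated` flag.
#' @export
truncate_trial <- function(features, timeline, events, pad_s = 10) {
  values <- if (inherits(features, "fog_features")) features$values
            else features
  fs <- if (inherits(features, "fog_features")) features$fs_hz
        else stop("supply a fog_features object", call. = FALSE)
  n <- nrow(values)
  if (nrow(events) == 0) {
    return(list(features = features, timeline = timeline, offset_s = 0,
                truncated = FALSE))
  }
  start_s <- max(0, min(events$start_s) - pad_s)
  end_s <- min(n / fs, max(events$end_s) + pad_s)
  i0 <- floor(start_s * fs) + 1L
  i1 <- min(n, ceiling(end_s * fs))
  features$values <- values[i0:i1, , drop = FALSE]
  list(features = features, timeline = timeline[i0:i1],
       offset_s = (i0 - 1) / fs, truncated = TRUE)
}

#' Build the 3 s / 0.5 s window grid over a feature matrix
#'
#' Training mode places window end points at every 0.5 s from 3 s after the
#' span start through the span end, so every window has a full 3 s history
#' inside the span. Prediction mode places one grid point every 0.5 s from
#' the span start through the span end inclusive (count = span/0.5 + 1),
#' each classifying the sample at its grid time; the trailing history is
#' drawn from the rows preceding the span (e.g. the tuning segment) where
#' available and back-filled with the first row otherwise. Windows are
#' stored by reference into the feature matrix (see
#' [materialize_windows()]).
#'
#' @param features A `fog_features` object or plain matrix (rows =
#'   timepoints).
#' @param timeline Per-sample labels aligned to the rows.
#' @param mode `"training"` or `"prediction"`.
#' @param span_start_s,span_end_s Span covered by the grid, in seconds
#'   relative to the first row; defaults to the whole matrix.
#' @param window_s Window length in seconds (default 3).
#' @param step_s Grid step in seconds (default 0.5).
#' @param fs Sampling rate; taken from `features` when available.
#' @return A list of class `fog_windows`: `values` (the backing matrix),
#'   `end_idx` (final-sample row of each window), `end_times_s` (grid
#'   times), `labels`, `mode`, `win_len`, `fs`.
#' @export
build_windows <- function(features, timeline, mode = c("training", "prediction"),
                          span_start_s = 0, span_end_s = NULL,
                          window_s = 3, step_s = 0.5, fs = NULL) {
  mode <- match.arg(mode)
  values <- if (inherits(features, "fog_features")) features$values
            else features
  if (is.null(fs)) fs <- features$fs_hz
  n <- nrow(values)
  win_len <- round(window_s * fs)
  if (mode == "training") {
    if (is.null(span_end_s)) span_end_s <- n / fs
    if (span_end_s - span_start_s < window_s) {
      stop("training span shorter than one window", call. = FALSE)
    }
    ends <- seq(span_start_s + window_s, span_end_s + 1e-9, by = step_s)
    end_idx <- round(ends * fs)
  } else {
    if (is.null(span_end_s)) span_end_s <- (n - 1) / fs
    if (span_end_s < span_start_s) {
      stop("prediction span is empty", call. = FALSE)
    }
    # snap the span end down to the 0.5 s grid
    span_end_s <- span_start_s +
      floor((span_end_s - span_start_s) / step_s + 1e-9) * step_s
    ends <- seq(span_start_s, span_end_s + 1e-9, by = step_s)
    end_idx <- round(ends * fs) + 1L
  }
  stopifnot(all(end_idx >= 1), all(end_idx <= n))
  structure(list(values = values, end_idx = as.integer(end_idx),
                 end_times_s = ends, labels = as.integer(timeline[end_idx]),
                 mode = mode, win_len = win_len, fs = fs),
            class = "fog_windows")
}

#' Number of windows in a window set
#' @param ws A `fog_windows` object.
#' @return Integer count.
#' @export
n_windows <- function(ws) length(ws$end_idx)

#' Materialize a window set as an explicit stacked matrix
#'
#' Copies every window's `win_len` rows out of the backing matrix into a
#' stacked matrix of `n_windows * win_len` rows (warm-up rows before the
#' first sample are back-filled with the first row). Needed by
#' augmentation and attribution, which perturb window contents.
#'
#' @param ws A `fog_windows` object.
#' @return A `fog_windows` object whose backing matrix is the stacked copy
#'   (with `end_idx` pointing at each window's final row).
#' @export
materialize_windows <- function(ws) {
  n <- n_windows(ws)
  offs <- rep(ws$end_idx, each = ws$win_len) -
    rep(seq(ws$win_len - 1L, 0L), times = n)
  stacked <- ws$values[pmax(offs, 1L), , drop = FALSE]
  ws$values <- stacked
  ws$end_idx <- ws$win_len * seq_len(n)
  ws
}

#' Balanced inverse-frequency class weights
#'
#' `weight_c = n_total / (2 * n_c)` for each class, so the minority class
#' is up-weighted and a balanced set gets unit weights.
#'
#' @param labels Integer 0/1 labels.
#' @return Named numeric vector `c("0" = ..., "1" = ...)`.
#' @export
class_weights <- function(labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n0 == 0 || n1 == 0) {
    stop("both classes must be present to compute class weights",
         call. = FALSE)
  }
  n <- n0 + n1
  c("0" = n / (2 * n0), "1" = n / (2 * n1))
}

#' Augment a window set with Gaussian jitter
#'
#' Appends two noisy copies of the window set (output size three times the
#' input): each copy adds independent Gaussian noise per feature with SD
#' equal to 1% of that feature's SD over the input windows. Labels are
#' copied unchanged and the original windows are preserved verbatim.
#'
#' @param ws A `fog_windows` object.
#' @param seed Integer seed.
#' @param copies Number of noisy copies, default 2.
#' @param sd_frac Noise SD as a fraction of each feature's SD, default 0.01.
#' @return A materialized `fog_windows` with `(1 + copies) * n` windows.
#' @export
augment_jitter <- function(ws, seed, copies = 2, sd_frac = 0.01) {
  stopifnot(n_windows(ws) > 0)
  orig <- materialize_windows(ws)
  sds <- apply(orig$values, 2, stats::sd)
  sds[!is.finite(sds)] <- 0
  set.seed(as.integer(seed %% .Machine$integer.max))
  blocks <- vector("list", copies + 1)
  blocks[[1]] <- orig$values
  for (k in seq_len(copies)) {
    noise <- matrix(stats::rnorm(length(orig$values)), nrow(orig$values)) *
      rep(sd_frac * sds, each = nrow(orig$values))
    blocks[[k + 1]] <- orig$values + noise
  }
  n <- n_windows(orig)
  structure(list(values = do.call(rbind, blocks),
                 end_idx = orig$win_len * seq_len(n * (copies + 1)),
                 end_times_s = rep(orig$end_times_s, copies + 1),
                 labels = rep(orig$labels, copies + 1),
                 mode = orig$mode, win_len = orig$win_len, fs = orig$fs),
            class = "fog_windows")
}

#' Concatenate window sets that share a feature layout
#'
#' @param ws_list List of `fog_windows` (possibly lazy references into
#'   different backing matrices).
#' @return A single `fog_windows` whose backing matrix is the row-bound
#'   concatenation.
#' @export
concat_windows <- function(ws_list) {
  stopifnot(length(ws_list) >= 1)
  mats <- lapply(ws_list, `[[`, "values")
  offsets <- cumsum(c(0L, vapply(mats, nrow, integer(1))))
  end_idx <- unlist(lapply(seq_along(ws_list), function(k) {
    pmax(ws_list[[k]]$end_idx, ws_list[[k]]$win_len) + offsets[k]
  }))
  structure(list(values = do.call(rbind, mats),
                 end_idx = as.integer(end_idx),
                 end_times_s = unlist(lapply(ws_list, `[[`, "end_times_s")),
                 labels = unlist(lapply(ws_list, `[[`, "labels")),
                 mode = ws_list[[1]]$mode, win_len = ws_list[[1]]$win_len,
                 fs = ws_list[[1]]$fs),
            class = "fog_windows")
}

# Window subset by index (keeps the backing matrix).
.subset_windows <- function(ws, idx) {
  ws$end_idx <- ws$end_idx[idx]
  ws$end_times_s <- ws$end_times_s[idx]
  ws$labels <- ws$labels[idx]
  ws
}
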