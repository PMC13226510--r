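# Derived bipolar channels and participant-level normalization.

.derived_channel_order <- function(side) {
  paste0(side, "_", c("0_1", "0_2", "0_3", "1_2", "1_3", "2_3"))
}

#' Derive the full 12-channel set from the 6 recorded bipolar pairs
#'
#' Per hemisphere the three unrecorded adjacent pairs are linear
#' combinations of the recorded ones:
#' `0_1 = 0_3 - 1_3`, `1_2 = 1_3 + 0_2 - 0_3`, `2_3 = 0_3 - 0_2`.
#' Recorded channels pass through unchanged. The derived channels satisfy
#' the telescoping identity `(0_1) + (1_2) + (2_3) = (0_3)` exactly.
#'
#' @param rec A `fog_trial` (or any list with a `channels` element holding
#'   the six recorded labels plus `fs_hz`).
#' @return A list of class `fog_channels` with 12 named channels per the
#'   fixed order `0_1, 0_2, 0_3, 1_2, 1_3, 2_3` per side, plus the trial
#'   metadata.
#' @export
derive_channels <- function(rec) {
  ch <- rec$channels
  missing <- setdiff(.recorded_channel_labels, names(ch))
  if (length(missing) > 0) {
    stop("missing recorded channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (side in c("Left", "Right")) {
    c02 <- ch[[paste0(side, "_0_2")]]
    c03 <- ch[[paste0(side, "_0_3")]]
    c13 <- ch[[paste0(side, "_1_3")]]
    out[[paste0(side, "_0_1")]] <- c03 - c13
    out[[paste0(side, "_0_2")]] <- c02
    out[[paste0(side, "_0_3")]] <- c03
    out[[paste0(side, "_1_2")]] <- c13 + c02 - c03
    out[[paste0(side, "_1_3")]] <- c13
    out[[paste0(side, "_2_3")]] <- c03 - c02
  }
  out <- out[c(.derived_channel_order("Left"), .derived_channel_order("Right"))]
  structure(list(participant_id = rec$participant_id, module = rec$module,
                 fs_hz = rec$fs_hz, resting = isTRUE(rec$resting),
                 channels = out),
            class = "fog_channels")
}

#' Z-score all 12 channels per participant across trials
#'
#' Normalization statistics are pooled over the concatenated samples of all
#' supplied trials, per channel, so each channel has pooled mean 0 and
#' pooled SD 1 afterwards. A constant channel (SD 0) is replaced by zeros
#' with a warning rather than NaN.
#'
#' @param chansets A list of `fog_channels` sets from one participant.
#' @param stats Optional precomputed statistics (as returned in `$stats`) to
#'   apply instead of pooling, e.g. to normalize a resting recording with
#'   the participant's walking-trial statistics.
#' @return A list with `sets` (normalized `fog_channels` list) and `stats`
#'   (data.frame with `channel`, `mean`, `sd`).
#' @export
zscore_participant <- function(chansets, stats = NULL) {
  stopifnot(length(chansets) >= 1)
  labels <- names(chansets[[1]]$channels)
  if (is.null(stats)) {
    stats <- do.call(rbind, lapply(labels, function(lb) {
      pooled <- unlist(lapply(chansets, function(cs) cs$channels[[lb]]),
                       use.names = FALSE)
      data.frame(channel = lb, mean = mean(pooled), sd = stats::sd(pooled),
                 stringsAsFactors = FALSE)
    }))
  }
  sets <- lapply(chansets, function(cs) {
    for (k in seq_len(nrow(stats))) {
      lb <- stats$channel[k]
      if (!is.finite(stats$sd[k]) || stats$sd[k] == 0) {
        warning("channel ", lb, " is constant; emitting zeros", call. = FALSE)
        cs$channels[[lb]] <- rep(0, length(cs$channels[[lb]]))
      } else {
        cs$channels[[lb]] <- (cs$channels[[lb]] - stats$mean[k]) / stats$sd[k]
      }
    }
    cs
  })
  list(sets = sets, stats = stats)
}
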