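# Alpha-beta burst detection: resting-state baseline thresholds and burst
# durations from amplitude envelopes of band-passed, squared LFP.

# Linear interpolation through local extrema of a series, evaluated on the
# full sample grid. Plateau-tolerant: a point is an extremum if it is
# weakly smaller/larger than both neighbours.
.extrema_envelope <- function(x, type = c("min", "max")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 3) return(x)
  left <- x[2:(n - 1)] - x[1:(n - 2)]
  right <- x[2:(n - 1)] - x[3:n]
  idx <- if (type == "min") which(left <= 0 & right <= 0) + 1L
         else which(left >= 0 & right >= 0) + 1L
  if (length(idx) < 2) return(rep(stats::median(x), n))
  stats::approx(idx, x[idx], xout = seq_len(n), rule = 2)$y
}

.bandpass <- function(x, fs, lo, hi) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# The five 6 Hz-wide noise-floor bands inside 45-63 Hz (3 Hz hop), the only
# layout placing five consecutive 6 Hz bands within that span.
.noise_band_edges <- function() {
  lo <- c(45, 48, 51, 54, 57)
  cbind(lo = lo, hi = lo + 6)
}

#' Resting-state burst baseline threshold for one channel
#'
#' The resting channel is band-pass filtered into five 6 Hz-wide bands
#' spanning 45-63 Hz, each filtered copy squared, the local minima of each
#' squared series interpolated onto the full time base, and the median of
#' each interpolated series taken. The threshold is 4 times the mean of the
#' five medians; being derived from a high-frequency noise floor it is
#' deliberately low, admitting a broad range of burst durations.
#'
#' @param x Resting-state samples of one channel (>= 20 s).
#' @param fs Sampling rate in Hz.
#' @return A list with `threshold` (squared-signal units) and `medians`
#'   (the five per-band medians).
#' @export
resting_burst_threshold <- function(x, fs) {
  if (length(x) < 20 * fs) {
    stop("resting channel must be at least 20 seconds", call. = FALSE)
  }
  edges <- .noise_band_edges()
  meds <- vapply(seq_len(nrow(edges)), function(k) {
    sq <- .bandpass(x, fs, edges[k, "lo"], edges[k, "hi"])^2
    stats::median(.extrema_envelope(sq, "min"))
  }, numeric(1))
  list(threshold = 4 * mean(meds), medians = meds)
}

#' Peak alpha-beta frequency of a channel from walking-trial data
#'
#' Frequency of maximal Welch PSD power within 8-30 Hz; used to center the
#' 6 Hz burst-detection band for that channel and trial.
#'
#' @param x Channel samples.
#' @param fs Sampling rate in Hz.
#' @return Peak frequency in Hz.
#' @export
trial_peak_freq <- function(x, fs) {
  w <- welch_psd(x, fs)
  sel <- which(w$freq >= 8 & w$freq <= 30)
  w$freq[sel][which.max(w$psd[sel])]
}

#' Burst intervals and durations for one channel
#'
#' The channel is band-pass filtered with a 6 Hz bandwidth centered on
#' `peak_freq`, squared, and its amplitude envelope estimated by linear
#' interpolation through the local maxima of the squared signal. Bursts are
#' the maximal intervals where the envelope exceeds the resting-state
#' threshold. Alongside the per-trial burst list and mean duration, a
#' per-timepoint series gives the duration of the burst containing each
#' timepoint (0 outside bursts), for time-resolved downstream use.
#'
#' @param x Channel samples.
#' @param fs Sampling rate in Hz.
#' @param peak_freq Center frequency (Hz) of the 6 Hz detection band,
#'   normally from [trial_peak_freq()].
#' @param threshold Resting-state baseline threshold from
#'   [resting_burst_threshold()].
#' @return A list with `bursts` (data.frame `start_s`, `end_s`,
#'   `duration_s`), `mean_duration_s`, `ongoing` (per-timepoint burst
#'   duration series) and `envelope`.
#' @export
burst_durations <- function(x, fs, peak_freq, threshold) {
  lo <- max(1, peak_freq - 3)
  hi <- min(fs / 2 - 1, peak_freq + 3)
  env <- .extrema_envelope(.bandpass(x, fs, lo, hi)^2, "max")
  above <- env > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ongoing <- numeric(length(x))
  if (length(keep) > 0) {
    dur <- r$lengths[keep] / fs
    for (k in seq_along(keep)) {
      ongoing[starts[keep[k]]:ends[keep[k]]] <- dur[k]
    }
    bursts <- data.frame(start_s = (starts[keep] - 1) / fs,
                         end_s = ends[keep] / fs,
                         duration_s = dur)
  } else {
    bursts <- data.frame(start_s = numeric(0), end_s = numeric(0),
                         duration_s = numeric(0))
  }
  list(bursts = bursts,
       mean_duration_s = if (nrow(bursts) > 0) mean(bursts$duration_s) else 0,
       ongoing = ongoing, envelope = env)
}
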