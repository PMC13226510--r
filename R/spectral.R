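# Spectral estimation: trailing-window Welch band powers, resting PSDs,
# aperiodic (1/f) fits and participant-specific band definitions.

#' Canonical frequency band definitions
#'
#' Delta (1-4 Hz), theta (4-8), alpha (8-13), beta (13-30) and gamma
#' (30-100), with trailing Welch history lengths of 500, 250, 125, 62 and 31
#' samples respectively (2 s down to 124 ms at 250 Hz: lower bands need
#' longer histories to resolve their frequencies).
#'
#' @return A data.frame with columns `name`, `lo_hz`, `hi_hz`,
#'   `welch_samples`.
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo_hz = c(1, 4, 8, 13, 30),
             hi_hz = c(4, 8, 13, 30, 100),
             welch_samples = c(500L, 250L, 125L, 62L, 31L),
             stringsAsFactors = FALSE)
}

#' Define a frequency band for trailing-window power estimation
#'
#' @param name Band name.
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo < hi`.
#' @param welch_samples Trailing history length in samples (>= 8).
#' @return A one-row data.frame band definition.
#' @export
band_def <- function(name, lo_hz, hi_hz, welch_samples) {
  stopifnot(lo_hz > 0, hi_hz > lo_hz, welch_samples >= 8)
  data.frame(name = name, lo_hz = lo_hz, hi_hz = hi_hz,
             welch_samples = as.integer(welch_samples),
             stringsAsFactors = FALSE)
}

.hann <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))

# Trapezoidal integral of a PSD between band edges, over the PSD's own grid.
.band_integral <- function(freq, psd_mat, lo, hi) {
  sel <- which(freq >= lo & freq <= hi)
  if (length(sel) == 0) return(rep(0, ncol(psd_mat)))
  if (length(sel) == 1) {
    df <- if (length(freq) > 1) freq[2] - freq[1] else hi - lo
    return(psd_mat[sel, ] * min(df, hi - lo))
  }
  f <- freq[sel]
  p <- psd_mat[sel, , drop = FALSE]
  w <- diff(f)
  colSums((p[-1, , drop = FALSE] + p[-length(sel), , drop = FALSE]) *
            (w / 2))
}

#' Causal per-timepoint band power from a trailing Welch window
#'
#' At each timepoint the power in `[lo_hz, hi_hz]` is the trapezoidal
#' integral of a Hann-windowed one-segment Welch PSD of the
#' `welch_samples` samples ending at (and including) that timepoint; no
#' future data enter any estimate. Timepoints with insufficient history are
#' back-filled with the first valid value. With `stride > 1` the estimate is
#' computed every `stride` samples and held until the next computation (a
#' documented approximation of the literal one-sample step).
#'
#' @param x Numeric sample vector.
#' @param band A one-row band definition from [band_def()] or
#'   [canonical_bands()].
#' @param fs Sampling rate in Hz.
#' @param stride Recomputation step in samples (default 1, the literal
#'   per-timepoint estimate).
#' @return Numeric vector of band power, same length as `x`.
#' @export
band_power_series <- function(x, band, fs, stride = 1L) {
  W <- band$welch_samples
  if (band$hi_hz > fs / 2) {
    stop("band '", band$name, "' extends above the Nyquist frequency",
         call. = FALSE)
  }
  n <- length(x)
  if (n < W) stop("signal shorter than the band's Welch history",
                  call. = FALSE)
  positions <- seq(W, n, by = stride)
  win <- .hann(W)
  scale <- 1 / (fs * sum(win^2))
  idx <- outer(seq_len(W) - W, positions, "+")      # W x npos sample indices
  seg <- matrix(x[idx], nrow = W) * win
  spec <- stats::mvfft(seg)
  half <- floor(W / 2) + 1
  psd <- (Mod(spec[seq_len(half), , drop = FALSE])^2) * scale
  if (half > 2) {
    interior <- 2:(half - 1 + (W %% 2))             # double all but DC/Nyquist
    psd[interior, ] <- 2 * psd[interior, ]
  }
  freq <- (seq_len(half) - 1) * fs / W
  pow <- .band_integral(freq, psd, band$lo_hz, band$hi_hz)
  # expand back to the sample grid: hold each value until the next estimate
  j <- pmax(1L, (seq_len(n) - W) %/% stride + 1L)
  j[seq_len(min(n, W - 1))] <- 1L
  pow[pmin(j, length(pow))]
}

#' Welch power spectral density of a whole recording segment
#'
#' Averaged Hann-windowed periodograms (1 s window, 0.5 s overlap by
#' default), the estimator used on resting data to locate
#' participant-specific spectral peaks.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param win_s Segment length in seconds.
#' @param overlap_s Segment overlap in seconds.
#' @return A list with `freq` (Hz) and `psd` (power/Hz).
#' @export
welch_psd <- function(x, fs, win_s = 1, overlap_s = 0.5) {
  W <- round(win_s * fs)
  hop <- W - round(overlap_s * fs)
  stopifnot(hop >= 1, length(x) >= W)
  starts <- seq(1, length(x) - W + 1, by = hop)
  win <- .hann(W)
  scale <- 1 / (fs * sum(win^2))
  seg <- vapply(starts, function(s) x[s:(s + W - 1)] * win, numeric(W))
  spec <- stats::mvfft(seg)
  half <- floor(W / 2) + 1
  psd <- rowMeans(Mod(spec[seq_len(half), , drop = FALSE])^2) * scale
  if (half > 2) {
    interior <- 2:(half - 1 + (W %% 2))
    psd[interior] <- 2 * psd[interior]
  }
  list(freq = (seq_len(half) - 1) * fs / W, psd = psd)
}

#' Fit a generalized power law C / f^alpha to a PSD
#'
#' Least-squares regression of log power on log frequency over the fit
#' range, excluding the alpha-beta peak-search range so narrow oscillatory
#' peaks do not bias the aperiodic baseline.
#'
#' @param freq Frequency grid (Hz).
#' @param psd Power values (same length).
#' @param fit_range Frequencies used for the fit, default `c(1, 100)` Hz.
#' @param exclude Frequency range excluded from the fit, default
#'   `c(8, 30)` Hz (the alpha-beta peak-search range); `NULL` to disable.
#' @return A list with `C` (amplitude), `alpha` (exponent) and `baseline()`,
#'   a function evaluating the fit at arbitrary frequencies.
#' @export
fit_one_over_f <- function(freq, psd, fit_range = c(1, 100),
                           exclude = c(8, 30)) {
  sel <- freq >= fit_range[1] & freq <= fit_range[2]
  if (!is.null(exclude)) sel <- sel & !(freq >= exclude[1] & freq <= exclude[2])
  f <- freq[sel]; p <- psd[sel]
  if (length(f) < 2) stop("too few frequencies in the fit range", call. = FALSE)
  if (any(p <= 0) || any(f <= 0)) {
    stop("non-positive power or frequency in the 1/f fit range", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, log(f)), log(p))
  C <- exp(fit$coefficients[[1]])
  alpha <- -fit$coefficients[[2]]
  list(C = C, alpha = alpha,
       baseline = function(fq) C * fq^(-alpha))
}

#' Participant-specific alpha-beta bands from a resting recording
#'
#' Per hemisphere: Welch PSDs (1 s Hann window, 0.5 s overlap) of that
#' hemisphere's six channels, a 1/f baseline fitted and subtracted per
#' channel, and the frequency of the largest above-baseline peak in the
#' alpha-beta range (8-30 Hz) across the hemisphere's channels selected
#' (a peak counts only when it rises at least half the aperiodic level
#' above the baseline, so estimator noise cannot masquerade as one).
#' Three bands of 6, 10 and 20 Hz bandwidth are centered at that frequency
#' (edges clipped to \[1, 100\] Hz). If no channel shows an above-baseline
#' peak the midpoint fallback of 19 Hz is used with a warning.
#'
#' @param resting A resting `fog_trial` (>= 20 s) or a `fog_channels` set
#'   derived from one.
#' @param welch_samples Trailing history (samples) used when these bands are
#'   later turned into per-timepoint powers; default 125 (0.5 s at 250 Hz),
#'   matching the alpha-band history since the bands live in 8-30 Hz.
#' @return A list of class `fog_custom_bands` with per-hemisphere elements
#'   `Left` and `Right`, each holding `peak_freq_hz`, `bands` (three-row
#'   band data.frame `cw6`, `cw10`, `cw20`) and the per-channel aperiodic
#'   fits.
#' @export
find_custom_bands <- function(resting, welch_samples = 125L) {
  chans <- if (inherits(resting, "fog_channels")) resting
           else derive_channels(resting)
  fs <- chans$fs_hz
  if (length(chans$channels[[1]]) < 20 * fs) {
    stop("resting recording must be at least 20 seconds", call. = FALSE)
  }
  out <- list()
  for (side in c("Left", "Right")) {
    labels <- grep(paste0("^", side, "_"), names(chans$channels), value = TRUE)
    best <- list(height = -Inf, freq = NA_real_)
    fits <- list()
    for (lb in labels) {
      w <- welch_psd(chans$channels[[lb]], fs)
      fit <- tryCatch(fit_one_over_f(w$freq, w$psd), error = function(e) NULL)
      if (is.null(fit)) next
      fits[[lb]] <- fit[c("C", "alpha")]
      sel <- which(w$freq >= 8 & w$freq <= 30)
      base <- fit$baseline(w$freq[sel])
      above <- w$psd[sel] - base
      k <- which.max(above)
      # require genuine prominence (half the aperiodic level) so estimator
      # noise on a peak-free spectrum does not masquerade as an oscillation
      if (above[k] > 0.5 * base[k] && above[k] > best$height) {
        best <- list(height = above[k], freq = w$freq[sel][k])
      }
    }
    if (!is.finite(best$height) || best$height <= 0) {
      warning("no above-baseline alpha-beta peak for ", side,
              " hemisphere; falling back to 19 Hz", call. = FALSE)
      best$freq <- 19
    }
    widths <- c(cw6 = 6, cw10 = 10, cw20 = 20)
    bands <- do.call(rbind, lapply(names(widths), function(nm) {
      half <- widths[[nm]] / 2
      band_def(nm, max(1, best$freq - half), min(100, best$freq + half),
               welch_samples)
    }))
    out[[side]] <- list(peak_freq_hz = best$freq, bands = bands,
                        aperiodic_fits = fits)
  }
  structure(out, class = "fog_custom_bands")
}
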