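#' Causal rolling statistics of a feature series
#'
#' Trailing-window mean, minimum, maximum and sample standard deviation at
#' every timepoint, for each requested window length. The window at
#' timepoint t covers the samples ending at (and including) t; during
#' warm-up, before a full window of history exists, the statistic is taken
#' over the available (expanding) history, so no timepoint is missing.
#'
#' @param series Numeric per-timepoint values.
#' @param fs Sampling rate of the series in Hz.
#' @param windows_s Window lengths in seconds (default 0.125, 0.5 and 2).
#' @param stats Which statistics to compute, a subset of
#'   `c("mean", "min", "max", "sd")`.
#' @return A numeric matrix, `length(series)` rows, one column per
#'   (window, statistic) pair named `"<stat>_<window>"`.
#' @export
rolling_stats <- function(series, fs, windows_s = c(0.125, 0.5, 2),
                          stats = c("mean", "min", "max", "sd")) {
  stats <- match.arg(stats, several.ok = TRUE)
  cols <- c(mean = 1L, min = 2L, max = 3L, sd = 4L)[stats]
  out <- matrix(NA_real_, nrow = length(series),
                ncol = length(windows_s) * length(stats))
  nm <- character(ncol(out))
  j <- 0L
  for (ws in windows_s) {
    w <- max(1L, round(ws * fs))
    block <- roll_stats_cpp(as.numeric(series), w)
    for (k in seq_along(stats)) {
      j <- j + 1L
      out[, j] <- block[, cols[k]]
      nm[j] <- paste0(stats[k], "_", format(ws, trim = TRUE))
    }
  }
  colnames(out) <- nm
  out
}
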