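# Shared fixtures and independent oracles used across the test files.

# Tiny model spec whose conv stack fits short windows.
tiny_model_spec <- function(n_features, window_len = 60, seed = 7, ...) {
  model_spec(n_features = n_features, window_len = window_len,
             conv_filters = c(4, 6, 8), conv_kernels = c(5, 3, 3),
             conv_strides = c(4, 2, 1), conv_dilations = c(2, 1, 1),
             n_heads = 2, ff_dim = 10, gru_units = 3, dense_units = 5,
             dropout = 0, seed = seed, ...)
}

# Explicit window set around a stacked matrix.
stacked_windows <- function(vals, n, win_len, labels = integer(n), fs = 250) {
  structure(list(values = vals, end_idx = win_len * seq_len(n),
                 end_times_s = seq_len(n) * 0.5, labels = as.integer(labels),
                 mode = "training", win_len = win_len, fs = fs),
            class = "fog_windows")
}

random_windows <- function(n, win_len, n_features, pos_frac = 0.4, seed = 1,
                           sep = 0) {
  set.seed(seed)
  lab <- stats::rbinom(n, 1, pos_frac)
  vals <- matrix(stats::rnorm(n * win_len * n_features), n * win_len,
                 n_features)
  if (sep != 0) vals[, 1] <- vals[, 1] + rep(lab * sep, each = win_len)
  stacked_windows(vals, n, win_len, labels = lab)
}

# Independent single-segment Hann periodogram band power (brute force).
oracle_band_power <- function(seg, fs, lo, hi) {
  W <- length(seg)
  k <- seq(0, W - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (W - 1)))
  sp <- abs(stats::fft(seg * w))^2 / (fs * sum(w^2))
  half <- floor(W / 2) + 1
  psd <- sp[seq_len(half)]
  if (half > 2) {
    interior <- 2:(half - 1 + (W %% 2))
    psd[interior] <- 2 * psd[interior]
  }
  freq <- (seq_len(half) - 1) * fs / W
  sel <- which(freq >= lo & freq <= hi)
  if (length(sel) < 2) return(psd[sel] * (freq[2] - freq[1]))
  sum(diff(freq[sel]) * (psd[sel][-1] + psd[sel][-length(sel)]) / 2)
}

# Mean band power over fixed-length chunks of selected sample indices.
oracle_chunk_power <- function(x, idx, fs, lo, hi, chunk = 512) {
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  pows <- unlist(lapply(runs, function(r) {
    if (length(r) < chunk) return(NULL)
    starts <- seq(1, length(r) - chunk + 1, by = chunk %/% 2)
    vapply(starts, function(s) {
      seg <- x[r[s:(s + chunk - 1)]]
      sp <- abs(stats::fft(seg))^2 / length(seg)
      f <- (seq_along(seg) - 1) * fs / length(seg)
      mean(sp[f >= lo & f <= hi])
    }, numeric(1))
  }))
  mean(pows)
}

# Measured FOG band-power shift (dB) for one channel, excluding a margin
# around each event boundary (the pre-onset ramp).
oracle_fog_shift_db <- function(x, events, fs, peak, margin_s = 3) {
  lab <- label_timepoints(events, length(x), fs)
  excl <- rep(FALSE, length(x))
  m <- round(margin_s * fs)
  for (k in seq_len(nrow(events))) {
    for (b in c(events$start_s[k], events$end_s[k])) {
      i0 <- max(1, round(b * fs) - m)
      i1 <- min(length(x), round(b * fs) + m)
      excl[i0:i1] <- TRUE
    }
  }
  pin <- oracle_chunk_power(x, which(lab == 1 & !excl), fs, peak - 3, peak + 3)
  pout <- oracle_chunk_power(x, which(lab == 0 & !excl), fs, peak - 3, peak + 3)
  10 * log10(pin / pout)
}

# A resting trial with controlled sinusoidal peaks per channel on a 1/f
# background (for custom-band tests).
synthetic_resting <- function(fs = 250, dur = 24, peaks = list(), seed = 5,
                              flat = FALSE) {
  set.seed(seed)
  n <- dur * fs
  tt <- (seq_len(n) - 1) / fs
  base <- function() {
    if (flat) return(stats::rnorm(n))
    freqs <- seq(0, fs - fs / n, length.out = n)
    freqs <- pmin(freqs, fs - freqs)
    scale <- pmax(freqs, 1)^-1
    spec <- stats::fft(stats::rnorm(n)) * scale
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x / stats::sd(x)
  }
  chans <- list()
  for (lb in c("Left_0_2", "Left_0_3", "Left_1_3",
               "Right_0_2", "Right_0_3", "Right_1_3")) {
    x <- base()
    if (!is.null(peaks[[lb]])) {
      for (p in peaks[[lb]]) x <- x + p$amp * sin(2 * pi * p$freq * tt)
    }
    chans[[lb]] <- x
  }
  fog_trial("P1", "resting", fs, chans, resting = TRUE)
}

# Textbook confusion-matrix metrics, written independently of the package.
oracle_metrics <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1); fp <- sum(y == 0 & yhat == 1)
  tn <- sum(y == 0 & yhat == 0); fn <- sum(y == 1 & yhat == 0)
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  spec <- ifelse(tn + fp == 0, 0, tn / (tn + fp))
  npv <- ifelse(tn + fn == 0, 0, tn / (tn + fn))
  f1p <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  f1n <- ifelse(npv + spec == 0, 0, 2 * npv * spec / (npv + spec))
  list(sensitivity = rec, specificity = spec, precision = prec,
       macro_f1 = (f1p + f1n) / 2,
       weighted_f1 = ((tp + fn) * f1p + (tn + fp) * f1n) / length(y))
}

# The eight per-trial rows printed for the held-out test sets (durations in
# seconds, freeze counts, freeze time, and the reported per-trial metrics).
published_trial_rows <- function() {
  data.frame(
    participant = c("S1", "S2", "S2", "S3", "S4", "S4", "S5", "S5"),
    module = c("cognitive", "cognitive", "physical", "cognitive",
               "cognitive", "physical", "cognitive", "anxiety"),
    test_duration_s = c(51.5, 77, 33.5, 58, 59.5, 41.5, 65.5, 60.5),
    n_freezes = c(3, 6, 5, 3, 1, 4, 6, 2),
    freeze_duration_s = c(33.5, 33.9, 18.2, 17.4, 13.5, 8.2, 29.3, 15.2),
    weighted_f1 = c(0.735, 0.511, 0.434, 0.638, 0.736, 0.761, 0.712, 0.797),
    macro_f1 = c(0.729, 0.510, 0.429, 0.609, 0.614, 0.649, 0.701, 0.744),
    sensitivity = c(0.627, 0.536, 0.556, 0.694, 0.370, 0.529, 0.667, 0.767),
    specificity = c(0.919, 0.488, 0.313, 0.593, 0.849, 0.806, 0.750, 0.793),
    stringsAsFactors = FALSE)
}

# Hand-assembled cohort-features object (full control over events/metadata)
# for cross-validation planning tests.
manual_cohort_features <- function(trials, fs = 250) {
  feats <- lapply(trials, function(tr) {
    structure(list(values = tr$values, fs_hz = fs,
                   channel_of = rep("Left_0_2", ncol(tr$values)),
                   participant_id = tr$participant, module = tr$module),
              class = "fog_features")
  })
  structure(list(features = feats,
                 events = lapply(trials, `[[`, "events"),
                 custom_bands = NULL, thresholds = NULL, pruning = NULL,
                 fs_hz = fs),
            class = "fog_cohort_features")
}
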