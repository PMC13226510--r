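# Synthetic cohort generation.
#
# Each hemisphere is built from four latent monopolar contact signals; the
# three recorded bipolar pairs are emitted as contact differences, so the
# derived-channel algebra used downstream (0-1, 1-2, 2-3 reconstruction and
# the telescoping identity) is physically meaningful by construction.

# Montage profile: gain of the common oscillatory source at contacts 0..3.
.contact_gains <- c(1.0, 0.75, 0.45, 0.2)
.osc_gain <- 1.5      # oscillation amplitude relative to unit-SD background
.burst_base_env <- 0.6  # tonic oscillation level (carries the dB signature)
.burst_amp <- 0.5       # additional envelope during a burst
.burst_rate_hz <- 0.6
.burst_mean_s <- 0.25

#' @keywords internal
.trial_seed <- function(seed, p_idx, m_idx) {
  as.integer((abs(seed) * 100003 + p_idx * 1009 + m_idx * 101) %%
               (.Machine$integer.max - 1L)) + 1L
}

# 1/f^alpha-shaped Gaussian noise with unit SD. Spectrum is flattened below
# 1 Hz, mimicking the device high-pass, and has no DC component.
.sim_aperiodic <- function(n, fs, alpha) {
  freqs <- seq(0, fs - fs / n, length.out = n)
  freqs <- pmin(freqs, fs - freqs)          # two-sided frequency magnitudes
  scale <- pmax(freqs, 1)^(-alpha / 2)
  scale[1] <- 0
  spec <- stats::fft(stats::rnorm(n)) * scale
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Unit-SD band-limited carrier (filtered white noise).
.sim_carrier <- function(n, fs, lo, hi) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

# Burst amplitude-modulation envelope. Burst onsets are Poisson in time;
# durations are exponential with mean scaled by `fog_scale` inside FOG.
# Burst amplitude inside FOG is divided by sqrt(fog_scale) so the expected
# burst power is unchanged: the configured dB shift, applied separately,
# remains the sole driver of FOG band-power changes.
.sim_burst_env <- function(n, fs, fog_mask, fog_scale) {
  env <- numeric(n)
  t <- stats::rexp(1, .burst_rate_hz)
  while (t < n / fs) {
    i0 <- floor(t * fs) + 1
    in_fog <- i0 <= n && fog_mask[i0]
    dur <- stats::rexp(1, 1 / (.burst_mean_s * if (in_fog) fog_scale else 1))
    amp <- .burst_amp * (if (in_fog) 1 / sqrt(fog_scale) else 1)
    i1 <- min(n, i0 + max(1L, round(dur * fs)) - 1L)
    env[i0:i1] <- pmax(env[i0:i1], amp)
    t <- t + dur + stats::rexp(1, .burst_rate_hz)
  }
  # Soften onsets/offsets with a short Gaussian kernel (sd 20 ms).
  ks <- round(0.02 * fs)
  kern <- stats::dnorm(seq(-3 * ks, 3 * ks), sd = ks)
  kern <- kern / sum(kern)
  sm <- stats::filter(c(rep(env[1], 3 * ks), env, rep(env[n], 3 * ks)),
                      kern, sides = 2)
  .burst_base_env + as.numeric(sm[(3 * ks + 1):(3 * ks + n)])
}

# dB gain profile of the FOG signature: `shift_db` inside each event, linear
# (in dB) ramp over `ramp_s` seconds before each onset, 0 elsewhere.
.fog_db_profile <- function(n, fs, events, shift_db, ramp_s) {
  db <- numeric(n)
  if (nrow(events) == 0 || shift_db == 0) return(db)
  tt <- (seq_len(n) - 1) / fs
  for (k in seq_len(nrow(events))) {
    s <- events$start_s[k]; e <- events$end_s[k]
    inside <- tt >= s & tt < e
    db[inside] <- shift_db
    if (ramp_s > 0) {
      ramp <- tt >= (s - ramp_s) & tt < s
      db[ramp] <- pmax(db[ramp], shift_db * (tt[ramp] - (s - ramp_s)) / ramp_s)
      if (shift_db < 0) {
        db[ramp] <- pmin(db[ramp], shift_db * (tt[ramp] - (s - ramp_s)) / ramp_s)
      }
    }
  }
  db
}

# Draw non-overlapping FOG events with >= 3 s separation.
.place_events <- function(n_range, dur_range, total_s, min_gap = 3) {
  n_ev <- if (n_range[1] == n_range[2]) n_range[1] else
    sample(seq(n_range[1], n_range[2]), 1)
  if (n_ev == 0) return(fog_events(numeric(0), numeric(0)))
  durs <- stats::runif(n_ev, dur_range[1], dur_range[2])
  free <- total_s - sum(durs) - (n_ev + 1) * min_gap
  if (free < 0) {
    stop("requested FOG events cannot fit in the trial without overlap; ",
         "reduce n_fog_per_trial or fog_duration_s", call. = FALSE)
  }
  w <- stats::runif(n_ev + 1)
  gaps <- min_gap + free * w / sum(w)
  starts <- cumsum(gaps[seq_len(n_ev)]) + cumsum(c(0, durs[-n_ev]))
  fog_events(round(starts, 3), round(starts + durs, 3))
}

# One hemisphere: 4 latent contacts -> 3 recorded bipolar pairs.
.sim_hemisphere <- function(n, fs, peak, alpha, events, shift_db, ramp_s,
                            fog_scale, noise_sd, fog_mask) {
  carrier <- .sim_carrier(n, fs, max(1, peak - 3), min(fs / 2 - 1, peak + 3))
  env <- .sim_burst_env(n, fs, fog_mask, fog_scale)
  gain <- 10^(.fog_db_profile(n, fs, events, shift_db, ramp_s) / 20)
  osc <- .osc_gain * carrier * env * gain
  contacts <- lapply(seq_along(.contact_gains), function(i) {
    .contact_gains[i] * osc + .sim_aperiodic(n, fs, alpha) +
      noise_sd * stats::rnorm(n)
  })
  list(`0_2` = contacts[[1]] - contacts[[3]],
       `0_3` = contacts[[1]] - contacts[[4]],
       `1_3` = contacts[[2]] - contacts[[4]])
}

#' Simulate one walking trial with ground-truth FOG events
#'
#' Generates six recorded bipolar LFP channels (three per hemisphere:
#' `0_2`, `0_3`, `1_3`) of `trial_duration_s * fs_hz` samples. Each channel
#' is a 1/f-shaped aperiodic background plus a band-limited oscillation at
#' the participant's peak frequency (right hemisphere offset by +1 Hz),
#' amplitude-modulated into bursts, plus broadband noise. During FOG events
#' (ramped in over `pre_fog_ramp_s` before onset) the oscillatory power is
#' shifted by the configured dB amount and burst durations are scaled.
#'
#' @param spec A [cohort_spec()].
#' @param participant Participant index in `1:n_participants`.
#' @param module Module name (must appear in `spec$modules`).
#' @param seed Optional integer overriding the seed derived from the spec.
#' @return A list of class `fog_sim_trial` with elements `recording`
#'   (a `fog_trial`), `events` (a `fog_events` table) and `generator_params`.
#' @export
simulate_trial <- function(spec, participant, module, seed = NULL) {
  stopifnot(inherits(spec, "fog_cohort_spec"))
  m_idx <- match(module, spec$modules)
  if (is.na(m_idx) || participant < 1 || participant > spec$n_participants) {
    stop("participant/module outside the cohort spec", call. = FALSE)
  }
  if (is.null(seed)) seed <- .trial_seed(spec$seed, participant, m_idx)
  set.seed(seed)
  fs <- spec$fs_hz
  n <- round(spec$trial_duration_s * fs)
  events <- .place_events(spec$n_fog_per_trial, spec$fog_duration_s,
                          spec$trial_duration_s)
  tt <- (seq_len(n) - 1) / fs
  fog_mask <- rep(FALSE, n)
  for (k in seq_len(nrow(events))) {
    fog_mask <- fog_mask | (tt >= events$start_s[k] & tt < events$end_s[k])
  }
  shift <- spec$fog_power_shift_db[participant, m_idx]
  peak_l <- spec$peak_freq_hz[participant]
  peak_r <- min(30, peak_l + 1)
  chans <- c(
    stats::setNames(
      .sim_hemisphere(n, fs, peak_l, spec$aperiodic_exponent[participant],
                      events, shift, spec$pre_fog_ramp_s,
                      spec$fog_burst_scale, spec$noise_sd, fog_mask),
      paste0("Left_", c("0_2", "0_3", "1_3"))),
    stats::setNames(
      .sim_hemisphere(n, fs, peak_r, spec$aperiodic_exponent[participant],
                      events, shift, spec$pre_fog_ramp_s,
                      spec$fog_burst_scale, spec$noise_sd, fog_mask),
      paste0("Right_", c("0_2", "0_3", "1_3")))
  )
  rec <- fog_trial(participant_id = paste0("P", participant), module = module,
                   fs_hz = fs, channels = chans, resting = FALSE)
  structure(list(recording = rec, events = events,
                 generator_params = list(
                   seed = seed, peak_freq_left = peak_l,
                   peak_freq_right = peak_r, fog_power_shift_db = shift,
                   fog_burst_scale = spec$fog_burst_scale,
                   aperiodic_exponent = spec$aperiodic_exponent[participant])),
            class = "fog_sim_trial")
}

#' Simulate a seated resting recording
#'
#' Same spectral construction as [simulate_trial()] but free of FOG events;
#' used downstream to locate the participant-specific oscillatory peak and
#' to derive resting-state burst thresholds.
#'
#' @inheritParams simulate_trial
#' @return A `fog_trial` with `resting = TRUE`.
#' @export
simulate_resting <- function(spec, participant, seed = NULL) {
  stopifnot(inherits(spec, "fog_cohort_spec"))
  if (is.null(seed)) seed <- .trial_seed(spec$seed, participant, 0L)
  set.seed(seed)
  fs <- spec$fs_hz
  n <- round(spec$resting_duration_s * fs)
  no_events <- fog_events(numeric(0), numeric(0))
  fog_mask <- rep(FALSE, n)
  peak_l <- spec$peak_freq_hz[participant]
  peak_r <- min(30, peak_l + 1)
  chans <- c(
    stats::setNames(
      .sim_hemisphere(n, fs, peak_l, spec$aperiodic_exponent[participant],
                      no_events, 0, 0, 1, spec$noise_sd, fog_mask),
      paste0("Left_", c("0_2", "0_3", "1_3"))),
    stats::setNames(
      .sim_hemisphere(n, fs, peak_r, spec$aperiodic_exponent[participant],
                      no_events, 0, 0, 1, spec$noise_sd, fog_mask),
      paste0("Right_", c("0_2", "0_3", "1_3")))
  )
  fog_trial(participant_id = paste0("P", participant), module = "resting",
            fs_hz = fs, channels = chans, resting = TRUE)
}

#' Simulate a full cohort
#'
#' One trial per participant per module plus one resting recording per
#' participant, all deterministic under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `fog_cohort` with elements `spec`, `trials`
#'   (list of `fog_sim_trial`) and `resting` (list of `fog_trial`, one per
#'   participant).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fog_cohort_spec"))
  trials <- list()
  for (p in seq_len(spec$n_participants)) {
    for (m in spec$modules) {
      trials[[paste0("P", p, "_", m)]] <- simulate_trial(spec, p, m)
    }
  }
  resting <- lapply(seq_len(spec$n_participants), function(p)
    simulate_resting(spec, p))
  names(resting) <- paste0("P", seq_len(spec$n_participants))
  structure(list(spec = spec, trials = trials, resting = resting),
            class = "fog_cohort")
}

#' @export
print.fog_cohort <- function(x, ...) {
  cat("Synthetic LFP cohort:", length(x$trials), "trials,",
      length(x$resting), "resting recordings\n")
  n_ev <- vapply(x$trials, function(tr) nrow(tr$events), integer(1))
  cat("  FOG events per trial:", paste(n_ev, collapse = ", "), "\n")
  invisible(x)
}
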