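#' Specification of a synthetic LFP cohort
#'
#' Describes the study conditions a synthetic cohort emulates: bilateral STN
#' recordings sampled at 250 Hz from three bipolar contact pairs per
#' hemisphere, a seated resting recording per participant, and walking trials
#' in which freezing-of-gait (FOG) episodes carry participant- and
#' module-specific spectral signatures (a band-power shift at the
#' participant's oscillatory peak and a change in burst durations).
#'
#' @param n_participants Number of participants.
#' @param modules Character vector of module names; each participant completes
#'   one trial per module.
#' @param trial_duration_s Duration of each walking trial in seconds.
#' @param resting_duration_s Duration of the seated resting recording in
#'   seconds; must be at least 20.
#' @param fs_hz Sampling rate in Hz.
#' @param aperiodic_exponent Per-participant exponent alpha of the 1/f^alpha
#'   aperiodic background (recycled across participants).
#' @param peak_freq_hz Per-participant oscillatory peak frequency in Hz,
#'   within the alpha-beta range 8-30 Hz (recycled across participants).
#' @param fog_power_shift_db Band-power change (dB, may be signed) of the
#'   oscillation during FOG. Scalar, per-participant vector, or
#'   participants x modules matrix.
#' @param fog_burst_scale Multiplicative change of mean burst duration during
#'   FOG (> 0).
#' @param pre_fog_ramp_s Seconds over which the FOG signature ramps in
#'   (linearly in dB) before each event onset.
#' @param n_fog_per_trial Integer range `c(min, max)` of FOG events per trial.
#' @param fog_duration_s Range `c(min, max)` of individual FOG durations in
#'   seconds.
#' @param noise_sd Standard deviation of the broadband white measurement
#'   noise added to each latent contact (the aperiodic background has unit
#'   SD).
#' @param seed Integer seed; identical specs produce byte-identical cohorts.
#'
#' @return An object of class `fog_cohort_spec`.
#' @seealso [simulate_cohort()], [heterogeneous_cohort_spec()]
#' @export
cohort_spec <- function(n_participants = 5,
                        modules = c("physical", "anxiety", "cognitive"),
                        trial_duration_s = 100,
                        resting_duration_s = 30,
                        fs_hz = 250,
                        aperiodic_exponent = 2,
                        peak_freq_hz = c(14, 18, 22, 16, 25),
                        fog_power_shift_db = 6,
                        fog_burst_scale = 2,
                        pre_fog_ramp_s = 2,
                        n_fog_per_trial = c(1, 3),
                        fog_duration_s = c(5, 12),
                        noise_sd = 0.05,
                        seed = 1L) {
  stopifnot(n_participants >= 1, length(modules) >= 1, fs_hz > 0,
            trial_duration_s > 0, fog_burst_scale > 0, pre_fog_ramp_s >= 0,
            noise_sd >= 0)
  if (resting_duration_s < 20) {
    stop("resting_duration_s must be at least 20 seconds", call. = FALSE)
  }
  exponent <- rep_len(aperiodic_exponent, n_participants)
  peaks <- rep_len(peak_freq_hz, n_participants)
  if (any(peaks < 8 | peaks > 30)) {
    stop("peak_freq_hz must lie within [8, 30] Hz", call. = FALSE)
  }
  shift <- fog_power_shift_db
  if (is.matrix(shift)) {
    if (nrow(shift) != n_participants || ncol(shift) != length(modules)) {
      stop("fog_power_shift_db matrix must be n_participants x length(modules)",
           call. = FALSE)
    }
  } else {
    shift <- matrix(rep_len(shift, n_participants), n_participants,
                    length(modules))
  }
  dimnames(shift) <- list(paste0("P", seq_len(n_participants)), modules)
  n_fog_per_trial <- as.integer(round(n_fog_per_trial))
  stopifnot(length(n_fog_per_trial) == 2, n_fog_per_trial[1] >= 0,
            n_fog_per_trial[1] <= n_fog_per_trial[2])
  stopifnot(length(fog_duration_s) == 2, fog_duration_s[1] > 0,
            fog_duration_s[1] <= fog_duration_s[2],
            fog_duration_s[2] < trial_duration_s)
  structure(list(
    n_participants = as.integer(n_participants),
    modules = modules,
    trial_duration_s = trial_duration_s,
    resting_duration_s = resting_duration_s,
    fs_hz = fs_hz,
    aperiodic_exponent = exponent,
    peak_freq_hz = peaks,
    fog_power_shift_db = shift,
    fog_burst_scale = fog_burst_scale,
    pre_fog_ramp_s = pre_fog_ramp_s,
    n_fog_per_trial = n_fog_per_trial,
    fog_duration_s = fog_duration_s,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "fog_cohort_spec")
}

#' Compact heterogeneous cohort with participant-flipped FOG signatures
#'
#' A smaller cohort in which the sign of the FOG band-power shift flips
#' across participants (power elevation during FOG for some, reduction for
#' others), emulating the between-participant heterogeneity that motivates
#' per-trial transfer learning: a base model trained across participants
#' with opposing signatures carries conflicting signal for a held-out
#' trial, which the tuning pass on that trial's opening segment helps
#' resolve.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_spec()].
#' @return A `fog_cohort_spec`.
#' @export
heterogeneous_cohort_spec <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(
    n_participants = 3,
    modules = c("physical", "cognitive"),
    peak_freq_hz = c(14, 18, 24),
    fog_power_shift_db = c(7, -7, 7),
    seed = seed
  )
  defaults[names(args)] <- args
  do.call(cohort_spec, defaults)
}

#' @export
print.fog_cohort_spec <- function(x, ...) {
  cat("Synthetic LFP cohort spec:", x$n_participants, "participants x",
      length(x$modules), "modules (", paste(x$modules, collapse = ", "), ")\n")
  cat("  trial", x$trial_duration_s, "s, resting", x$resting_duration_s,
      "s at", x$fs_hz, "Hz; seed", x$seed, "\n")
  cat("  peak freqs:", paste(x$peak_freq_hz, collapse = ", "), "Hz;",
      "FOG power shifts (dB):",
      paste(unique(as.vector(x$fog_power_shift_db)), collapse = ", "), "\n")
  invisible(x)
}
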