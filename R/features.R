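# Feature assembly: per-channel spectral, rolling and burst features with a
# configurable composition, plus correlation pruning.

#' Configure the feature composition
#'
#' The full composition computes, per channel: the z-scored raw series, 5
#' canonical band powers, 3 participant-specific band powers, the 12
#' rolling statistics (4 statistics x 3 windows) of each of those 9 base
#' series, and the time-resolved burst-duration series -- 118 features per
#' channel, 1,416 over the 12 channels.
#'
#' @param families Feature families to include: any of `"raw"`,
#'   `"canonical"`, `"custom"`, `"rolling"`, `"burst"`.
#' @param rolling_windows_s Rolling window lengths in seconds.
#' @param rolling_stats Rolling statistics to compute.
#' @param stride Band-power recomputation stride in samples (1 = literal
#'   per-timepoint sliding window; larger values compute-and-hold).
#' @return A list of class `fog_feature_config`.
#' @export
feature_config <- function(families = c("raw", "canonical", "custom",
                                        "rolling", "burst"),
                           rolling_windows_s = c(0.125, 0.5, 2),
                           rolling_stats = c("mean", "min", "max", "sd"),
                           stride = 1L) {
  families <- match.arg(families, several.ok = TRUE)
  structure(list(families = families,
                 rolling_windows_s = rolling_windows_s,
                 rolling_stats = rolling_stats,
                 stride = as.integer(stride)),
            class = "fog_feature_config")
}

#' Reduced feature composition for desk-scale modelling
#'
#' Canonical and participant-specific band powers plus the burst-duration
#' series (9 features per channel, 108 total), with band powers recomputed
#' every `stride` samples and held. This is the composition the
#' cross-validation experiments run on; the full composition remains
#' available through [feature_config()].
#'
#' @param stride Band-power recomputation stride in samples.
#' @return A `fog_feature_config`.
#' @export
reduced_feature_config <- function(stride = 25L) {
  feature_config(families = c("canonical", "custom", "burst"),
                 stride = stride)
}

#' Assemble the per-trial feature matrix
#'
#' Computes the configured feature families for each of the 12 channels of
#' a (z-scored) channel set and concatenates them with unique names of the
#' form `<channel>|<family>|...`, so every feature is attributable to
#' exactly one channel. All features are causal and free of missing values
#' (warm-up timepoints are back-filled).
#'
#' @param chanset A `fog_channels` set (normally z-scored).
#' @param custom_bands A [find_custom_bands()] result (required when the
#'   `"custom"` family is configured).
#' @param thresholds Named list (one entry per channel label) of
#'   [resting_burst_threshold()] results (required for the `"burst"`
#'   family).
#' @param config A [feature_config()].
#' @return A list of class `fog_features`: `values` (timepoints x features
#'   matrix with column names), `fs_hz`, `channel_of` (channel label per
#'   feature) and trial metadata.
#' @export
assemble_features <- function(chanset, custom_bands = NULL, thresholds = NULL,
                              config = feature_config()) {
  stopifnot(inherits(chanset, "fog_channels"))
  if (length(chanset$channels) == 0) stop("empty channel list", call. = FALSE)
  fs <- chanset$fs_hz
  fam <- config$families
  if ("custom" %in% fam && is.null(custom_bands)) {
    stop("custom bands requested but not supplied", call. = FALSE)
  }
  if ("burst" %in% fam && is.null(thresholds)) {
    stop("burst features requested but no thresholds supplied", call. = FALSE)
  }
  canon <- canonical_bands()
  blocks <- list()
  for (lb in names(chanset$channels)) {
    x <- chanset$channels[[lb]]
    side <- sub("_.*", "", lb)
    base <- list()
    if ("raw" %in% fam) base[[paste0(lb, "|raw")]] <- x
    if ("canonical" %in% fam) {
      for (k in seq_len(nrow(canon))) {
        base[[paste0(lb, "|pow|", canon$name[k])]] <-
          band_power_series(x, canon[k, ], fs, stride = config$stride)
      }
    }
    if ("custom" %in% fam) {
      cb <- custom_bands[[side]]$bands
      for (k in seq_len(nrow(cb))) {
        base[[paste0(lb, "|pow|", cb$name[k])]] <-
          band_power_series(x, cb[k, ], fs, stride = config$stride)
      }
    }
    block <- do.call(cbind, base)
    if ("rolling" %in% fam) {
      rolled <- lapply(names(base), function(nm) {
        r <- rolling_stats(base[[nm]], fs,
                           windows_s = config$rolling_windows_s,
                           stats = config$rolling_stats)
        colnames(r) <- paste0(sub("^([^|]+)\\|", "\\1|roll|", nm), "|",
                              colnames(r))
        r
      })
      block <- cbind(block, do.call(cbind, rolled))
    }
    if ("burst" %in% fam) {
      pk <- trial_peak_freq(x, fs)
      bd <- burst_durations(x, fs, pk, thresholds[[lb]]$threshold)
      block <- cbind(block, matrix(bd$ongoing, ncol = 1,
                                   dimnames = list(NULL,
                                                   paste0(lb, "|burst_dur"))))
    }
    blocks[[lb]] <- block
  }
  counts <- vapply(blocks, ncol, integer(1))
  stopifnot(length(unique(counts)) == 1)   # equal feature count per channel
  values <- do.call(cbind, unname(blocks))
  structure(list(values = values, fs_hz = fs,
                 channel_of = sub("\\|.*", "", colnames(values)),
                 participant_id = chanset$participant_id,
                 module = chanset$module),
            class = "fog_features")
}

#' Drop one member of every highly correlated feature pair
#'
#' Pearson correlations are computed over the supplied timepoints; pairs
#' with `|r| > r_max` are visited in deterministic sorted-name order and
#' one member of each still-surviving pair is dropped, the choice made by
#' the seeded generator. Afterwards no surviving pair exceeds `r_max`.
#'
#' @param values Timepoints x features matrix with column names (pool the
#'   training trials' rows to prune a whole cohort consistently).
#' @param r_max Correlation threshold, default 0.95.
#' @param seed Integer seed for the random member choice.
#' @return A list with `keep` (surviving feature names, original order) and
#'   `dropped` (data.frame `dropped`, `kept`, `r`).
#' @export
prune_correlated <- function(values, r_max = 0.95, seed = 1L) {
  stopifnot(ncol(values) >= 2)
  nm <- colnames(values)
  ord <- order(nm)
  cm <- suppressWarnings(stats::cor(values[, ord, drop = FALSE]))
  cm[!is.finite(cm)] <- 0
  hits <- which(abs(cm) > r_max & upper.tri(cm), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  alive <- rep(TRUE, length(nm))
  names(alive) <- nm[ord]
  dropped <- list()
  rng <- .seeded_rng(seed)
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1]; j <- hits[k, 2]
    ni <- nm[ord][i]; nj <- nm[ord][j]
    if (!alive[ni] || !alive[nj]) next
    out <- if (rng() < 0.5) ni else nj
    keep_one <- if (out == ni) nj else ni
    alive[out] <- FALSE
    dropped[[length(dropped) + 1L]] <-
      data.frame(dropped = out, kept = keep_one, r = cm[i, j],
                 stringsAsFactors = FALSE)
  }
  keep <- nm[nm %in% names(alive)[alive]]
  list(keep = keep,
       dropped = if (length(dropped) > 0) do.call(rbind, dropped)
                 else data.frame(dropped = character(0), kept = character(0),
                                 r = numeric(0)))
}

# Small self-contained uniform generator so pruning's random choices do not
# disturb (or depend on) the caller's RNG stream.
.seeded_rng <- function(seed) {
  state <- as.double(seed %% 2147483647)
  if (state <= 0) state <- 1
  function() {
    state <<- (state * 16807) %% 2147483647
    state / 2147483647
  }
}

#' Featurize a simulated cohort
#'
#' Runs the full per-participant pipeline: derive the 12 channels for every
#' walking trial and the resting recording, z-score per participant across
#' that participant's trials (the resting recording is normalized with the
#' same statistics so resting-derived thresholds live in the same units),
#' locate the participant-specific alpha-beta bands on the resting
#' recording, derive resting burst thresholds per channel, assemble each
#' trial's feature matrix, and optionally prune correlated features over
#' the pooled cohort.
#'
#' @param cohort A [simulate_cohort()] result (or an equivalently shaped
#'   list read by [read_cohort()] with `spec` metadata attached).
#' @param config A [feature_config()].
#' @param prune Prune correlated features (over pooled trials)? Default
#'   `TRUE`.
#' @param r_max Pruning correlation threshold.
#' @param seed Seed for the pruning choices.
#' @return A list of class `fog_cohort_features`: `features` (named list of
#'   `fog_features`, one per trial), `events` (named list of event tables),
#'   `custom_bands`, `thresholds`, `pruning` and `fs_hz`.
#' @export
featurize_cohort <- function(cohort, config = reduced_feature_config(),
                             prune = TRUE, r_max = 0.95, seed = 1L) {
  stopifnot(inherits(cohort, "fog_cohort"))
  participants <- names(cohort$resting)
  feats <- list()
  events <- list()
  custom <- list()
  thresholds <- list()
  for (p in participants) {
    trial_names <- names(cohort$trials)[
      vapply(cohort$trials,
             function(tr) tr$recording$participant_id == p, logical(1))]
    chansets <- lapply(cohort$trials[trial_names],
                       function(tr) derive_channels(tr$recording))
    z <- zscore_participant(chansets)
    rest <- zscore_participant(list(derive_channels(cohort$resting[[p]])),
                               stats = z$stats)$sets[[1]]
    cb <- find_custom_bands(rest)
    th <- lapply(rest$channels, function(x)
      resting_burst_threshold(x, rest$fs_hz))
    custom[[p]] <- cb
    thresholds[[p]] <- th
    for (nm in trial_names) {
      feats[[nm]] <- assemble_features(z$sets[[nm]], cb, th, config)
      events[[nm]] <- cohort$trials[[nm]]$events
    }
  }
  feats <- feats[names(cohort$trials)]
  events <- events[names(cohort$trials)]
  pruning <- NULL
  if (prune && ncol(feats[[1]]$values) >= 2) {
    pooled <- do.call(rbind, lapply(feats, `[[`, "values"))
    pruning <- prune_correlated(pooled, r_max = r_max, seed = seed)
    feats <- lapply(feats, function(fm) {
      keep_idx <- match(pruning$keep, colnames(fm$values))
      fm$values <- fm$values[, keep_idx, drop = FALSE]
      fm$channel_of <- fm$channel_of[keep_idx]
      fm
    })
  }
  structure(list(features = feats, events = events, custom_bands = custom,
                 thresholds = thresholds, pruning = pruning,
                 fs_hz = cohort$spec$fs_hz),
            class = "fog_cohort_features")
}
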