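# Trial/event containers and on-disk formats.
#
# Trials travel as JSON: {participant, module, fs_hz, resting, channels:
# {label: [...]}}. Events travel as CSV with header `start_s,end_s,label`.
# Times are trial-relative seconds with t = 0 at the first sample; event
# intervals are half-open [start, end).

.recorded_channel_labels <- c("Left_0_2", "Left_0_3", "Left_1_3",
                              "Right_0_2", "Right_0_3", "Right_1_3")

#' Construct a validated trial recording
#'
#' @param participant_id Participant identifier string.
#' @param module Module name (or `"resting"`).
#' @param fs_hz Sampling rate in Hz.
#' @param channels Named list of equal-length numeric sample vectors; must
#'   contain the six recorded bipolar labels `Left_0_2`, `Left_0_3`,
#'   `Left_1_3`, `Right_0_2`, `Right_0_3`, `Right_1_3`.
#' @param resting Logical; `TRUE` for seated resting recordings.
#' @return An object of class `fog_trial`.
#' @export
fog_trial <- function(participant_id, module, fs_hz, channels,
                      resting = FALSE) {
  if (!is.list(channels) || is.null(names(channels))) {
    stop("channels must be a named list of sample vectors", call. = FALSE)
  }
  missing <- setdiff(.recorded_channel_labels, names(channels))
  if (length(missing) > 0) {
    stop("missing recorded channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("all channels must have equal length; got lengths ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  if (lens[1] == 0) stop("channels must be non-empty", call. = FALSE)
  if (!is.numeric(fs_hz) || fs_hz <= 0) {
    stop("fs_hz must be a positive sampling rate", call. = FALSE)
  }
  structure(list(participant_id = participant_id, module = module,
                 fs_hz = fs_hz,
                 channels = lapply(channels, as.numeric),
                 resting = isTRUE(resting),
                 duration_s = unname(lens[1]) / fs_hz),
            class = "fog_trial")
}

#' @export
print.fog_trial <- function(x, ...) {
  cat("LFP trial", x$participant_id, "/", x$module,
      if (x$resting) "(resting)" else "", ":",
      length(x$channels), "channels x",
      length(x$channels[[1]]), "samples @", x$fs_hz, "Hz (",
      round(x$duration_s, 2), "s )\n")
  invisible(x)
}

#' Construct a validated FOG event table
#'
#' @param start_s,end_s Numeric vectors of event start/end times in
#'   trial-relative seconds. Intervals are half-open `[start, end)`.
#' @param label Event label, recycled; defaults to `"FOG"`.
#' @return A `data.frame` of class `fog_events`, sorted by start time.
#' @export
fog_events <- function(start_s, end_s, label = "FOG") {
  stopifnot(length(start_s) == length(end_s))
  df <- data.frame(start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   label = rep_len(label, length(start_s)),
                   stringsAsFactors = FALSE)
  bad <- which(df$start_s >= df$end_s)
  if (length(bad) > 0) {
    stop("event row ", bad[1], ": start_s must be < end_s", call. = FALSE)
  }
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1) {
    olap <- which(df$start_s[-1] < df$end_s[-nrow(df)])
    if (length(olap) > 0) {
      stop("event rows ", olap[1], " and ", olap[1] + 1, " overlap",
           call. = FALSE)
    }
  }
  class(df) <- c("fog_events", "data.frame")
  df
}

#' Write a trial recording to JSON
#'
#' @param rec A [fog_trial()].
#' @param path Output path.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path, overwrite = FALSE) {
  stopifnot(inherits(rec, "fog_trial"))
  if (file.exists(path) && !overwrite) {
    stop("file exists and overwrite = FALSE: ", path, call. = FALSE)
  }
  obj <- list(participant = rec$participant_id, module = rec$module,
              fs_hz = rec$fs_hz, resting = rec$resting,
              channels = rec$channels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial recording from JSON
#'
#' Validates the schema: all six recorded channel labels present, equal
#' sample counts, positive sampling rate.
#'
#' @param path Path to a trial JSON file written by [write_trial()].
#' @return A `fog_trial`.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("participant", "module", "fs_hz", "resting", "channels")) {
    if (is.null(obj[[field]])) {
      stop("trial file missing field '", field, "': ", path, call. = FALSE)
    }
  }
  fog_trial(participant_id = obj$participant, module = obj$module,
            fs_hz = obj$fs_hz, channels = as.list(obj$channels),
            resting = obj$resting)
}

#' Write a FOG event table to CSV
#'
#' @param events A [fog_events()] table.
#' @param path Output path.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, overwrite = FALSE) {
  stopifnot(inherits(events, "fog_events"))
  if (file.exists(path) && !overwrite) {
    stop("file exists and overwrite = FALSE: ", path, call. = FALSE)
  }
  utils::write.csv(as.data.frame(unclass(events)), path, row.names = FALSE)
  invisible(path)
}

#' Read FOG event annotations from CSV
#'
#' Expects columns `start_s` and `end_s` (seconds); rows are validated
#' (start < end, within `[0, trial_duration_s]`, non-overlapping after
#' sorting) and returned sorted by start time.
#'
#' @param path Path to the CSV file.
#' @param trial_duration_s Trial duration used for bounds checking.
#' @return A `fog_events` table.
#' @export
read_events <- function(path, trial_duration_s) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s") %in% names(df))) {
    stop("events CSV must have start_s and end_s columns: ", path,
         call. = FALSE)
  }
  bad <- which(df$start_s < 0 | df$end_s > trial_duration_s)
  if (length(bad) > 0) {
    stop("event row ", bad[1], " lies outside [0, ", trial_duration_s,
         "] seconds", call. = FALSE)
  }
  fog_events(df$start_s, df$end_s,
             label = if ("label" %in% names(df)) df$label else "FOG")
}

#' Write a simulated cohort to a directory
#'
#' One trial JSON and one events CSV per trial, one resting JSON per
#' participant, plus a `manifest.json` index recording the file layout and
#' the generator seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite existing files? Default `FALSE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "fog_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cohort$spec$seed, fs_hz = cohort$spec$fs_hz,
                   trials = list(), resting = list())
  for (nm in names(cohort$trials)) {
    tr <- cohort$trials[[nm]]
    tpath <- file.path(dir, paste0(nm, ".json"))
    epath <- file.path(dir, paste0(nm, "_events.csv"))
    write_trial(tr$recording, tpath, overwrite = overwrite)
    write_events(tr$events, epath, overwrite = overwrite)
    manifest$trials[[nm]] <- list(trial = basename(tpath),
                                  events = basename(epath))
  }
  for (nm in names(cohort$resting)) {
    rpath <- file.path(dir, paste0(nm, "_resting.json"))
    write_trial(cohort$resting[[nm]], rpath, overwrite = overwrite)
    manifest$resting[[nm]] <- basename(rpath)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return A list with `trials` (each a list of `recording` and `events`)
#'   and `resting` recordings.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  trials <- lapply(manifest$trials, function(entry) {
    rec <- read_trial(file.path(dir, entry$trial))
    list(recording = rec,
         events = read_events(file.path(dir, entry$events), rec$duration_s))
  })
  resting <- lapply(manifest$resting, function(f) read_trial(file.path(dir, f)))
  list(trials = trials, resting = resting)
}
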