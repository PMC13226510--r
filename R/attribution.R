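# Channel-grouped Shapley attribution via expected (integrated) gradients.

#' Estimate per-input Shapley contributions with a gradient-based approach
#'
#' For each explained window the contribution of every scalar input
#' (timepoint x feature) is estimated by integrated gradients along the
#' straight path from each background reference window to the explained
#' window (midpoint rule with `n_steps` steps), averaged over the
#' background set. The baseline is the mean model output over the same
#' background windows, so baseline + sum(contributions) approximates the
#' window's predicted probability (local accuracy).
#'
#' @param model A trained `fog_model` (ignored when `grad_fn` is given).
#' @param ws Materialized `fog_windows` to explain.
#' @param background Materialized `fog_windows` of background references
#'   (normally sampled from the fold's training windows, see
#'   [sample_background()]).
#' @param n_steps Integration steps per path, default 8.
#' @param grad_fn Optional function `(stacked_matrix, n) ->
#'   list(prob, dx)` overriding the model's [input_gradient()]; lets a
#'   surrogate model with a known closed form stand in during testing.
#' @param chunk_bg Background windows processed per gradient batch.
#' @return A list of class `fog_shap`: `values` (stacked
#'   `(n * win_len) x n_features` contributions), `baseline`, `prob`,
#'   `feature_names`, `n`, `win_len`.
#' @export
estimate_shap <- function(model, ws, background, n_steps = 8L,
                          grad_fn = NULL, chunk_bg = 16L) {
  n_bg <- n_windows(background)
  if (n_bg < 1) stop("background set is empty", call. = FALSE)
  wl <- ws$win_len
  nf <- ncol(ws$values)
  if (is.null(grad_fn)) {
    grad_fn <- function(mat, n) {
      tmp <- structure(list(values = mat, end_idx = wl * seq_len(n),
                            labels = integer(n), end_times_s = numeric(n),
                            mode = "prediction", win_len = wl, fs = ws$fs),
                       class = "fog_windows")
      input_gradient(model, tmp)
    }
  }
  bg_mat <- materialize_windows(background)$values
  baseline <- mean(grad_fn(bg_mat, n_bg)$prob)
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  n <- n_windows(ws)
  contrib <- matrix(0, n * wl, nf)
  prob <- numeric(n)
  for (w in seq_len(n)) {
    rows <- (w - 1L) * wl + seq_len(wl)
    x <- ws$values[rows, , drop = FALSE]
    grad_sum <- matrix(0, wl, nf)  # per background, mean over alphas added
    for (b0 in seq(1L, n_bg, by = chunk_bg)) {
      bs <- b0:min(n_bg, b0 + chunk_bg - 1L)
      paths <- vector("list", length(bs) * n_steps)
      diffs <- vector("list", length(bs))
      i <- 0L
      for (bi in seq_along(bs)) {
        brows <- (bs[bi] - 1L) * wl + seq_len(wl)
        bmat <- bg_mat[brows, , drop = FALSE]
        diffs[[bi]] <- x - bmat
        for (a in alphas) {
          i <- i + 1L
          paths[[i]] <- bmat + a * diffs[[bi]]
        }
      }
      gr <- grad_fn(do.call(rbind, paths), length(paths))$dx
      i <- 0L
      for (bi in seq_along(bs)) {
        gmean <- matrix(0, wl, nf)
        for (s in seq_len(n_steps)) {
          i <- i + 1L
          gmean <- gmean + gr[(i - 1L) * wl + seq_len(wl), , drop = FALSE]
        }
        grad_sum <- grad_sum + diffs[[bi]] * (gmean / n_steps)
      }
    }
    contrib[rows, ] <- grad_sum / n_bg
    prob[w] <- grad_fn(x, 1L)$prob
  }
  structure(list(values = contrib, baseline = baseline, prob = prob,
                 feature_names = colnames(ws$values), n = n, win_len = wl),
            class = "fog_shap")
}

#' Check local accuracy of a Shapley tensor
#'
#' @param shap A `fog_shap`.
#' @return Data.frame with per-window `prob`, `reconstructed`
#'   (baseline + contribution sum) and `abs_error`.
#' @export
shap_additivity <- function(shap) {
  total <- vapply(seq_len(shap$n), function(w) {
    rows <- (w - 1L) * shap$win_len + seq_len(shap$win_len)
    sum(shap$values[rows, ])
  }, numeric(1))
  recon <- shap$baseline + total
  data.frame(window = seq_len(shap$n), prob = shap$prob,
             reconstructed = recon, abs_error = abs(recon - shap$prob))
}

#' Sum contributions over the features of each LFP channel
#'
#' Features are assigned to channels by the `<channel>|...` prefix of
#' their names; the channel groups partition the feature set, so the sum
#' of the group sums equals the total contribution exactly.
#'
#' @param shap A `fog_shap`.
#' @param feature_names Optional override of the feature names.
#' @return A `(n * win_len) x n_channels` matrix of per-channel
#'   contribution sums per window-timepoint.
#' @export
group_by_channel <- function(shap, feature_names = NULL) {
  nms <- if (is.null(feature_names)) shap$feature_names else feature_names
  if (is.null(nms)) stop("no feature names available", call. = FALSE)
  chan <- sub("\\|.*", "", nms)
  if (any(chan == nms)) {
    stop("unmappable feature name(s): ",
         paste(utils::head(nms[chan == nms], 3), collapse = ", "),
         call. = FALSE)
  }
  channels <- unique(chan)
  out <- matrix(0, nrow(shap$values), length(channels),
                dimnames = list(NULL, channels))
  for (ch in channels) {
    out[, ch] <- rowSums(shap$values[, chan == ch, drop = FALSE])
  }
  out
}

#' Partial-dependence summary table for one channel
#'
#' One row per (window, timepoint): the sum of the selected raw feature
#' values of the channel on x, the sum of the corresponding contributions
#' on y, and the channel's time-resolved alpha-beta burst duration as the
#' color variable.
#'
#' @param shap A `fog_shap`.
#' @param ws The materialized windows the tensor explains (raw values).
#' @param channel Channel label, e.g. `"Left_0_2"`.
#' @param subset_regex Regular expression selecting the summed feature
#'   subset within the channel; the default selects band powers and their
#'   rolling metrics.
#' @param burst_feature Name suffix of the burst-duration series used for
#'   coloring (NA color when the feature set lacks it).
#' @return A data.frame with `window`, `timepoint`, `x_sum`, `shap_sum`,
#'   `burst_color`.
#' @export
partial_dependence_table <- function(shap, ws, channel,
                                     subset_regex = "\\|(roll\\|)?pow\\|",
                                     burst_feature = "burst_dur") {
  nms <- shap$feature_names
  sel <- which(startsWith(nms, paste0(channel, "|")) &
                 grepl(subset_regex, nms))
  if (length(sel) == 0) stop("empty feature subset for channel ", channel,
                             call. = FALSE)
  bcol <- which(nms == paste0(channel, "|", burst_feature))
  data.frame(
    window = rep(seq_len(shap$n), each = shap$win_len),
    timepoint = rep(seq_len(shap$win_len), shap$n),
    x_sum = rowSums(ws$values[, sel, drop = FALSE]),
    shap_sum = rowSums(shap$values[, sel, drop = FALSE]),
    burst_color = if (length(bcol) == 1) ws$values[, bcol] else NA_real_)
}

#' Sample a seeded background set from training windows
#'
#' @param train_ws Training `fog_windows`.
#' @param n_background Number of background windows, default 100.
#' @param seed Integer seed.
#' @return A materialized `fog_windows` subset.
#' @export
sample_background <- function(train_ws, n_background = 100L, seed = 1L) {
  n <- n_windows(train_ws)
  set.seed(as.integer(seed %% .Machine$integer.max))
  keep <- sort(sample(n, min(n_background, n)))
  sub <- train_ws
  sub$end_idx <- train_ws$end_idx[keep]
  sub$end_times_s <- train_ws$end_times_s[keep]
  sub$labels <- train_ws$labels[keep]
  materialize_windows(sub)
}
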