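# Training: Adam, class-weighted binary focal loss, learning-rate reduction
# on plateau (monitored by training loss) and early stopping (monitored by
# validation loss), plus the transfer-learning tuning stage that freezes
# the first two convolutional blocks.

#' Training configuration
#'
#' @param epochs Maximum epochs (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Windows per minibatch.
#' @param gamma Focal-loss focusing parameter (default 2).
#' @param class_weights Optional named weights `c("0"=, "1"=)`; computed
#'   from the training labels via [class_weights()] when `NULL`.
#' @param val_fraction Fraction of training windows held out (stratified,
#'   seeded) as the validation monitor for early stopping; 0 monitors the
#'   training loss instead.
#' @param es_patience Early-stopping patience in epochs.
#' @param lr_patience Plateau patience (epochs without training-loss
#'   improvement) before the learning rate is multiplied by `lr_factor`.
#' @param lr_factor,min_lr Learning-rate reduction factor and floor.
#' @param min_delta Minimum loss improvement that resets either patience
#'   counter.
#' @param restore_best Restore the parameters with the best monitored loss
#'   when training stops.
#' @param seed Seed for the validation split, batch shuffling and dropout.
#' @return A list of class `fog_train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 1e-3, batch_size = 256L,
                         gamma = 2, class_weights = NULL, val_fraction = 0.1,
                         es_patience = 5L, lr_patience = 3L,
                         lr_factor = 0.5, min_lr = 1e-8, min_delta = 1e-4,
                         restore_best = TRUE, seed = 1L) {
  stopifnot(epochs >= 1, lr >= 0, batch_size >= 1, gamma >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), gamma = gamma,
                 class_weights = class_weights, val_fraction = val_fraction,
                 es_patience = as.integer(es_patience),
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor, min_lr = min_lr,
                 min_delta = min_delta, restore_best = restore_best,
                 seed = as.integer(seed)),
            class = "fog_train_config")
}

#' Transfer-learning configuration
#'
#' The tuning stage freezes the first two layers (the first two
#' convolutional blocks), drops the learning rate to 5e-6 and trains for up
#' to 100 further epochs with the same optimizer, loss and callbacks.
#'
#' @param frozen_layers Number of leading conv blocks to freeze (default 2).
#' @param lr Tuning learning rate (default 5e-6).
#' @param ... Overrides passed to [train_config()].
#' @return A `fog_train_config` with a `frozen_layers` field.
#' @export
tune_config <- function(frozen_layers = 2L, lr = 5e-6, batch_size = 32L,
                        min_delta = 0, es_patience = 8L, ...) {
  cfg <- train_config(lr = lr, batch_size = batch_size,
                      min_delta = min_delta, es_patience = es_patience, ...)
  cfg$frozen_layers <- as.integer(frozen_layers)
  class(cfg) <- c("fog_tune_config", class(cfg))
  cfg
}

# Class-weighted binary focal loss and its gradient at the logit.
.focal_loss <- function(prob, y, cw, gamma) {
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  w <- ifelse(y == 1, cw[["1"]], cw[["0"]])
  loss <- -w * (1 - pt)^gamma * log(pt)
  # dL/d pt, then chain through pt = y p + (1-y)(1-p) and p = sigmoid(z)
  dpt <- -w * ((1 - pt)^gamma / pt - gamma * (1 - pt)^(gamma - 1) * log(pt))
  dz <- dpt * ifelse(y == 1, 1, -1) * p * (1 - p)
  list(loss = mean(loss), dz = dz / length(y))
}

.adam_zero <- function(params) {
  lapply(params, function(gr) lapply(gr, function(x) x * 0))
}

.adam_update <- function(params, grads, state, lr, step, frozen,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (gname in names(params)) {
    if (gname %in% frozen) next
    for (lname in names(params[[gname]])) {
      gr <- grads[[gname]][[lname]]
      if (is.null(gr)) next
      state$m[[gname]][[lname]] <- beta1 * state$m[[gname]][[lname]] +
        (1 - beta1) * gr
      state$v[[gname]][[lname]] <- beta2 * state$v[[gname]][[lname]] +
        (1 - beta2) * gr^2
      mhat <- state$m[[gname]][[lname]] / bc1
      vhat <- state$v[[gname]][[lname]] / bc2
      params[[gname]][[lname]] <- params[[gname]][[lname]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# Stratified validation indices; guarantees the training remainder keeps
# both classes.
.val_split <- function(labels, fraction) {
  if (fraction <= 0) return(integer(0))
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  take <- function(idx) {
    k <- floor(fraction * length(idx))
    k <- min(k, length(idx) - 1L)
    if (k < 1) integer(0) else sample(idx, k)
  }
  sort(c(take(idx0), take(idx1)))
}

.fit_loop <- function(model, ws, config, frozen = character(0),
                      val_ws = NULL) {
  labels <- ws$labels
  if (length(unique(labels)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  set.seed(config$seed)
  cw <- config$class_weights
  if (is.null(cw)) cw <- class_weights(labels)
  n <- n_windows(ws)
  if (is.null(val_ws)) {
    val_idx <- .val_split(labels, config$val_fraction)
    train_idx <- setdiff(seq_len(n), val_idx)
    monitor_val <- length(val_idx) > 0
  } else {
    # explicit held-out monitor set (e.g. the untouched tail of the tuning
    # span): train on every window of `ws`
    val_idx <- integer(0)
    train_idx <- seq_len(n)
    monitor_val <- n_windows(val_ws) > 0
  }
  state <- list(m = .adam_zero(model$params), v = .adam_zero(model$params))
  # the first conv block's patch matrix only depends on the window set:
  # build it once and slice per batch
  c1 <- list(patch = .im2col_input(ws$values, ws$end_idx, ws$win_len,
                                   model$spec$conv_kernels[1],
                                   model$spec$conv_strides[1],
                                   model$spec$conv_dilations[1]),
             n_full = n)
  lr <- config$lr
  step <- 0L
  best_val <- Inf
  best_train <- Inf
  best_params <- model$params
  wait_es <- 0L
  wait_lr <- 0L
  history <- list()
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(train_idx)
    ep_loss <- 0
    for (start in seq(1L, length(perm), by = config$batch_size)) {
      batch <- perm[start:min(length(perm), start + config$batch_size - 1L)]
      fw <- .nn_forward(model, ws, idx = batch, training = TRUE,
                        keep_cache = TRUE, conv1_cache = c1)
      fl <- .focal_loss(fw$prob, labels[batch], cw, config$gamma)
      if (!is.finite(fl$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (lr=", lr, ", batch of ", length(batch), ")", call. = FALSE)
      }
      g <- .nn_backward(model, fw$cache, fl$dz)
      step <- step + 1L
      upd <- .adam_update(model$params, g, state, lr, step, frozen)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + fl$loss * length(batch)
    }
    train_loss <- ep_loss / length(perm)
    val_loss <- NA_real_
    if (monitor_val) {
      if (is.null(val_ws)) {
        vp <- .nn_forward(model, ws, idx = val_idx, conv1_cache = c1)$prob
        vl <- labels[val_idx]
      } else {
        vp <- .nn_forward(model, val_ws)$prob
        vl <- val_ws$labels
      }
      val_loss <- .focal_loss(vp, vl, cw, config$gamma)$loss
    }
    monitor <- if (monitor_val) val_loss else train_loss
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss, lr = lr)
    # learning-rate reduction on training-loss plateau
    if (train_loss < best_train - config$min_delta) {
      best_train <- train_loss
      wait_lr <- 0L
    } else {
      wait_lr <- wait_lr + 1L
      if (wait_lr >= config$lr_patience) {
        lr <- max(config$min_lr, lr * config$lr_factor)
        wait_lr <- 0L
      }
    }
    # early stopping on the monitored (validation) loss
    if (monitor < best_val - config$min_delta) {
      best_val <- monitor
      best_params <- model$params
      wait_es <- 0L
    } else {
      wait_es <- wait_es + 1L
      if (wait_es >= config$es_patience) break
    }
  }
  if (config$restore_best) model$params <- best_params
  list(model = model, history = do.call(rbind, history))
}

#' Train the base classifier
#'
#' Minimizes the class-weighted binary focal loss with Adam; the learning
#' rate is halved on training-loss plateaus and training stops early when
#' the validation loss stops improving.
#'
#' @param model A `fog_model` from [build_model()].
#' @param ws Training `fog_windows` (both classes must be present).
#' @param config A [train_config()].
#' @return A list with the trained `model` and the per-epoch `history`.
#' @export
train_base <- function(model, ws, config = train_config()) {
  .fit_loop(model, ws, config)
}

#' Transfer-tune a trained classifier on a held-out trial's opening segment
#'
#' Continues training with the first `frozen_layers` conv blocks frozen
#' (their parameters are bit-identical before and after) at the reduced
#' tuning learning rate, personalizing the model to the held-out
#' participant and FOG trigger.
#'
#' @param model A trained `fog_model`.
#' @param ws Tuning windows (normally the augmented first-40 s windows of
#'   the held-out trial).
#' @param config A [tune_config()].
#' @param val_ws Optional clean (non-augmented) window set monitored for
#'   early stopping instead of a random split of `ws` -- a random split
#'   would place jittered copies of training windows in the monitor.
#' @return A list with the tuned `model` and the tuning `history`.
#' @export
transfer_tune <- function(model, ws, config = tune_config(), val_ws = NULL) {
  stopifnot(n_windows(ws) > 0)
  frozen <- paste0("conv", seq_len(config$frozen_layers))
  .fit_loop(model, ws, config, frozen = frozen, val_ws = val_ws)
}
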