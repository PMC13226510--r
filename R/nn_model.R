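# The FOG sequence classifier: a convolutional stack over the 3 s feature
# window, sinusoidal positional encoding, a transformer block, a
# cross-attention block re-querying the convolutional features, a
# bidirectional GRU fed by both the attended and the raw convolutional
# streams (shortcut connection), and a temperature-scaled sigmoid head.

#' Specify the classifier architecture
#'
#' Sizes default to the smallest configuration that exercises every
#' component; all are tunable. The convolutional stack downsamples the
#' 750-sample window with multi-scale kernels so the attention and
#' recurrent stages operate on a short latent sequence.
#'
#' @param n_features Number of input features per timepoint.
#' @param window_len Window length in samples (default 750 = 3 s at 250 Hz).
#' @param conv_filters,conv_kernels,conv_strides,conv_dilations Integer
#'   vectors (one entry per conv block). The first block's default dilation
#'   spaces its taps 25 samples (0.1 s) apart, matching the band-power
#'   recomputation stride, so its receptive field covers 0.7 s of genuinely
#'   varying feature history.
#' @param n_heads Attention heads (must divide the last conv filter count).
#' @param ff_dim Width of the transformer feed-forward layer.
#' @param gru_units Units per GRU direction.
#' @param dense_units Width of the dense head.
#' @param dropout Dropout rate applied to the pooled representation during
#'   training.
#' @param temperature_init Initial value of the learnable temperature that
#'   divides the output logit.
#' @param seed Seed for parameter initialization.
#' @return A list of class `fog_model_spec`.
#' @export
model_spec <- function(n_features, window_len = 750,
                       conv_filters = c(16, 24, 32),
                       conv_kernels = c(7, 5, 3),
                       conv_strides = c(50, 1, 1),
                       conv_dilations = c(25, 1, 1),
                       n_heads = 2, ff_dim = 64, gru_units = 16,
                       dense_units = 16, dropout = 0.2,
                       temperature_init = 1, seed = 1L) {
  stopifnot(length(conv_filters) == length(conv_kernels),
            length(conv_filters) == length(conv_strides),
            length(conv_filters) == length(conv_dilations),
            n_features >= 1, temperature_init > 0)
  d_model <- conv_filters[length(conv_filters)]
  stopifnot(d_model %% n_heads == 0)
  t_len <- window_len
  for (b in seq_along(conv_filters)) {
    span <- (conv_kernels[b] - 1L) * conv_dilations[b] + 1L
    t_len <- (t_len - span) %/% conv_strides[b] + 1L
    if (t_len < 1) stop("conv stack consumes the whole window", call. = FALSE)
  }
  structure(list(n_features = as.integer(n_features),
                 window_len = as.integer(window_len),
                 conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 conv_strides = as.integer(conv_strides),
                 conv_dilations = as.integer(conv_dilations),
                 n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
                 gru_units = as.integer(gru_units),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, temperature_init = temperature_init,
                 latent_len = as.integer(t_len), d_model = as.integer(d_model),
                 seed = as.integer(seed)),
            class = "fog_model_spec")
}

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.attn_params <- function(d_model) {
  list(Wq = .glorot(d_model, d_model), bq = numeric(d_model),
       Wk = .glorot(d_model, d_model), bk = numeric(d_model),
       Wv = .glorot(d_model, d_model), bv = numeric(d_model),
       Wo = .glorot(d_model, d_model), bo = numeric(d_model))
}

.gru_params <- function(d_in, units) {
  list(Wz = .glorot(d_in, units), Wr = .glorot(d_in, units),
       Wh = .glorot(d_in, units), Uz = .glorot(units, units),
       Ur = .glorot(units, units), Uh = .glorot(units, units),
       bz = numeric(units), br = numeric(units), bh = numeric(units))
}

#' Build (initialize) a classifier from its spec
#'
#' Parameter initialization is Glorot-uniform and fully determined by the
#' spec's seed: the same spec yields bit-identical initial parameters.
#'
#' @param spec A [model_spec()].
#' @return A list of class `fog_model` with `spec` and `params`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "fog_model_spec"))
  set.seed(spec$seed)
  d <- spec$d_model
  p <- list()
  c_in <- spec$n_features
  for (b in seq_along(spec$conv_filters)) {
    p[[paste0("conv", b)]] <- list(
      W = .glorot(spec$conv_kernels[b] * c_in, spec$conv_filters[b]),
      b = numeric(spec$conv_filters[b]))
    c_in <- spec$conv_filters[b]
  }
  p$self_attn <- .attn_params(d)
  p$ln1 <- list(gamma = rep(1, d), beta = numeric(d))
  p$ffn <- list(W1 = .glorot(d, spec$ff_dim), b1 = numeric(spec$ff_dim),
                W2 = .glorot(spec$ff_dim, d), b2 = numeric(d))
  p$ln2 <- list(gamma = rep(1, d), beta = numeric(d))
  p$cross_attn <- .attn_params(d)
  p$ln3 <- list(gamma = rep(1, d), beta = numeric(d))
  p$gru_fwd <- .gru_params(2 * d, spec$gru_units)
  p$gru_bwd <- .gru_params(2 * d, spec$gru_units)
  p$dense1 <- list(W = .glorot(2 * spec$gru_units, spec$dense_units),
                   b = numeric(spec$dense_units))
  p$dense2 <- list(W = .glorot(spec$dense_units, 1), b = numeric(1))
  p$temp <- list(log_tau = log(spec$temperature_init))
  structure(list(spec = spec, params = p), class = "fog_model")
}

#' @export
print.fog_model <- function(x, ...) {
  n_par <- sum(vapply(unlist(x$params, recursive = FALSE),
                      length, integer(1)))
  cat("FOG sequence classifier:", x$spec$n_features, "features x",
      x$spec$window_len, "samples ->", x$spec$latent_len,
      "latent steps x", x$spec$d_model, "channels;",
      n_par, "parameters\n")
  invisible(x)
}

#' Total trainable parameter count
#' @param model A `fog_model`.
#' @return Integer number of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

# Full forward pass over a subset of a window set. Returns probabilities
# and, when `keep_cache`, everything the backward pass needs.
.nn_forward <- function(model, ws, idx = NULL, training = FALSE,
                        keep_cache = FALSE, conv1_cache = NULL) {
  sp <- model$spec
  p <- model$params
  end_idx <- if (is.null(idx)) ws$end_idx else ws$end_idx[idx]
  n <- length(end_idx)
  stopifnot(ncol(ws$values) == sp$n_features)
  cache <- list(n = n)
  # conv stack
  t_in <- sp$window_len
  h <- NULL
  for (b in seq_along(sp$conv_filters)) {
    k <- sp$conv_kernels[b]; st <- sp$conv_strides[b]
    dl <- sp$conv_dilations[b]
    if (b == 1) {
      if (!is.null(conv1_cache)) {
        t1 <- (sp$window_len - ((k - 1L) * dl + 1L)) %/% st + 1L
        if (is.null(idx)) idx <- seq_len(conv1_cache$n_full)
        sel <- rep(idx, t1) +
          conv1_cache$n_full * rep(0:(t1 - 1L), each = n)
        patch <- conv1_cache$patch[sel, , drop = FALSE]
      } else {
        patch <- .im2col_input(ws$values, end_idx, sp$window_len, k, st, dl)
      }
    } else {
      patch <- .im2col_hidden(h, n, t_in, k, st)
    }
    pre <- sweep(patch %*% p[[paste0("conv", b)]]$W, 2,
                 p[[paste0("conv", b)]]$b, `+`)
    h_new <- pmax(pre, 0)
    if (keep_cache) {
      cache[[paste0("conv", b)]] <- list(patch = patch, act = h_new > 0,
                                         t_in = t_in)
    }
    t_in <- (t_in - ((k - 1L) * dl + 1L)) %/% st + 1L
    h <- h_new
  }
  t_lat <- sp$latent_len
  h_conv <- h                                    # (n*t_lat) x d_model
  pe <- .positional_encoding(t_lat, sp$d_model)
  h_pos <- h_conv + pe[rep(seq_len(t_lat), each = n), , drop = FALSE]
  # transformer block
  sa <- .mha_fwd(h_pos, h_pos, p$self_attn, n, t_lat, t_lat, sp$n_heads)
  ln1 <- .layernorm_fwd(h_pos + sa$y, p$ln1$gamma, p$ln1$beta)
  ff_pre <- sweep(ln1$y %*% p$ffn$W1, 2, p$ffn$b1, `+`)
  ff_act <- pmax(ff_pre, 0)
  ff_out <- sweep(ff_act %*% p$ffn$W2, 2, p$ffn$b2, `+`)
  ln2 <- .layernorm_fwd(ln1$y + ff_out, p$ln2$gamma, p$ln2$beta)
  # cross-attention: transformer output queries the conv features
  ca <- .mha_fwd(ln2$y, h_pos, p$cross_attn, n, t_lat, t_lat, sp$n_heads)
  ln3 <- .layernorm_fwd(ln2$y + ca$y, p$ln3$gamma, p$ln3$beta)
  # recurrent stage on [attended, conv shortcut]
  g_in <- cbind(ln3$y, h_conv)
  gf <- .gru_fwd(g_in, p$gru_fwd, n, t_lat, reverse = FALSE)
  gb <- .gru_fwd(g_in, p$gru_bwd, n, t_lat, reverse = TRUE)
  g_out <- cbind(gf$hs, gb$hs)
  pooled <- .time_pool(g_out, n, t_lat)
  drop_mask <- NULL
  if (training && sp$dropout > 0) {
    drop_mask <- matrix(stats::rbinom(length(pooled), 1, 1 - sp$dropout),
                        nrow(pooled)) / (1 - sp$dropout)
    pooled <- pooled * drop_mask
  }
  d1_pre <- sweep(pooled %*% p$dense1$W, 2, p$dense1$b, `+`)
  d1 <- pmax(d1_pre, 0)
  u <- as.vector(d1 %*% p$dense2$W) + p$dense2$b
  tau <- exp(p$temp$log_tau)
  z <- u / tau
  prob <- .sigmoid(z)
  if (!keep_cache) return(list(prob = prob))
  cache$h_conv <- h_conv; cache$h_pos <- h_pos
  cache$sa <- sa; cache$ln1 <- ln1
  cache$ff_act <- ff_act; cache$ln1y <- ln1$y
  cache$ln2 <- ln2; cache$ca <- ca; cache$ln3 <- ln3
  cache$g_in <- g_in; cache$gf <- gf; cache$gb <- gb
  cache$pooled <- pooled; cache$drop_mask <- drop_mask
  cache$d1 <- d1; cache$u <- u; cache$z <- z; cache$tau <- tau
  cache$t_lat <- t_lat
  list(prob = prob, cache = cache)
}

# Backward pass from dL/dz (gradient at the pre-sigmoid, post-temperature
# logit). Returns parameter gradients and optionally the gradient w.r.t.
# the stacked window input (materialized windows only).
.nn_backward <- function(model, cache, dz, need_dx = FALSE) {
  sp <- model$spec
  p <- model$params
  n <- cache$n
  t_lat <- cache$t_lat
  g <- list()
  # head
  du <- dz / cache$tau
  g$temp <- list(log_tau = sum(dz * (-cache$z)))
  g$dense2 <- list(W = crossprod(cache$d1, matrix(du, ncol = 1)),
                   b = sum(du))
  dd1 <- (matrix(du, ncol = 1) %*% t(p$dense2$W)) * (cache$d1 > 0)
  g$dense1 <- list(W = crossprod(cache$pooled, dd1), b = colSums(dd1))
  dpooled <- dd1 %*% t(p$dense1$W)
  if (!is.null(cache$drop_mask)) dpooled <- dpooled * cache$drop_mask
  dg_out <- (1 / t_lat) * dpooled[rep(seq_len(n), t_lat), , drop = FALSE]
  u <- sp$gru_units
  bf <- .gru_bwd(cache$gf, p$gru_fwd, dg_out[, seq_len(u), drop = FALSE],
                 n, t_lat)
  bb <- .gru_bwd(cache$gb, p$gru_bwd, dg_out[, u + seq_len(u), drop = FALSE],
                 n, t_lat)
  g$gru_fwd <- bf$grads
  g$gru_bwd <- bb$grads
  dg_in <- bf$dx + bb$dx
  d <- sp$d_model
  dln3y <- dg_in[, seq_len(d), drop = FALSE]
  dh_conv <- dg_in[, d + seq_len(d), drop = FALSE]   # shortcut branch
  ln3b <- .layernorm_bwd(cache$ln3, p$ln3$gamma, dln3y)
  g$ln3 <- list(gamma = ln3b$dgamma, beta = ln3b$dbeta)
  cab <- .mha_bwd(cache$ca, p$cross_attn, ln3b$dx)
  g$cross_attn <- cab$grads
  dln2y <- ln3b$dx + cab$dhq
  dh_pos <- cab$dhkv
  ln2b <- .layernorm_bwd(cache$ln2, p$ln2$gamma, dln2y)
  g$ln2 <- list(gamma = ln2b$dgamma, beta = ln2b$dbeta)
  dff_act <- (ln2b$dx %*% t(p$ffn$W2)) * (cache$ff_act > 0)
  g$ffn <- list(W1 = crossprod(cache$ln1y, dff_act), b1 = colSums(dff_act),
                W2 = crossprod(cache$ff_act, ln2b$dx), b2 = colSums(ln2b$dx))
  dln1y <- ln2b$dx + dff_act %*% t(p$ffn$W1)
  ln1b <- .layernorm_bwd(cache$ln1, p$ln1$gamma, dln1y)
  g$ln1 <- list(gamma = ln1b$dgamma, beta = ln1b$dbeta)
  sab <- .mha_bwd(cache$sa, p$self_attn, ln1b$dx)
  g$self_attn <- sab$grads
  dh_pos <- dh_pos + ln1b$dx + sab$dhq + sab$dhkv
  dh <- dh_conv + dh_pos                            # positional enc is const
  # conv stack backward
  for (b in rev(seq_along(sp$conv_filters))) {
    cc <- cache[[paste0("conv", b)]]
    dpre <- dh * cc$act
    g[[paste0("conv", b)]] <- list(W = crossprod(cc$patch, dpre),
                                   b = colSums(dpre))
    if (b > 1) {
      dpatch <- dpre %*% t(p[[paste0("conv", b)]]$W)
      dh <- .col2im_hidden(dpatch, n, cc$t_in, sp$conv_filters[b - 1],
                           sp$conv_kernels[b], sp$conv_strides[b])
    } else if (need_dx) {
      dpatch <- dpre %*% t(p$conv1$W)
      g$dx <- .col2im_input(dpatch, n, sp$window_len, sp$n_features,
                            sp$conv_kernels[1], sp$conv_strides[1],
                            sp$conv_dilations[1])
    }
  }
  g
}

#' Predict the FOG probability series for a prediction-grid window set
#'
#' Inference is deterministic (no dropout) and causal: each probability
#' uses only the 3 s of data ending at its grid point, so truncating
#' future inputs leaves past outputs unchanged.
#'
#' @param model A trained `fog_model`.
#' @param ws A `fog_windows` set (normally prediction-grid).
#' @param batch_size Windows per forward batch.
#' @return A list of class `fog_probs` with `end_times_s`, `prob` and the
#'   window `labels`.
#' @export
predict_series <- function(model, ws, batch_size = 512L) {
  n <- n_windows(ws)
  prob <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    prob[idx] <- .nn_forward(model, ws, idx = idx)$prob
  }
  structure(list(end_times_s = ws$end_times_s, prob = prob,
                 labels = ws$labels),
            class = "fog_probs")
}

#' Gradient of the predicted probability with respect to the window input
#'
#' Used by the gradient-based Shapley estimator. Requires materialized
#' windows (explicit stacked rows).
#'
#' @param model A `fog_model`.
#' @param ws A materialized `fog_windows` set.
#' @param idx Optional window subset.
#' @return A list with `prob` (length n) and `dx`, the
#'   `(n * window_len) x n_features` stacked gradient.
#' @export
input_gradient <- function(model, ws, idx = NULL) {
  fw <- .nn_forward(model, ws, idx = idx, keep_cache = TRUE)
  p <- fw$prob
  dz <- p * (1 - p)            # d prob / d logit
  g <- .nn_backward(model, fw$cache, dz, need_dx = TRUE)
  list(prob = p, dx = g$dx)
}
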