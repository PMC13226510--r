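# Neural-network building blocks with hand-derived backward passes.
#
# Batched sequence activations are stored as (n * T) x C matrices in
# window-major order: row r = w + (t - 1) * n holds window w, timestep t.
# This makes every dense transform a single BLAS matmul and lets attention
# run as O(T) vectorized sweeps instead of per-window loops.

# ---- im2col / col2im for strided 1-D convolution --------------------------

# Patch matrix for windows referenced into a backing feature matrix.
# Output rows ordered window-major; columns grouped by kernel tap j then
# input feature. Rows before the first sample are clamped (back-filled).
.im2col_input <- function(values, end_idx, win_len, k, stride, dil = 1L) {
  n <- length(end_idx)
  span <- (k - 1L) * dil + 1L
  t_out <- (win_len - span) %/% stride + 1L
  base <- end_idx - win_len                       # 0-based offsets
  p_off <- rep((seq_len(t_out) - 1L) * stride, each = n)
  out <- matrix(0, n * t_out, k * ncol(values))
  for (j in seq_len(k)) {
    rows <- pmax(rep(base, t_out) + p_off + (j - 1L) * dil + 1L, 1L)
    out[, (j - 1L) * ncol(values) + seq_len(ncol(values))] <-
      values[rows, , drop = FALSE]
  }
  out
}

# Scatter patch gradients back onto the (n * win_len) x F stacked input.
# Only valid for materialized windows (disjoint rows, no clamping).
.col2im_input <- function(dpatch, n, win_len, n_feat, k, stride, dil = 1L) {
  span <- (k - 1L) * dil + 1L
  t_out <- (win_len - span) %/% stride + 1L
  dx <- matrix(0, n * win_len, n_feat)
  base <- (seq_len(n) - 1L) * win_len
  p_off <- rep((seq_len(t_out) - 1L) * stride, each = n)
  for (j in seq_len(k)) {
    rows <- rep(base, t_out) + p_off + (j - 1L) * dil + 1L
    dx[rows, ] <- dx[rows, ] + dpatch[, (j - 1L) * n_feat + seq_len(n_feat)]
  }
  dx
}

# Patch matrix over a window-major hidden activation (n * t_in) x C.
.im2col_hidden <- function(hmat, n, t_in, k, stride) {
  c_in <- ncol(hmat)
  t_out <- (t_in - k) %/% stride + 1L
  p_off <- rep((seq_len(t_out) - 1L) * stride, each = n)
  w_idx <- rep(seq_len(n), t_out)
  out <- matrix(0, n * t_out, k * c_in)
  for (j in seq_len(k)) {
    rows <- w_idx + n * (p_off + j - 1L)
    out[, (j - 1L) * c_in + seq_len(c_in)] <- hmat[rows, , drop = FALSE]
  }
  out
}

.col2im_hidden <- function(dpatch, n, t_in, c_in, k, stride) {
  t_out <- (t_in - k) %/% stride + 1L
  p_off <- rep((seq_len(t_out) - 1L) * stride, each = n)
  w_idx <- rep(seq_len(n), t_out)
  dh <- matrix(0, n * t_in, c_in)
  for (j in seq_len(k)) {
    rows <- w_idx + n * (p_off + j - 1L)
    dh[rows, ] <- dh[rows, ] + dpatch[, (j - 1L) * c_in + seq_len(c_in)]
  }
  dh
}

# ---- layer norm -----------------------------------------------------------

.layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat * rep(1, nrow(x)) %o% gamma, 2, beta, `+`),
       xhat = xhat, inv = inv)
}

.layernorm_bwd <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  dxhat <- dy * rep(1, nrow(dy)) %o% gamma
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

# ---- multi-head attention -------------------------------------------------

# Forward: window-major Q-side activations (n*tq x d_model) attend over
# K/V-side (n*tk x d_model). Returns per-head score tensors for backward.
.mha_fwd <- function(hq, hkv, w, n, tq, tk, n_heads) {
  d_model <- ncol(hq)
  dh <- d_model / n_heads
  q <- hq %*% w$Wq; q <- sweep(q, 2, w$bq, `+`)
  k <- hkv %*% w$Wk; k <- sweep(k, 2, w$bk, `+`)
  v <- hkv %*% w$Wv; v <- sweep(v, 2, w$bv, `+`)
  scale <- 1 / sqrt(dh)
  o_all <- matrix(0, n * tq, d_model)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    qh <- q[, cols, drop = FALSE]
    kh <- k[, cols, drop = FALSE]
    vh <- v[, cols, drop = FALSE]
    s <- array(0, c(n, tq, tk))
    for (j in seq_len(tk)) {
      krep <- kh[(j - 1) * n + seq_len(n), , drop = FALSE][rep(seq_len(n), tq), ,
                                                           drop = FALSE]
      s[, , j] <- matrix(rowSums(qh * krep) * scale, n, tq)
    }
    mx <- s[, , 1]
    if (tk > 1) for (j in 2:tk) mx <- pmax(mx, s[, , j])
    p <- array(0, c(n, tq, tk))
    tot <- matrix(0, n, tq)
    for (j in seq_len(tk)) {
      p[, , j] <- exp(s[, , j] - mx)
      tot <- tot + p[, , j]
    }
    oh <- matrix(0, n * tq, dh)
    for (j in seq_len(tk)) {
      p[, , j] <- p[, , j] / tot
      vrep <- vh[(j - 1) * n + seq_len(n), , drop = FALSE][rep(seq_len(n), tq), ,
                                                           drop = FALSE]
      oh <- oh + as.vector(p[, , j]) * vrep
    }
    o_all[, cols] <- oh
    heads[[h]] <- list(p = p, qh = qh, kh = kh, vh = vh)
  }
  y <- o_all %*% w$Wo
  y <- sweep(y, 2, w$bo, `+`)
  list(y = y, o_all = o_all, heads = heads, q = q, k = k, v = v,
       hq = hq, hkv = hkv, n = n, tq = tq, tk = tk, n_heads = n_heads)
}

# Backward: returns gradients for the weight block plus dhq / dhkv.
.mha_bwd <- function(cache, w, dy) {
  n <- cache$n; tq <- cache$tq; tk <- cache$tk
  n_heads <- cache$n_heads
  d_model <- ncol(dy)
  dh <- d_model / n_heads
  scale <- 1 / sqrt(dh)
  grads <- list(Wo = crossprod(cache$o_all, dy), bo = colSums(dy))
  do_all <- dy %*% t(w$Wo)
  dq <- matrix(0, n * tq, d_model)
  dk <- matrix(0, n * tk, d_model)
  dv <- matrix(0, n * tk, d_model)
  grp <- rep(seq_len(n), tq)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1) * dh + seq_len(dh)
    hd <- cache$heads[[h]]
    doh <- do_all[, cols, drop = FALSE]
    dp <- array(0, c(n, tq, tk))
    for (j in seq_len(tk)) {
      vrep <- hd$vh[(j - 1) * n + seq_len(n), , drop = FALSE][grp, , drop = FALSE]
      dp[, , j] <- matrix(rowSums(doh * vrep), n, tq)
      dv[(j - 1) * n + seq_len(n), cols] <-
        rowsum(as.vector(hd$p[, , j]) * doh, grp)
    }
    srow <- matrix(0, n, tq)
    for (j in seq_len(tk)) srow <- srow + dp[, , j] * hd$p[, , j]
    dqh <- matrix(0, n * tq, dh)
    for (j in seq_len(tk)) {
      ds_j <- hd$p[, , j] * (dp[, , j] - srow)
      krep <- hd$kh[(j - 1) * n + seq_len(n), , drop = FALSE][grp, , drop = FALSE]
      dqh <- dqh + as.vector(ds_j) * krep * scale
      dk[(j - 1) * n + seq_len(n), cols] <-
        dk[(j - 1) * n + seq_len(n), cols, drop = FALSE] +
        rowsum(as.vector(ds_j) * hd$qh, grp) * scale
    }
    dq[, cols] <- dqh
  }
  grads$Wq <- crossprod(cache$hq, dq); grads$bq <- colSums(dq)
  grads$Wk <- crossprod(cache$hkv, dk); grads$bk <- colSums(dk)
  grads$Wv <- crossprod(cache$hkv, dv); grads$bv <- colSums(dv)
  list(grads = grads,
       dhq = dq %*% t(w$Wq),
       dhkv = dk %*% t(w$Wk) + dv %*% t(w$Wv))
}

# ---- GRU ------------------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

# One direction over window-major input (n*t_in x d_in). `reverse` runs
# time backwards. Returns window-major hidden states (n*t_in x units).
.gru_fwd <- function(x, w, n, t_in, reverse = FALSE) {
  units <- ncol(w$Uz)
  h_prev <- matrix(0, n, units)
  steps <- if (reverse) rev(seq_len(t_in)) else seq_len(t_in)
  hs <- matrix(0, n * t_in, units)
  cache <- vector("list", t_in)
  for (s in seq_along(steps)) {
    t <- steps[s]
    rows <- (t - 1) * n + seq_len(n)
    xt <- x[rows, , drop = FALSE]
    z <- .sigmoid(sweep(xt %*% w$Wz + h_prev %*% w$Uz, 2, w$bz, `+`))
    r <- .sigmoid(sweep(xt %*% w$Wr + h_prev %*% w$Ur, 2, w$br, `+`))
    hh <- tanh(sweep(xt %*% w$Wh + (r * h_prev) %*% w$Uh, 2, w$bh, `+`))
    h <- (1 - z) * h_prev + z * hh
    hs[rows, ] <- h
    cache[[s]] <- list(xt = xt, z = z, r = r, hh = hh, h_prev = h_prev,
                       rows = rows)
    h_prev <- h
  }
  list(hs = hs, cache = cache, steps = steps)
}

.gru_bwd <- function(fwd, w, dhs, n, t_in) {
  units <- ncol(w$Uz)
  d_in <- nrow(w$Wz)
  g <- list(Wz = matrix(0, d_in, units), Wr = matrix(0, d_in, units),
            Wh = matrix(0, d_in, units), Uz = matrix(0, units, units),
            Ur = matrix(0, units, units), Uh = matrix(0, units, units),
            bz = numeric(units), br = numeric(units), bh = numeric(units))
  dx <- matrix(0, nrow(dhs), d_in)
  dh_next <- matrix(0, n, units)
  for (s in rev(seq_len(t_in))) {
    cc <- fwd$cache[[s]]
    dh <- dhs[cc$rows, , drop = FALSE] + dh_next
    dz_pre <- dh * (cc$hh - cc$h_prev) * cc$z * (1 - cc$z)
    dhh_pre <- dh * cc$z * (1 - cc$hh^2)
    dr_pre <- (dhh_pre %*% t(w$Uh)) * cc$h_prev * cc$r * (1 - cc$r)
    g$Wz <- g$Wz + crossprod(cc$xt, dz_pre)
    g$Wr <- g$Wr + crossprod(cc$xt, dr_pre)
    g$Wh <- g$Wh + crossprod(cc$xt, dhh_pre)
    g$Uz <- g$Uz + crossprod(cc$h_prev, dz_pre)
    g$Ur <- g$Ur + crossprod(cc$h_prev, dr_pre)
    g$Uh <- g$Uh + crossprod(cc$r * cc$h_prev, dhh_pre)
    g$bz <- g$bz + colSums(dz_pre)
    g$br <- g$br + colSums(dr_pre)
    g$bh <- g$bh + colSums(dhh_pre)
    dx[cc$rows, ] <- dz_pre %*% t(w$Wz) + dr_pre %*% t(w$Wr) +
      dhh_pre %*% t(w$Wh)
    dh_next <- dh * (1 - cc$z) +
      ((dhh_pre %*% t(w$Uh)) * cc$r) +
      dz_pre %*% t(w$Uz) + dr_pre %*% t(w$Ur)
  }
  list(grads = g, dx = dx)
}

# ---- misc -----------------------------------------------------------------

# Sinusoidal positional encoding, T x C.
.positional_encoding <- function(t_len, d_model) {
  pos <- seq_len(t_len) - 1
  pe <- matrix(0, t_len, d_model)
  for (i in seq_len(ceiling(d_model / 2))) {
    angle <- pos / (10000^((2 * (i - 1)) / d_model))
    pe[, 2 * i - 1] <- sin(angle)
    if (2 * i <= d_model) pe[, 2 * i] <- cos(angle)
  }
  pe
}

# Mean over the time dimension of a window-major matrix -> n x C.
.time_pool <- function(x, n, t_in) {
  out <- matrix(0, n, ncol(x))
  for (t in seq_len(t_in)) out <- out + x[(t - 1) * n + seq_len(n), ,
                                          drop = FALSE]
  out / t_in
}
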