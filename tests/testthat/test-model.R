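# The sequence classifier: initialization, gradients, training behaviour,
# transfer-tuning contracts, prediction semantics.

test_that("initialization is deterministic and outputs are probabilities", {
  sp <- tiny_model_spec(n_features = 4)
  m1 <- build_model(sp)
  m2 <- build_model(sp)
  expect_identical(m1$params, m2$params)
  ws <- random_windows(6, 60, 4, seed = 31)
  p <- predict_series(m1, ws)$prob
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict_series(m1, ws)$prob)   # inference determinism
})

test_that("parameter count equals the layer-by-layer closed form", {
  sp <- tiny_model_spec(n_features = 4)
  m <- build_model(sp)
  d <- 8; ff <- 10; g <- 3; dn <- 5
  expected <-
    (5 * 4 * 4 + 4) + (3 * 4 * 6 + 6) + (3 * 6 * 8 + 8) +   # conv stack
    2 * (4 * (d * d + d)) +                                 # two MHA blocks
    3 * (2 * d) +                                           # three layer norms
    (d * ff + ff + ff * d + d) +                            # transformer FFN
    2 * (3 * (2 * d) * g + 3 * g * g + 3 * g) +             # BiGRU
    (2 * g * dn + dn) + (dn * 1 + 1) +                      # dense head
    1                                                       # temperature
  expect_identical(n_parameters(m), as.integer(expected))
})

test_that("analytic gradients match finite differences", {
  set.seed(33)
  sp <- tiny_model_spec(n_features = 3)
  m <- build_model(sp)
  ws <- random_windows(5, 60, 3, seed = 34)
  cw <- c("0" = 1.1, "1" = 0.9)
  loss_at <- function(model) {
    fogdetect:::.focal_loss(fogdetect:::.nn_forward(model, ws)$prob,
                            ws$labels, cw, 2)$loss
  }
  fw <- fogdetect:::.nn_forward(m, ws, keep_cache = TRUE)
  fl <- fogdetect:::.focal_loss(fw$prob, ws$labels, cw, 2)
  g <- fogdetect:::.nn_backward(m, fw$cache, fl$dz, need_dx = TRUE)
  eps <- 1e-6
  for (gname in names(m$params)) {
    for (lname in names(m$params[[gname]])) {
      par <- m$params[[gname]][[lname]]
      for (i in sample(length(par), min(3, length(par)))) {
        mp <- m; mp$params[[gname]][[lname]][i] <- par[i] + eps
        mm <- m; mm$params[[gname]][[lname]][i] <- par[i] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(g[[gname]][[lname]][i], num, tolerance = 1e-4,
                     label = paste("grad", gname, lname, i))
      }
    }
  }
  # input gradients (used by the Shapley estimator)
  ig <- input_gradient(m, ws)
  for (i in sample(length(ws$values), 5)) {
    wp <- ws; wp$values[i] <- ws$values[i] + eps
    wm <- ws; wm$values[i] <- ws$values[i] - eps
    num <- (sum(fogdetect:::.nn_forward(m, wp)$prob) -
              sum(fogdetect:::.nn_forward(m, wm)$prob)) / (2 * eps)
    expect_equal(ig$dx[i], num, tolerance = 1e-4)
  }
})

test_that("training separates a linearly separable construction", {
  ws <- random_windows(n = 120, win_len = 60, n_features = 4, seed = 35,
                       sep = 2.5)
  sp <- tiny_model_spec(n_features = 4, seed = 36)
  fit <- train_base(build_model(sp), ws,
                    train_config(epochs = 60, batch_size = 32, seed = 37))
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  pr <- predict_series(fit$model, ws)
  expect_gt(timepoint_metrics(ws$labels, pr$prob)$weighted_f1, 0.9)
  expect_error(train_base(build_model(sp),
                          {w <- ws; w$labels <- rep(1L, n_windows(w)); w}),
               "single class")
})

test_that("learning rate is reduced on a training-loss plateau", {
  ws <- random_windows(30, 60, 3, seed = 38)
  sp <- tiny_model_spec(n_features = 3)
  # a huge min_delta makes every epoch a plateau epoch
  cfg <- train_config(epochs = 8, lr = 1e-3, min_delta = 10,
                      lr_patience = 2, lr_factor = 0.5, es_patience = 99,
                      val_fraction = 0, seed = 39)
  fit <- train_base(build_model(sp), ws, cfg)
  expect_equal(fit$history$lr[1:8],
               1e-3 * c(1, 1, 1, 0.5, 0.5, 0.25, 0.25, 0.125))
})

test_that("transfer tuning freezes the first two conv blocks bit-exactly", {
  ws <- random_windows(40, 60, 4, seed = 40, sep = 1)
  sp <- tiny_model_spec(n_features = 4, seed = 41)
  base <- train_base(build_model(sp), ws,
                     train_config(epochs = 5, batch_size = 16, seed = 42))
  tuned <- transfer_tune(base$model, ws,
                         tune_config(epochs = 5, lr = 1e-3, batch_size = 16,
                                     restore_best = FALSE, seed = 43))
  expect_identical(tuned$model$params$conv1, base$model$params$conv1)
  expect_identical(tuned$model$params$conv2, base$model$params$conv2)
  expect_false(identical(tuned$model$params$dense2, base$model$params$dense2))
  # zero learning rate leaves every parameter untouched
  frozen <- transfer_tune(base$model, ws,
                          tune_config(epochs = 3, lr = 0, batch_size = 16,
                                      restore_best = FALSE, seed = 44))
  expect_identical(frozen$model$params, base$model$params)
})

test_that("temperature sharpens probabilities without changing decisions", {
  sp <- tiny_model_spec(n_features = 3, seed = 45)
  m <- build_model(sp)
  ws <- random_windows(20, 60, 3, seed = 46)
  p1 <- predict_series(m, ws)$prob
  m$params$temp$log_tau <- m$params$temp$log_tau - 1   # lower temperature
  p2 <- predict_series(m, ws)$prob
  expect_true(all(abs(p2 - 0.5) >= abs(p1 - 0.5) - 1e-12))
  expect_identical(p1 >= 0.5, p2 >= 0.5)
})

test_that("prediction series are causal over the grid", {
  fs <- 250
  set.seed(47)
  n <- round(20 * fs)
  fm <- structure(list(values = matrix(stats::rnorm(n * 3), n, 3),
                       fs_hz = fs), class = "fog_features")
  tl <- integer(n)
  sp <- model_spec(n_features = 3, seed = 48)
  m <- build_model(sp)
  full <- build_windows(fm, tl, "prediction", span_start_s = 5)
  p_full <- predict_series(m, full)$prob
  # drop the final 5 s of input: earlier predictions are unchanged
  fm2 <- fm; fm2$values <- fm$values[1:round(15 * fs), , drop = FALSE]
  short <- build_windows(fm2, integer(round(15 * fs)), "prediction",
                         span_start_s = 5)
  p_short <- predict_series(m, short)$prob
  expect_equal(p_short, p_full[seq_along(p_short)])
  # a 60.5 s span yields 122 probabilities (span / 0.5 + 1)
  big <- structure(list(values = matrix(0, round(63.5 * fs) + 1, 3),
                        fs_hz = fs), class = "fog_features")
  ws2 <- build_windows(big, integer(nrow(big$values)), "prediction",
                       span_start_s = 3)
  expect_identical(n_windows(ws2), 122L)
})
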