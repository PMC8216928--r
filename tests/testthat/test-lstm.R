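# The sequence model: shape contracts, seeded determinism, gradient
# correctness against central finite differences, training behaviour.

test_that("built models honour the shape contract and seeded init", {
  cfg <- model_config(layer_dim = 8L, seed = 21L)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(params_to_vec(m1), params_to_vec(m2))

  x <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
  fw <- lstm_forward(m1, x)
  expect_equal(dim(fw$yhat), c(3, 6))   # one prediction per window month

  # wider input channels are accepted (generalization retained)
  cfg3 <- model_config(layer_dim = 8L, input_channels = 3L, seed = 1L)
  m3 <- build_model(cfg3)
  x3 <- array(rnorm(2 * 6 * 3), c(2, 6, 3))
  expect_equal(dim(lstm_forward(m3, x3)$yhat), c(2, 6))

  expect_error(model_config(layer_dim = 0L), "config error")
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(layer_dim = 5L, seed = 42L)
  m <- build_model(cfg)
  set.seed(7)
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  y <- matrix(rnorm(4 * 6), 4, 6)
  fw <- lstm_forward(m, x, keep_cache = TRUE)
  g_an <- grads_to_vec(lstm_backward(m, fw, y))
  theta <- params_to_vec(m)
  lossfn <- function(v) {
    f <- lstm_forward(vec_to_params(m, v), x)
    mean((f$yhat - y)^2)
  }
  eps <- 1e-6
  idx <- sort(sample(seq_along(theta), 60))
  g_num <- vapply(idx, function(k) {
    vp <- theta; vp[k] <- vp[k] + eps
    vm <- theta; vm[k] <- vm[k] - eps
    (lossfn(vp) - lossfn(vm)) / (2 * eps)
  }, double(1))
  expect_lt(max(abs(g_num - g_an[idx])), 1e-7)
})

test_that("training is deterministic and learns a constant target", {
  set.seed(3)
  x <- array(rnorm(30 * 6 * 2), c(30, 6, 2))
  y <- matrix(0.42, 30, 6)
  train <- structure(list(x = x, y = y, pixel_id = 1), class = "windowed_samples")
  cfg <- model_config(layer_dim = 8L, max_epochs = 150L, patience = 20L,
                      batch_size = 8L, learning_rate = 1e-2, seed = 13L)
  m1 <- train_pixel(build_model(cfg), train, cfg)
  m2 <- train_pixel(build_model(cfg), train, cfg)
  expect_identical(m1$fit$loss_history, m2$fit$loss_history)
  expect_identical(params_to_vec(m1), params_to_vec(m2))
  expect_lt(m1$fit$train_rmse, 0.01)
  expect_equal(length(m1$fit$loss_history), m1$fit$epochs_run)

  # best-so-far loss is non-increasing and the checkpoint equals its minimum
  best_path <- cummin(m1$fit$loss_history)
  expect_true(all(diff(best_path) <= 0))
  # checkpointed parameters reproduce the best epoch loss up to the drift
  # between the epoch-mean minibatch loss and the end-of-epoch parameters
  fw <- lstm_forward(m1, x)
  expect_lte(mean((fw$yhat - y)^2), min(m1$fit$loss_history) + 1e-6)
})

test_that("a trained model fits a noise-free pixel and predicts in order", {
  fx <- fitted_tiny_model()
  expect_true(fx$model$trained)
  expect_lt(fx$model$fit$train_rmse, 0.05)

  pred1 <- predict_pixel(fx$model, fx$sw$val)
  pred2 <- predict_pixel(fx$model, fx$sw$val)
  expect_identical(pred1, pred2)                   # pure function
  expect_length(pred1, dim(fx$sw$val$x)[1] * 6)    # one value per month

  expect_error(predict_pixel(build_model(fx$cfg), fx$sw$val), "state error")
})

test_that("fit_grid trains one independent seeded model per pixel", {
  spec <- grid_spec(2, 2, fine_factor = 1, n_years = 4)
  params <- response_params(w_T = 0.3, w_P = 0.2, noise_sd = 0, ar_coef = 0)
  clim <- generate_climate(spec, params, seed = 6, temp_noise_sd = 0,
                           precip_noise_sd = 0)
  nd <- mvc_composite(generate_ndvi(clim, spec, params, seed = 6)$ndvi)
  ds <- filter_valid_pixels(nd, clim, train_months = 36L)
  cfg <- model_config(layer_dim = 8L, max_epochs = 8L, seed = 2L)
  g1 <- fit_grid(ds, cfg)
  expect_equal(nrow(g1$fits), 4)
  expect_length(g1$failures, 0)
  # per-pixel seeds differ, so the fitted parameters differ across pixels
  expect_false(identical(params_to_vec(g1$models[[1]]),
                         params_to_vec(g1$models[[2]])))
  g2 <- fit_grid(ds, cfg)
  expect_identical(g1$fits$train_rmse, g2$fits$train_rmse)
  expect_error(fit_grid(list(), cfg), "empty-dataset")
})
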