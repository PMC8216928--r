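# Per-pixel sequence model: two stacked LSTM layers and a dense head over
# 6-month windows, trained with Adam on mean squared error. Implemented
# directly on base matrix algebra (batched over windows) with hand-derived
# backpropagation through time; gradients are verified against central
# finite differences in the test suite.
#
# Gate layout: the 4H columns of each layer's weight matrices are the
# input (i), forget (f), cell (g) and output (o) gates, in that order:
#   G = X_t %*% Wx + h_{t-1} %*% Wh + b
#   c_t = sigm(f) * c_{t-1} + sigm(i) * tanh(g);  h_t = sigm(o) * tanh(c_t)
# The dense head maps every timestep's top-layer state to one NDVI value
# (sequence-to-sequence: all 6 window months are predicted).

sigm <- function(x) 1 / (1 + exp(-x))

#' Model configuration for the per-pixel sequence model
#'
#' @param layer_dim Hidden dimension of each LSTM layer (default 75).
#' @param n_layers Number of stacked LSTM layers (default 2).
#' @param input_channels Input channels per month (default 2: temperature,
#'   precipitation).
#' @param output_channels Output channels per month (default 1: NDVI).
#' @param window Months per window (default 6).
#' @param max_epochs Training epoch cap (default 300).
#' @param patience Epochs without loss improvement (beyond `tol`) before
#'   stopping (default 20).
#' @param tol Minimum loss decrease that counts as improvement (default 1e-6).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Windows per parameter update (default 32).
#' @param seed Master seed for initialization and batch shuffling.
#' @return An object of class `model_config`.
#' @export
model_config <- function(layer_dim = 75L, n_layers = 2L, input_channels = 2L,
                         output_channels = 1L, window = 6L,
                         max_epochs = 300L, patience = 20L, tol = 1e-6,
                         learning_rate = 1e-3, batch_size = 32L, seed = 1L) {
  if (layer_dim < 1L || n_layers < 1L || input_channels < 1L ||
      output_channels < 1L || window < 1L)
    stop("config error: dimensions must be positive")
  structure(list(layer_dim = as.integer(layer_dim),
                 n_layers = as.integer(n_layers),
                 input_channels = as.integer(input_channels),
                 output_channels = as.integer(output_channels),
                 window = as.integer(window),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), tol = tol,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an untrained per-pixel model
#'
#' Parameters are initialized uniformly in `[-1/sqrt(H), 1/sqrt(H)]` under
#' the config seed; forget-gate biases start at 1 so early training does
#' not flush the cell state.
#'
#' @param cfg A [model_config()].
#' @return An object of class `pixel_model` (untrained).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(cfg$seed)
  H <- cfg$layer_dim
  lim <- 1 / sqrt(H)
  layers <- vector("list", cfg$n_layers)
  in_dim <- cfg$input_channels
  for (l in seq_len(cfg$n_layers)) {
    b <- runif(4L * H, -lim, lim)
    b[(H + 1L):(2L * H)] <- 1   # forget gate bias
    layers[[l]] <- list(
      Wx = matrix(runif(in_dim * 4L * H, -lim, lim), in_dim, 4L * H),
      Wh = matrix(runif(H * 4L * H, -lim, lim), H, 4L * H),
      b  = b)
    in_dim <- H
  }
  head <- list(Wd = matrix(runif(H * cfg$output_channels, -lim, lim),
                           H, cfg$output_channels),
               bd = rep(0, cfg$output_channels))
  structure(list(layers = layers, head = head, cfg = cfg, trained = FALSE),
            class = "pixel_model")
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf("pixel_model: %d x LSTM(%d) + dense, window %d, %s\n",
              x$cfg$n_layers, x$cfg$layer_dim, x$cfg$window,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Internal: batched forward pass.
# x: array (B, T, C). Returns yhat (B, T) and, if keep_cache, everything the
# backward pass needs.
lstm_forward <- function(model, x, keep_cache = FALSE) {
  B <- dim(x)[1]; T <- dim(x)[2]
  H <- model$cfg$layer_dim
  nL <- length(model$layers)
  cache <- if (keep_cache) vector("list", nL)
  inp <- vector("list", T)
  for (t in seq_len(T)) inp[[t]] <- matrix(x[, t, ], B, dim(x)[3])
  for (l in seq_len(nL)) {
    L <- model$layers[[l]]
    bias <- rep(L$b, each = B)
    h <- matrix(0, B, H); c <- matrix(0, B, H)
    steps <- if (keep_cache) vector("list", T)
    out <- vector("list", T)
    for (t in seq_len(T)) {
      G <- inp[[t]] %*% L$Wx + h %*% L$Wh + bias
      i <- sigm(G[, 1:H, drop = FALSE])
      f <- sigm(G[, (H + 1L):(2L * H), drop = FALSE])
      g <- tanh(G[, (2L * H + 1L):(3L * H), drop = FALSE])
      o <- sigm(G[, (3L * H + 1L):(4L * H), drop = FALSE])
      c_prev <- c
      c <- f * c + i * g
      tc <- tanh(c)
      h_prev <- h
      h <- o * tc
      if (keep_cache)
        steps[[t]] <- list(x = inp[[t]], h_prev = h_prev, c_prev = c_prev,
                           i = i, f = f, g = g, o = o, c = c, tc = tc)
      out[[t]] <- h
    }
    if (keep_cache) cache[[l]] <- steps
    inp <- out
  }
  yhat <- matrix(0, B, T)
  for (t in seq_len(T))
    yhat[, t] <- inp[[t]] %*% model$head$Wd + model$head$bd
  list(yhat = yhat, top_h = inp, cache = cache)
}

# Internal: backward pass for MSE loss. fw is lstm_forward(..., TRUE) output.
# Returns gradients in the same shape as the parameters, plus the loss.
lstm_backward <- function(model, fw, y) {
  B <- nrow(y); T <- ncol(y)
  H <- model$cfg$layer_dim
  nL <- length(model$layers)
  resid <- fw$yhat - y
  loss <- mean(resid^2)
  dy <- 2 * resid / (B * T)              # dL/dyhat

  dWd <- matrix(0, H, 1L); dbd <- 0
  dtop <- vector("list", T)              # dL/dh for the top layer, per step
  for (t in seq_len(T)) {
    dWd <- dWd + crossprod(fw$top_h[[t]], dy[, t, drop = FALSE])
    dbd <- dbd + sum(dy[, t])
    dtop[[t]] <- dy[, t, drop = FALSE] %*% t(model$head$Wd)
  }

  grads <- vector("list", nL)
  dabove <- dtop
  for (l in rev(seq_len(nL))) {
    L <- model$layers[[l]]
    steps <- fw$cache[[l]]
    in_dim <- nrow(L$Wx)
    dWx <- matrix(0, in_dim, 4L * H)
    dWh <- matrix(0, H, 4L * H)
    db <- rep(0, 4L * H)
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    dbelow <- vector("list", T)
    for (t in rev(seq_len(T))) {
      s <- steps[[t]]
      dh <- dabove[[t]] + dh_next
      dc <- dc_next + dh * s$o * (1 - s$tc^2)
      di <- dc * s$g
      df <- dc * s$c_prev
      dg <- dc * s$i
      do_ <- dh * s$tc
      dG <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      dWx <- dWx + crossprod(s$x, dG)
      dWh <- dWh + crossprod(s$h_prev, dG)
      db <- db + colSums(dG)
      dh_next <- dG %*% t(L$Wh)
      dc_next <- dc * s$f
      dbelow[[t]] <- dG %*% t(L$Wx)
    }
    grads[[l]] <- list(Wx = dWx, Wh = dWh, b = db)
    dabove <- dbelow
  }
  list(layers = grads, head = list(Wd = dWd, bd = dbd), loss = loss)
}

# Internal: flatten parameters to one vector and back (for Adam and the
# finite-difference gradient check).
params_to_vec <- function(model) {
  unlist(c(lapply(model$layers, function(L) list(L$Wx, L$Wh, L$b)),
           list(model$head$Wd, model$head$bd)), use.names = FALSE)
}

vec_to_params <- function(model, v) {
  pos <- 0L
  take <- function(n) {
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  for (l in seq_along(model$layers)) {
    L <- model$layers[[l]]
    model$layers[[l]]$Wx <- matrix(take(length(L$Wx)), nrow(L$Wx), ncol(L$Wx))
    model$layers[[l]]$Wh <- matrix(take(length(L$Wh)), nrow(L$Wh), ncol(L$Wh))
    model$layers[[l]]$b <- take(length(L$b))
  }
  model$head$Wd <- matrix(take(length(model$head$Wd)),
                          nrow(model$head$Wd), ncol(model$head$Wd))
  model$head$bd <- take(length(model$head$bd))
  model
}

grads_to_vec <- function(gr) {
  unlist(c(lapply(gr$layers, function(L) list(L$Wx, L$Wh, L$b)),
           list(gr$head$Wd, gr$head$bd)), use.names = FALSE)
}

#' Train a per-pixel model with Adam on mean squared error
#'
#' Minibatch Adam with seeded shuffling. Training stops at `max_epochs` or
#' once the best epoch loss has not improved by more than `tol` for
#' `patience` consecutive epochs; the best-loss parameters seen are
#' retained (checkpointing). The per-epoch loss is the window-mean MSE over
#' the epoch's minibatches.
#'
#' @param model An untrained [build_model()] output.
#' @param train A `windowed_samples` object (training split).
#' @param cfg The [model_config()] (defaults to the model's own).
#' @return The trained `pixel_model`, with a `fit` element (the fit report:
#'   `pixel_id`, `train_rmse`, `loss_history`, `epochs_run`, `converged`).
#' @export
train_pixel <- function(model, train, cfg = model$cfg) {
  stopifnot(inherits(model, "pixel_model"),
            inherits(train, "windowed_samples"))
  n_win <- dim(train$x)[1]
  if (n_win < 1L) stop("empty-dataset error: no training windows")
  set.seed(cfg$seed + 1L)   # shuffle stream; init consumed cfg$seed
  theta <- params_to_vec(model)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  best_loss <- Inf; best_theta <- theta; wait <- 0L
  loss_history <- numeric(0)
  converged <- FALSE

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n_win)
    batch_starts <- seq(1L, n_win, by = cfg$batch_size)
    epoch_sse <- 0
    for (bs in batch_starts) {
      sel <- ord[bs:min(bs + cfg$batch_size - 1L, n_win)]
      xb <- train$x[sel, , , drop = FALSE]
      yb <- train$y[sel, , drop = FALSE]
      fw <- lstm_forward(model, xb, keep_cache = TRUE)
      bk <- lstm_backward(model, fw, yb)
      if (!is.finite(bk$loss))
        stop(sprintf("divergence error: non-finite loss at pixel %s",
                     train$pixel_id))
      epoch_sse <- epoch_sse + bk$loss * length(sel)
      g <- grads_to_vec(bk)
      step <- step + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^step)
      vhat <- v / (1 - beta2^step)
      theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      model <- vec_to_params(model, theta)
    }
    epoch_loss <- epoch_sse / n_win
    loss_history <- c(loss_history, epoch_loss)
    if (epoch_loss < best_loss - cfg$tol) {
      best_loss <- epoch_loss
      best_theta <- theta
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) { converged <- TRUE; break }
    }
  }
  model <- vec_to_params(model, best_theta)
  model$trained <- TRUE
  fw <- lstm_forward(model, train$x)
  model$fit <- list(pixel_id = train$pixel_id,
                    train_rmse = sqrt(mean((fw$yhat - train$y)^2)),
                    loss_history = loss_history,
                    epochs_run = length(loss_history),
                    converged = converged)
  model
}

#' Predict a monthly NDVI series from tiled windows
#'
#' Runs the trained model over non-overlapping windows and concatenates the
#' per-window predictions in window order, yielding one prediction per
#' month of the split. Prediction is a pure function of the model and
#' inputs.
#'
#' @param model A trained `pixel_model`.
#' @param windows A `windowed_samples` object tiled at stride = window.
#' @return Numeric vector of monthly predictions.
#' @export
predict_pixel <- function(model, windows) {
  stopifnot(inherits(model, "pixel_model"))
  if (!isTRUE(model$trained)) stop("state error: model is untrained")
  fw <- lstm_forward(model, windows$x)
  as.vector(t(fw$yhat))
}

#' Fit one independent model per pixel
#'
#' Every pixel gets its own independently initialized and trained model;
#' per-pixel seeds are derived deterministically from the config seed and
#' the pixel id, so grids can be refit reproducibly and pixel by pixel. A
#' diverging pixel is recorded as a failure, not fatal.
#'
#' @param datasets List of `pixel_dataset` objects.
#' @param cfg A [model_config()].
#' @param train_stride,val_stride Window strides passed to
#'   [window_series()].
#' @param verbose Print a progress line per pixel.
#' @return List with `models` (per pixel), `fits` (data frame of fit
#'   reports) and `failures` (named list of error messages).
#' @export
fit_grid <- function(datasets, cfg, train_stride = 1L, val_stride = 6L,
                     verbose = FALSE) {
  if (length(datasets) == 0L) stop("empty-dataset error: no pixel datasets")
  models <- vector("list", length(datasets))
  failures <- list()
  rows <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    pcfg <- cfg
    pcfg$seed <- as.integer((as.double(cfg$seed) * 7919 +
                             as.double(ds$pixel_id) * 104729) %% 2147483647)
    res <- tryCatch({
      sw <- window_series(ds, train_stride, val_stride)
      mod <- train_pixel(build_model(pcfg), sw$train, pcfg)
      mod$pixel_id <- ds$pixel_id
      mod
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(ds$pixel_id)]] <- conditionMessage(res)
      next
    }
    models[[k]] <- res
    rows[[k]] <- data.frame(pixel_id = ds$pixel_id,
                            train_rmse = res$fit$train_rmse,
                            epochs_run = res$fit$epochs_run,
                            converged = res$fit$converged)
    if (verbose)
      message(sprintf("pixel %d: train RMSE %.4g (%d epochs)",
                      ds$pixel_id, res$fit$train_rmse, res$fit$epochs_run))
  }
  keep <- !vapply(models, is.null, logical(1))
  list(models = models[keep], fits = do.call(rbind, rows[keep]),
       failures = failures)
}
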