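# Permutation-importance sensitivity analysis on the validation split:
# PIT (temperature), PIP (precipitation), their difference PID, and the
# three-way sensitivity classification at the +/-0.01 thresholds.
#
# Importance is measured on the error scale: PI = mean over repeats of
# (validation MSE with the feature permuted) minus (baseline validation
# MSE), so larger = more important and the unit is NDVI^2. Permutation
# shuffles the feature's values across all validation months jointly
# (destroying its temporal alignment while keeping its marginal
# distribution), then re-tiles the windows.

#' Permutation importance of one input feature
#'
#' @param model A trained `pixel_model`.
#' @param val A `windowed_samples` object tiling the validation split
#'   (stride = window, so months map one-to-one to window positions).
#' @param feature `"temperature"` or `"precipitation"`.
#' @param n_repeats Number of independent permutations (default 10).
#' @param seed Integer seed for the permutation stream.
#' @return A list: `pi_value` (mean permuted MSE minus baseline MSE),
#'   `repeat_sd` (sd of the per-repeat differences), `baseline_mse`.
#' @export
permutation_importance <- function(model, val,
                                   feature = c("temperature", "precipitation"),
                                   n_repeats = 10L, seed = 1L) {
  feature <- match.arg(feature)
  if (n_repeats < 1L) stop("parameter error: n_repeats must be >= 1")
  ch <- if (feature == "temperature") 1L else 2L
  y <- as.vector(t(val$y))
  base_pred <- predict_pixel(model, val)
  e0 <- mean((y - base_pred)^2)

  n_win <- dim(val$x)[1]; W <- dim(val$x)[2]
  # series view of the feature: months in window-tiling order
  series <- as.vector(t(val$x[, , ch]))
  set.seed(derive_seed(seed, "perm"))
  diffs <- numeric(n_repeats)
  xp <- val
  for (r in seq_len(n_repeats)) {
    perm <- series[sample.int(length(series))]
    xp$x[, , ch] <- matrix(perm, n_win, W, byrow = TRUE)
    pred <- predict_pixel(model, xp)
    diffs[r] <- mean((y - pred)^2) - e0
  }
  list(pi_value = mean(diffs),
       repeat_sd = if (n_repeats > 1L) sd(diffs) else NA_real_,
       baseline_mse = e0)
}

#' Classify climate sensitivity from PIT and PIP
#'
#' PID = PIT - PIP. PID >= `threshold` (default 0.01) means more sensitive
#' to temperature; PID <= `-threshold` more sensitive to precipitation;
#' strictly between, sensitive to both (boundaries inclusive on the pure
#' classes).
#'
#' @param pit,pip Finite permutation importances of temperature and
#'   precipitation.
#' @param threshold Classification threshold on PID (default 0.01).
#' @return A list: `pid`, `sens_class` in
#'   `{"temperature","precipitation","both"}`.
#' @export
classify_pid <- function(pit, pip, threshold = 0.01) {
  if (!is.finite(pit) || !is.finite(pip))
    stop("domain error: PIT and PIP must be finite")
  pid <- pit - pip
  cls <- if (pid >= threshold) "temperature"
         else if (pid <= -threshold) "precipitation"
         else "both"
  list(pid = pid, sens_class = cls)
}

#' Permutation-importance sensitivity for every fitted pixel
#'
#' @param grid_fit A [fit_grid()] result.
#' @param datasets The `pixel_dataset` list.
#' @param n_repeats Permutation repeats per feature (default 10).
#' @param seed Integer seed; per-pixel streams are derived from it.
#' @param threshold PID classification threshold.
#' @param val_stride Validation window stride (must tile: default 6).
#' @return Data frame with one row per pixel: `pixel_id`, `pit`, `pip`,
#'   `pid`, `sens_class`, `pit_sd`, `pip_sd`, `n_repeats`.
#' @export
sensitivity_grid <- function(grid_fit, datasets, n_repeats = 10L, seed = 1L,
                             threshold = 0.01, val_stride = 6L) {
  byid <- setNames(datasets, vapply(datasets, function(d) d$pixel_id,
                                    double(1)))
  rows <- lapply(grid_fit$models, function(m) {
    ds <- byid[[as.character(m$pixel_id)]]
    sw <- window_series(ds, val_stride = val_stride)
    pseed <- as.integer((as.double(seed) * 7919 +
                         as.double(m$pixel_id) * 130363) %% 2147483647)
    pit <- permutation_importance(m, sw$val, "temperature", n_repeats, pseed)
    pip <- permutation_importance(m, sw$val, "precipitation", n_repeats,
                                  pseed + 1L)
    cl <- classify_pid(pit$pi_value, pip$pi_value, threshold)
    data.frame(pixel_id = m$pixel_id, pit = pit$pi_value,
               pip = pip$pi_value, pid = cl$pid, sens_class = cl$sens_class,
               pit_sd = pit$repeat_sd, pip_sd = pip$repeat_sd,
               n_repeats = n_repeats)
  })
  do.call(rbind, rows)
}

#' Aggregate sensitivity to the biome (dominant land-cover) level
#'
#' Per land-cover class: mean PIT, PIP, PID, the class fractions over the
#' three sensitivity classes, and the pixel count. Classes with zero pixels
#' are omitted.
#'
#' @param sens Data frame from [sensitivity_grid()].
#' @param datasets The `pixel_dataset` list (carries land-cover codes).
#' @return Data frame, one row per represented land-cover class.
#' @export
biome_sensitivity <- function(sens, datasets) {
  codes <- setNames(vapply(datasets, function(d) d$landcover, integer(1)),
                    vapply(datasets, function(d) d$pixel_id, double(1)))
  lc <- codes[as.character(sens$pixel_id)]
  if (anyNA(lc)) stop("scheme error: pixel without a land-cover code")
  rows <- lapply(sort(unique(lc)), function(code) {
    s <- sens[lc == code, ]
    data.frame(landcover_code = code, n_pixels = nrow(s),
               mean_pit = mean(s$pit), mean_pip = mean(s$pip),
               mean_pid = mean(s$pid),
               frac_temperature = mean(s$sens_class == "temperature"),
               frac_precipitation = mean(s$sens_class == "precipitation"),
               frac_both = mean(s$sens_class == "both"))
  })
  do.call(rbind, rows)
}
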