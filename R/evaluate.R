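# Model skill: RMSE for training fit, the CV error statistic for
# validation, quality classification at the 15% rule, and grid summaries.

#' Root mean square error
#'
#' @param measured,predicted Equal-length numeric vectors of finite values.
#' @return `sqrt(mean((measured - predicted)^2))`, in NDVI units here.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted))
    stop("alignment error: series lengths differ")
  if (length(measured) < 1L) stop("empty series")
  if (!all(is.finite(measured)) || !all(is.finite(predicted)))
    stop("non-finite values in series")
  sqrt(mean((measured - predicted)^2))
}

#' Coefficient-of-variation model error
#'
#' The deviation of predicted from measured data relative to the measured
#' level: `rmse(measured, predicted) / mean(measured)`. Unitless; a model
#' with CV below 15% is considered to perform well.
#'
#' @param measured,predicted Equal-length numeric vectors.
#' @return Non-negative proportion.
#' @export
cv_error <- function(measured, predicted) {
  r <- rmse(measured, predicted)
  m <- mean(measured)
  if (m == 0) stop("undefined-CV error: mean of measured series is zero")
  r / m
}

#' Classify model quality from its CV
#'
#' `"good"` iff CV < 0.15; the boundary value 0.15 itself maps to
#' `"poor"`.
#'
#' @param cv_value Non-negative CV.
#' @param threshold Quality threshold (default 0.15).
#' @return `"good"` or `"poor"`.
#' @export
classify_quality <- function(cv_value, threshold = 0.15) {
  if (any(!is.finite(cv_value)) || any(cv_value < 0))
    stop("domain error: CV must be finite and non-negative")
  ifelse(cv_value < threshold, "good", "poor")
}

#' Validate a trained pixel model on its held-out months
#'
#' Predicts the validation split with non-overlapping windows (each month
#' predicted exactly once), then scores CV, validation RMSE and the
#' quality label.
#'
#' @param model A trained `pixel_model`.
#' @param ds The `pixel_dataset` the model was fit on.
#' @param val_stride Validation window stride (default 6, tiling).
#' @return A list of class `validation_report`: `pixel_id`, `cv`,
#'   `rmse_val`, `quality`, `predicted_series`, `measured_series`.
#' @export
validate_pixel <- function(model, ds, val_stride = 6L) {
  sw <- window_series(ds, val_stride = val_stride)
  pred <- predict_pixel(model, sw$val)
  meas <- as.vector(t(sw$val$y))
  cv <- cv_error(meas, pred)
  structure(list(pixel_id = ds$pixel_id, cv = cv,
                 rmse_val = rmse(meas, pred),
                 quality = classify_quality(cv),
                 predicted_series = pred, measured_series = meas),
            class = "validation_report")
}

#' Validate every fitted pixel of a grid
#'
#' Pixels whose measured validation mean is non-positive (CV undefined or
#' sign-flipped) are flagged and excluded, with a warning.
#'
#' @param grid_fit A [fit_grid()] result.
#' @param datasets The `pixel_dataset` list the grid was fit on.
#' @param val_stride Validation window stride.
#' @return List with `reports` (validation_report list) and `table` (data
#'   frame `pixel_id`, `cv`, `rmse_val`, `quality`).
#' @export
validate_grid <- function(grid_fit, datasets, val_stride = 6L) {
  ids <- vapply(grid_fit$models, function(m) m$pixel_id, double(1))
  byid <- setNames(datasets, vapply(datasets, function(d) d$pixel_id,
                                    double(1)))
  reports <- list(); skipped <- 0L
  for (m in grid_fit$models) {
    ds <- byid[[as.character(m$pixel_id)]]
    sw <- window_series(ds, val_stride = val_stride)
    if (mean(sw$val$y) <= 0) { skipped <- skipped + 1L; next }
    reports[[length(reports) + 1L]] <- validate_pixel(m, ds, val_stride)
  }
  if (skipped > 0L)
    warning(sprintf("%d pixel(s) with non-positive mean NDVI excluded from CV",
                    skipped))
  table <- do.call(rbind, lapply(reports, function(r)
    data.frame(pixel_id = r$pixel_id, cv = r$cv, rmse_val = r$rmse_val,
               quality = r$quality)))
  list(reports = reports, table = table)
}

#' Summarize model skill over the grid
#'
#' Fractions of pixels whose training RMSE and validation CV fall below
#' configurable thresholds.
#'
#' @param fits Fit-report data frame from [fit_grid()].
#' @param vals Validation table from [validate_grid()].
#' @param rmse_threshold,cv_threshold Thresholds (defaults 0.01 and 0.15).
#' @return A one-row data frame: `n_pixels`, `fraction_rmse_below`,
#'   `fraction_cv_below`, and the thresholds used.
#' @export
grid_summary <- function(fits, vals, rmse_threshold = 0.01,
                         cv_threshold = 0.15) {
  if (is.null(fits) || nrow(fits) == 0L)
    stop("empty-dataset error: no fit reports")
  if (is.null(vals) || nrow(vals) == 0L)
    stop("empty-dataset error: no validation reports")
  data.frame(n_pixels = nrow(fits),
             fraction_rmse_below = mean(fits$train_rmse < rmse_threshold),
             fraction_cv_below = mean(vals$cv < cv_threshold),
             rmse_threshold = rmse_threshold, cv_threshold = cv_threshold)
}
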