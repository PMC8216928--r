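# Error attribution: six per-pixel climate/vegetation factors, OLS
# regressions of model CV on each, and land-cover stratification of skill.
#
# Factor definitions (per pixel, over the full analysis period):
#   MAT  = mean of annual mean temperatures (degC)
#   MAP  = mean of annual total precipitation (mm/year)
#   dTMP = mean temperature of the last 5 years minus the first 5 years
#   IAT  = sd/mean of annual mean temperatures       (interannual CV)
#   IAP  = sd/mean of annual total precipitation
#   IAV  = sd/mean of annual mean NDVI
# IAT on a Celsius scale is ill-defined when the annual-mean temperature
# crosses zero; such pixels are computed on a Kelvin offset (+273.15) with
# a note, since the ratio otherwise explodes or flips sign.

# Internal: fold a monthly series to annual aggregates.
annual_agg <- function(x, years, fun) {
  as.numeric(tapply(x, years, fun))
}

#' Compute the six error-attribution factors per pixel
#'
#' @param climate A coarse [climate_grid()].
#' @param ndvi The matching monthly coarse [ndvi_grid()].
#' @param edge_years Years in the change windows at each end of the period
#'   (default 5, i.e. last-5-minus-first-5 temperature change).
#' @return Data frame: `pixel_id, lat_idx, lon_idx, mat, map, dtmp, iat,
#'   iap, iav, iat_kelvin` (flag: IAT computed on the Kelvin scale).
#' @export
compute_factors <- function(climate, ndvi, edge_years = 5L) {
  stopifnot(inherits(climate, "climate_grid"), inherits(ndvi, "ndvi_grid"))
  d <- dim(climate$temperature)
  if (!identical(d, dim(ndvi$values)))
    stop("alignment error: climate and NDVI grids differ in shape")
  years <- climate$time$year
  n_years <- length(unique(years))
  if (n_years < 2L * edge_years)
    stop("window error: period shorter than the two change windows")
  first_w <- years < min(years) + edge_years
  last_w <- years >= max(years) - edge_years + 1L
  rows <- list(); k <- 0L
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    tt <- climate$temperature[, i, j]
    pp <- climate$precipitation[, i, j]
    yy <- ndvi$values[, i, j]
    if (anyNA(tt) || anyNA(pp) || anyNA(yy)) next
    at <- annual_agg(tt, years, mean)
    ap <- annual_agg(pp, years, sum)
    av <- annual_agg(yy, years, mean)
    kelvin <- min(at) <= 0 && max(at) >= 0
    at_cv <- if (kelvin) at + 273.15 else at
    k <- k + 1L
    rows[[k]] <- data.frame(
      pixel_id = (i - 1L) * d[3] + j, lat_idx = i, lon_idx = j,
      mat = mean(at), map = mean(ap),
      dtmp = mean(tt[last_w]) - mean(tt[first_w]),
      iat = abs(sd(at_cv) / mean(at_cv)),
      iap = sd(ap) / mean(ap),
      iav = sd(av) / mean(av),
      iat_kelvin = kelvin)
  }
  if (k == 0L) stop("empty-dataset error: no gap-free pixel")
  do.call(rbind, rows)
}

#' Regress model CV on one error factor across pixels
#'
#' Ordinary least squares of validation CV on the chosen factor, reported
#' as slope, intercept, R-squared and the two-sided p-value of the slope.
#'
#' @param vals Validation table (`pixel_id`, `cv`) from [validate_grid()].
#' @param factors Data frame from [compute_factors()].
#' @param factor One of `"mat", "map", "dtmp", "iat", "iap", "iav"`.
#' @return One-row data frame: `factor, slope, intercept, r_squared,
#'   p_value, n`.
#' @export
regress_cv_on_factor <- function(vals, factors,
                                 factor = c("iav", "iat", "iap", "mat",
                                            "map", "dtmp")) {
  factor <- match.arg(factor)
  df <- merge(vals[, c("pixel_id", "cv")],
              factors[, c("pixel_id", factor)], by = "pixel_id")
  names(df)[3] <- "x"
  if (nrow(df) < 3L) stop("need at least 3 pixels with both CV and factor")
  if (sd(df$x) == 0) stop("degenerate-regression error: factor has zero variance")
  fit <- lm(cv ~ x, data = df)
  sm <- summary(fit)
  data.frame(factor = factor,
             slope = unname(coef(fit)[2]),
             intercept = unname(coef(fit)[1]),
             r_squared = sm$r.squared,
             p_value = sm$coefficients[2, 4],
             n = nrow(df))
}

#' Regress model CV on every factor
#'
#' @inheritParams regress_cv_on_factor
#' @return Data frame with one row per factor, in the order of the six
#'   factor definitions.
#' @export
regress_cv_all <- function(vals, factors) {
  do.call(rbind, lapply(c("mat", "map", "dtmp", "iat", "iap", "iav"),
                        function(f) regress_cv_on_factor(vals, factors, f)))
}

#' Stratify model skill by dominant land-cover class
#'
#' Per-class mean, median and count of validation CV, sorted by mean CV.
#' Classes with zero pixels are omitted.
#'
#' @param vals Validation table (`pixel_id`, `cv`).
#' @param datasets The `pixel_dataset` list (carries land-cover codes).
#' @return Data frame: `landcover_code, n_pixels, mean_cv, median_cv`.
#' @export
landcover_strata <- function(vals, datasets) {
  codes <- setNames(vapply(datasets, function(d) as.integer(d$landcover),
                           integer(1)),
                    vapply(datasets, function(d) d$pixel_id, double(1)))
  lc <- codes[as.character(vals$pixel_id)]
  if (length(lc) == 0L || all(is.na(lc)))
    stop("empty-dataset error: no land-cover codes available")
  rows <- lapply(sort(unique(lc[!is.na(lc)])), function(code) {
    s <- vals$cv[!is.na(lc) & lc == code]
    data.frame(landcover_code = code, n_pixels = length(s),
               mean_cv = mean(s), median_cv = median(s))
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_cv), ]
}

#' Combined per-pixel analysis table
#'
#' Joins validation CV, the six factors, the land-cover code and the
#' sensitivity class into one tidy table for downstream plotting.
#'
#' @param vals Validation table.
#' @param factors Factor table from [compute_factors()].
#' @param sens Sensitivity table from [sensitivity_grid()] (optional).
#' @param datasets The `pixel_dataset` list (optional, for land cover).
#' @return A merged data frame keyed by `pixel_id`.
#' @export
analysis_table <- function(vals, factors, sens = NULL, datasets = NULL) {
  out <- merge(vals, factors, by = "pixel_id")
  if (!is.null(sens))
    out <- merge(out, sens[, c("pixel_id", "pit", "pip", "pid",
                               "sens_class")], by = "pixel_id")
  if (!is.null(datasets)) {
    codes <- data.frame(
      pixel_id = vapply(datasets, function(d) d$pixel_id, double(1)),
      landcover = vapply(datasets, function(d) as.integer(d$landcover),
                         integer(1)))
    out <- merge(out, codes, by = "pixel_id")
  }
  out[order(out$pixel_id), ]
}
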