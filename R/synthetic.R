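# Synthetic gridded vegetation-climate generator.
#
# The generative model (documented here because downstream tests lean on it):
#   monthly latent signal per coarse pixel
#     eta_t = atanh(base) + season_amp * cos(2*pi*(month - peak)/12)
#             + w_T * z(T, lag)_t + w_P * z(P, lag)_t + e_t
#   e_t = ar_coef * e_{t-1} + N(0, noise_sd)          (AR(1) memory noise)
#   z(X, lag)_t = mean of the standardized series (X - mean(X))/sd(X) over
#                 months max(1, t-lag+1)..t            (lagged climate memory)
#   NDVI composite k of month t (fine cell) = tanh(eta_t + d_k),
#     d_k ~ N(0, noise_sd/2) independent per fine cell and composite
# tanh squashes smoothly into (-1, 1); atanh(base) makes the no-signal,
# no-season limit equal `base` exactly. All fine cells of a coarse block
# share eta_t (weights and AR noise live at model resolution); only the
# sub-monthly composite perturbation is fine-cell-specific, so block-mean
# aggregation recovers the latent signal as noise vanishes.

# Internal: independent seed streams per stage, derived from one master seed
# so regenerating one stage never reshuffles another. Kept below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(climate = 101L, ndvi = 211L, landcover = 307L,
               invalid = 401L, weights = 503L, fit = 601L, perm = 701L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer((as.double(seed) * 48271 + offsets[[stream]]) %% 2147483647)
}

#' Response parameters of the synthetic vegetation model
#'
#' Parameters controlling how synthetic NDVI responds to climate.
#' `w_T` and `w_P` are unitless sensitivity weights (scalar, or a
#' coarse-grid matrix for per-pixel structure); `lag` is the months of
#' climate memory entering the lagged standardized-mean covariate; `base`
#' is the baseline NDVI level; `season_amp` the seasonal amplitude (in
#' squash-space units); `ar_coef`/`noise_sd` parameterize AR(1) interannual
#' noise (`noise_sd` may also be a coarse-grid matrix); `trend_per_year` is
#' a uniform linear warming applied to temperature (degC/year).
#'
#' @param w_T,w_P Sensitivity weights (scalar or `n_lat x n_lon` matrix).
#' @param lag Months of climate memory, >= 1.
#' @param base Baseline NDVI in (0, 1).
#' @param season_amp Seasonal NDVI amplitude (squash space).
#' @param ar_coef AR(1) coefficient in [0, 1).
#' @param noise_sd Innovation standard deviation (scalar or matrix).
#' @param trend_per_year Linear temperature trend, degC/year.
#' @return An object of class `response_params`.
#' @export
response_params <- function(w_T = 0.25, w_P = 0.25, lag = 3L, base = 0.35,
                            season_amp = 0.25, ar_coef = 0.3,
                            noise_sd = 0.02, trend_per_year = 0.03) {
  if (base <= 0 || base >= 1) stop("base must lie in (0, 1)")
  if (ar_coef < 0 || ar_coef >= 1) stop("ar_coef must lie in [0, 1)")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  if (lag < 1L) stop("lag must be >= 1 month")
  structure(list(w_T = w_T, w_P = w_P, lag = as.integer(lag), base = base,
                 season_amp = season_amp, ar_coef = ar_coef,
                 noise_sd = noise_sd, trend_per_year = trend_per_year),
            class = "response_params")
}

# Internal: broadcast a scalar-or-matrix parameter to the coarse grid.
as_pixel_field <- function(x, spec, what) {
  if (length(x) == 1L) return(matrix(x, spec$n_lat, spec$n_lon))
  if (is.matrix(x) && all(dim(x) == c(spec$n_lat, spec$n_lon))) return(x)
  stop(sprintf("alignment error: %s must be scalar or %d x %d matrix",
               what, spec$n_lat, spec$n_lon))
}

#' Generate a synthetic monthly climate grid
#'
#' Temperature is a latitude-dependent annual mean plus a sinusoidal
#' seasonal cycle (amplitude growing poleward), a uniform linear warming
#' trend, and Gaussian noise. Precipitation is a latitude-dependent base
#' rate modulated by a seasonal cycle plus noise, clipped at zero. Row 1 is
#' the warm, wet, weakly seasonal end of the gradient ("equatorward").
#'
#' @param spec A [grid_spec()].
#' @param params A [response_params()] (supplies `trend_per_year`).
#' @param seed Integer master seed; the climate stream is derived from it.
#' @param temp_range Annual-mean temperature at rows 1 and `n_lat` (degC).
#' @param temp_season_range Seasonal semi-amplitude at rows 1 and `n_lat`.
#' @param temp_noise_sd Monthly temperature noise sd (degC).
#' @param precip_range Mean precipitation at rows 1 and `n_lat` (mm/month).
#' @param precip_season_frac Relative seasonal modulation of precipitation.
#' @param precip_phase Months by which the precipitation peak lags the
#'   temperature peak (default 2). A non-zero offset makes the monthly
#'   (temperature, precipitation) pair identify the calendar month uniquely;
#'   with identical phases, months mirrored about the seasonal extremes have
#'   identical climate but different vegetation, an ambiguity real climate
#'   does not exhibit.
#' @param precip_noise_sd Monthly precipitation noise sd (mm/month).
#' @return A [climate_grid()] on the coarse grid.
#' @export
generate_climate <- function(spec, params, seed,
                             temp_range = c(25, -5),
                             temp_season_range = c(4, 14),
                             temp_noise_sd = 0.6,
                             precip_range = c(160, 40),
                             precip_season_frac = 0.5,
                             precip_phase = 2,
                             precip_noise_sd = 12) {
  stopifnot(inherits(spec, "grid_spec"), inherits(params, "response_params"))
  set.seed(derive_seed(seed, "climate"))
  tm <- spec$time
  n_t <- spec$n_months
  lat_frac <- if (spec$n_lat == 1L) 0 else
    (seq_len(spec$n_lat) - 1) / (spec$n_lat - 1)
  t_mean <- temp_range[1] + lat_frac * (temp_range[2] - temp_range[1])
  t_amp  <- temp_season_range[1] +
    lat_frac * (temp_season_range[2] - temp_season_range[1])
  p_mean <- precip_range[1] + lat_frac * (precip_range[2] - precip_range[1])

  season <- cos(2 * pi * (tm$month - 7) / 12)                  # peaks in July
  season_p <- cos(2 * pi * (tm$month - 7 - precip_phase) / 12) # lags by phase
  trend  <- params$trend_per_year * (tm$year - spec$start_year)

  temp <- array(0, c(n_t, spec$n_lat, spec$n_lon))
  prec <- array(0, c(n_t, spec$n_lat, spec$n_lon))
  for (i in seq_len(spec$n_lat)) {
    base_t <- t_mean[i] + t_amp[i] * season + trend
    base_p <- p_mean[i] * (1 + precip_season_frac * season_p)
    for (j in seq_len(spec$n_lon)) {
      temp[, i, j] <- base_t + rnorm(n_t, 0, temp_noise_sd)
      prec[, i, j] <- pmax(0, base_p + rnorm(n_t, 0, precip_noise_sd))
    }
  }
  climate_grid(temp, prec, tm)
}

# Internal: lagged standardized mean of one monthly series.
# Standardization uses the series' own full-period mean/sd; the lag window
# is max(1, t-lag+1)..t (truncated at the series start).
lagged_z <- function(x, lag) {
  s <- sd(x)
  z <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  cs <- cumsum(z)
  n <- length(z)
  lo <- pmax(0L, seq_len(n) - lag)           # cumsum index before window
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

#' Generate synthetic 15-day NDVI composites with known sensitivity truth
#'
#' Builds the latent monthly NDVI signal per coarse pixel from lagged
#' standardized climate (see the model sketch at the top of the source
#' file), then emits two 15-day composites per calendar month on the fine
#' grid, each the latent value perturbed by independent sub-monthly noise
#' (sd `noise_sd / 2`) before tanh squashing into (-1, 1).
#'
#' @param climate A coarse [climate_grid()].
#' @param spec The [grid_spec()] the climate was generated on.
#' @param params A [response_params()]; `w_T`, `w_P` and `noise_sd` may be
#'   coarse-grid matrices for per-pixel structure.
#' @param seed Integer master seed; NDVI stream derived from it.
#' @return A list with `ndvi` (fine 15-day [ndvi_grid()]) and `truth` (a
#'   data frame `pixel_id, lat_idx, lon_idx, w_T, w_P, class` where class is
#'   `"temperature"` iff `w_T > 0 & w_P == 0`, `"precipitation"` iff
#'   `w_P > 0 & w_T == 0`, else `"both"`).
#' @export
generate_ndvi <- function(climate, spec, params, seed) {
  stopifnot(inherits(climate, "climate_grid"), inherits(spec, "grid_spec"))
  d <- dim(climate$temperature)
  if (!all(d == c(spec$n_months, spec$n_lat, spec$n_lon)))
    stop("alignment error: climate does not match spec dimensions")
  set.seed(derive_seed(seed, "ndvi"))

  wT <- as_pixel_field(params$w_T, spec, "w_T")
  wP <- as_pixel_field(params$w_P, spec, "w_P")
  nsd <- as_pixel_field(params$noise_sd, spec, "noise_sd")
  n_t <- spec$n_months
  f <- spec$fine_factor
  season <- params$season_amp * cos(2 * pi * (spec$time$month - 8) / 12)

  vals <- array(NA_real_, c(2L * n_t, spec$fine_lat, spec$fine_lon))
  truth <- data.frame(pixel_id = integer(), lat_idx = integer(),
                      lon_idx = integer(), w_T = double(), w_P = double(),
                      class = character())
  k <- 0L
  for (i in seq_len(spec$n_lat)) {
    for (j in seq_len(spec$n_lon)) {
      k <- k + 1L
      zT <- lagged_z(climate$temperature[, i, j], params$lag)
      zP <- lagged_z(climate$precipitation[, i, j], params$lag)
      ar <- numeric(n_t)
      innov <- rnorm(n_t, 0, nsd[i, j])
      for (t in seq_len(n_t))
        ar[t] <- if (t == 1L) innov[1] else params$ar_coef * ar[t - 1L] + innov[t]
      eta <- atanh(params$base) + season + wT[i, j] * zT + wP[i, j] * zP + ar

      rows <- (i - 1L) * f + seq_len(f)
      cols <- (j - 1L) * f + seq_len(f)
      sub_sd <- nsd[i, j] / 2
      for (r in rows) for (cc in cols) {
        d1 <- rnorm(n_t, 0, sub_sd)
        d2 <- rnorm(n_t, 0, sub_sd)
        vals[seq(1L, 2L * n_t, by = 2L), r, cc] <- tanh(eta + d1)
        vals[seq(2L, 2L * n_t, by = 2L), r, cc] <- tanh(eta + d2)
      }
      cls <- if (wT[i, j] > 0 && wP[i, j] == 0) "temperature"
             else if (wP[i, j] > 0 && wT[i, j] == 0) "precipitation"
             else "both"
      truth <- rbind(truth, data.frame(
        pixel_id = k, lat_idx = i, lon_idx = j,
        w_T = wT[i, j], w_P = wP[i, j], class = cls))
    }
  }
  list(ndvi = ndvi_grid(vals, "15day", spec$time), truth = truth)
}

#' Generate a spatially clumped categorical land-cover layer
#'
#' Assigns class codes `1..n_classes` blockwise on the fine grid (one draw
#' per `block_size x block_size` block), so that dominant-class aggregation
#' to the coarse grid is non-trivial but spatially coherent.
#'
#' @param spec A [grid_spec()].
#' @param n_classes Number of classes, in `2..17` (IGBP-style scheme).
#' @param seed Integer master seed; land-cover stream derived from it.
#' @param block_size Side of the assignment block in fine cells (default:
#'   half a coarse cell, minimum 1).
#' @return A fine-grid [landcover_grid()].
#' @export
generate_landcover <- function(spec, n_classes, seed,
                               block_size = max(1L, spec$fine_factor %/% 2L)) {
  stopifnot(inherits(spec, "grid_spec"))
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > 17L)
    stop("invalid parameter: n_classes must lie in 2..17")
  set.seed(derive_seed(seed, "landcover"))
  nb_lat <- ceiling(spec$fine_lat / block_size)
  nb_lon <- ceiling(spec$fine_lon / block_size)
  blocks <- matrix(sample.int(n_classes, nb_lat * nb_lon, replace = TRUE),
                   nb_lat, nb_lon)
  codes <- blocks[(seq_len(spec$fine_lat) - 1L) %/% block_size + 1L,
                  (seq_len(spec$fine_lon) - 1L) %/% block_size + 1L,
                  drop = FALSE]
  landcover_grid(codes, n_classes)
}

#' Mark a fraction of pixels invalid for their whole series
#'
#' Invalidates exactly `floor(fraction * n_pixels)` pixels (chosen uniformly
#' under the derived seed), setting their full series to NA and recording
#' them in the validity mask — material for the strict validity filter to
#' delete.
#'
#' @param ndvi An [ndvi_grid()].
#' @param fraction Proportion of pixels to invalidate, in `[0, 1)`.
#' @param seed Integer master seed; invalidation stream derived from it.
#' @return The masked [ndvi_grid()].
#' @export
inject_invalid <- function(ndvi, fraction, seed) {
  stopifnot(inherits(ndvi, "ndvi_grid"))
  if (fraction < 0 || fraction >= 1)
    stop("invalid parameter: fraction must lie in [0, 1)")
  if (fraction == 0) return(ndvi)
  set.seed(derive_seed(seed, "invalid"))
  d <- dim(ndvi$values)
  n_pix <- d[2] * d[3]
  n_bad <- floor(fraction * n_pix)
  if (n_bad == 0L) return(ndvi)
  bad <- sample.int(n_pix, n_bad)
  lat <- (bad - 1L) %% d[2] + 1L
  lon <- (bad - 1L) %/% d[2] + 1L
  for (b in seq_len(n_bad)) {
    ndvi$values[, lat[b], lon[b]] <- NA_real_
    ndvi$valid[lat[b], lon[b]] <- FALSE
  }
  ndvi
}

#' Assign a block design of pure- and mixed-sensitivity pixels
#'
#' Builds coarse-grid `w_T`/`w_P` weight matrices realizing a requested
#' number of temperature-only, precipitation-only and mixed pixels (filled
#' in row-major order), for sensitivity-recovery experiments with known
#' ground truth.
#'
#' @param spec A [grid_spec()].
#' @param n_temp,n_precip,n_both Pixel counts per class; must sum to the
#'   number of coarse pixels.
#' @param w_strong Weight given to the active climate driver(s) of a pure
#'   pixel; mixed pixels get `w_strong / 2` on both.
#' @return A list with matrices `w_T`, `w_P` and a factor `class` vector in
#'   pixel-id order.
#' @export
sensitivity_design <- function(spec, n_temp, n_precip, n_both,
                               w_strong = 0.35) {
  n_pix <- spec$n_lat * spec$n_lon
  if (n_temp + n_precip + n_both != n_pix)
    stop("class counts must sum to the number of coarse pixels")
  cls <- rep(c("temperature", "precipitation", "both"),
             c(n_temp, n_precip, n_both))
  wT <- ifelse(cls == "temperature", w_strong,
               ifelse(cls == "both", w_strong / 2, 0))
  wP <- ifelse(cls == "precipitation", w_strong,
               ifelse(cls == "both", w_strong / 2, 0))
  # pixel_id k = (i-1)*n_lon + j is row-major; matrix() fills column-major,
  # so build by row index explicitly.
  to_mat <- function(v) matrix(v, spec$n_lat, spec$n_lon, byrow = TRUE)
  list(w_T = to_mat(wT), w_P = to_mat(wP), class = cls)
}
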