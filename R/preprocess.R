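# From raw composite grids to per-pixel aligned monthly series, the
# train/validation split and 6-month windows.

#' Maximum-value compositing of 15-day NDVI to monthly
#'
#' Each month's value is the maximum over that month's composites (two per
#' month), computed over the available composites; a month whose composites
#' are all missing stays missing. Taking the maximum suppresses negatively
#' biased contaminated composites (cloud, atmosphere).
#'
#' @param ndvi A 15-day cadence [ndvi_grid()].
#' @return A monthly [ndvi_grid()] on the same spatial grid.
#' @export
mvc_composite <- function(ndvi) {
  stopifnot(inherits(ndvi, "ndvi_grid"))
  if (ndvi$cadence != "15day")
    stop("cadence error: mvc_composite expects a 15-day grid")
  d <- dim(ndvi$values)
  if (d[1] %% 2L != 0L)
    stop("cadence error: odd composite count")
  n_m <- d[1] %/% 2L
  a <- ndvi$values[seq(1L, d[1], by = 2L), , , drop = FALSE]
  b <- ndvi$values[seq(2L, d[1], by = 2L), , , drop = FALSE]
  out <- pmax(a, b, na.rm = TRUE)   # NA only where both composites missing
  dim(out) <- c(n_m, d[2], d[3])
  ndvi_grid(out, "monthly", ndvi$time, valid = ndvi$valid)
}

# Internal: block-aggregate one (time, lat, lon) array by a function over
# factor x factor spatial blocks, ignoring NA; all-NA block -> NA.
block_aggregate <- function(values, factor, fun) {
  d <- dim(values)
  if (d[2] %% factor != 0L || d[3] %% factor != 0L)
    stop("shape error: grid dimensions not divisible by factor")
  n_lat <- d[2] %/% factor; n_lon <- d[3] %/% factor
  out <- array(NA_real_, c(d[1], n_lat, n_lon))
  for (i in seq_len(n_lat)) {
    rows <- (i - 1L) * factor + seq_len(factor)
    for (j in seq_len(n_lon)) {
      cols <- (j - 1L) * factor + seq_len(factor)
      block <- values[, rows, cols, drop = FALSE]
      dim(block) <- c(d[1], factor * factor)
      out[, i, j] <- apply(block, 1L, fun)
    }
  }
  out
}

#' Aggregate a fine NDVI grid to coarse resolution by block means
#'
#' Each coarse cell is the unweighted arithmetic mean of its
#' `factor x factor` fine block at every time step, ignoring missing fine
#' cells; an all-missing block yields a missing coarse value. `factor = 1`
#' is the identity.
#'
#' @param ndvi A fine [ndvi_grid()] (either cadence).
#' @param factor Integer block side; fine dimensions must be divisible.
#' @return A coarse [ndvi_grid()] of the same cadence.
#' @export
regrid_mean <- function(ndvi, factor) {
  stopifnot(inherits(ndvi, "ndvi_grid"))
  factor <- as.integer(factor)
  if (factor == 1L) return(ndvi)
  vals <- block_aggregate(ndvi$values, factor, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  d <- dim(vals)
  # a coarse pixel is valid if any of its fine cells is valid
  vmask <- matrix(TRUE, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    vmask[i, j] <- any(ndvi$valid[(i - 1L) * factor + seq_len(factor),
                                  (j - 1L) * factor + seq_len(factor)])
  ndvi_grid(vals, ndvi$cadence, ndvi$time, valid = vmask)
}

#' Aggregate land cover to coarse resolution by dominant class
#'
#' Each coarse cell takes the modal class of its `factor x factor` fine
#' block (the class with the highest within-cell proportion); ties are
#' broken by the smallest class code. `factor = 1` is the identity.
#'
#' @param lc A fine [landcover_grid()].
#' @param factor Integer block side; dimensions must be divisible.
#' @return A coarse [landcover_grid()].
#' @export
dominant_landcover <- function(lc, factor) {
  stopifnot(inherits(lc, "landcover_grid"))
  factor <- as.integer(factor)
  if (factor == 1L) return(lc)
  d <- dim(lc$codes)
  if (d[1] %% factor != 0L || d[2] %% factor != 0L)
    stop("shape error: land-cover dimensions not divisible by factor")
  n_lat <- d[1] %/% factor; n_lon <- d[2] %/% factor
  out <- matrix(NA_integer_, n_lat, n_lon)
  for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
    block <- lc$codes[(i - 1L) * factor + seq_len(factor),
                      (j - 1L) * factor + seq_len(factor)]
    counts <- tabulate(block, nbins = lc$n_classes)
    out[i, j] <- which.max(counts)   # which.max takes the lowest index on ties
  }
  landcover_grid(out, lc$n_classes)
}

#' Build gap-free per-pixel datasets with a train/validation split
#'
#' Applies the strict validity rule: a pixel with any missing NDVI or
#' climate entry anywhere in its monthly series is excluded. Each surviving
#' pixel yields one dataset carrying its aligned (temperature,
#' precipitation) inputs and NDVI target, split into the first
#' `train_months` and the remaining months, plus per-channel normalization
#' constants computed from the training months only.
#'
#' @param ndvi A monthly coarse [ndvi_grid()].
#' @param climate A coarse [climate_grid()] on the same grid and time axis.
#' @param train_months Months in the training split (default 264, i.e. 22
#'   years).
#' @param landcover Optional coarse [landcover_grid()]; its code is attached
#'   to each dataset.
#' @return A list of `pixel_dataset` objects.
#' @export
filter_valid_pixels <- function(ndvi, climate, train_months = 264L,
                                landcover = NULL) {
  stopifnot(inherits(ndvi, "ndvi_grid"), inherits(climate, "climate_grid"))
  if (ndvi$cadence != "monthly")
    stop("cadence error: expected a monthly NDVI grid")
  d <- dim(ndvi$values)
  if (!identical(d, dim(climate$temperature)))
    stop("alignment error: NDVI and climate grids differ in shape")
  train_months <- as.integer(train_months)
  val_months <- d[1] - train_months
  if (train_months < 6L || val_months < 6L)
    stop("window error: each split needs at least 6 months")
  out <- list()
  k <- 0L
  for (j in seq_len(d[3])) for (i in seq_len(d[2])) {
    y <- ndvi$values[, i, j]
    tt <- climate$temperature[, i, j]
    pp <- climate$precipitation[, i, j]
    if (!ndvi$valid[i, j] || anyNA(y) || anyNA(tt) || anyNA(pp)) next
    id <- (i - 1L) * d[3] + j
    tr <- seq_len(train_months)
    norm <- list(mean = c(temperature = mean(tt[tr]),
                          precipitation = mean(pp[tr])),
                 sd = c(temperature = max(sd(tt[tr]), 1e-12),
                        precipitation = max(sd(pp[tr]), 1e-12)))
    k <- k + 1L
    out[[k]] <- structure(
      list(pixel_id = id, lat_idx = i, lon_idx = j,
           temperature = tt, precipitation = pp, ndvi = y,
           train_months = train_months, val_months = val_months,
           norm = norm,
           landcover = if (is.null(landcover)) NA_integer_
                       else landcover$codes[i, j]),
      class = "pixel_dataset")
  }
  if (k == 0L) stop("empty-dataset error: no pixel survived the validity filter")
  out[order(vapply(out, function(x) x$pixel_id, integer(1)))]
}

# Internal: cut one split of a dataset into length-6 windows at a stride.
# Returns x: (n_windows, 6, 2) normalized inputs; y: (n_windows, 6) targets.
make_windows <- function(ds, idx, stride, window = 6L) {
  n <- length(idx)
  if (n < window) stop("window error: split shorter than the window length")
  starts <- seq(1L, n - window + 1L, by = stride)
  x <- array(0, c(length(starts), window, 2L))
  y <- matrix(0, length(starts), window)
  tn <- (ds$temperature - ds$norm$mean["temperature"]) / ds$norm$sd["temperature"]
  pn <- (ds$precipitation - ds$norm$mean["precipitation"]) / ds$norm$sd["precipitation"]
  for (w in seq_along(starts)) {
    sel <- idx[starts[w] + 0:(window - 1L)]
    x[w, , 1L] <- tn[sel]
    x[w, , 2L] <- pn[sel]
    y[w, ] <- ds$ndvi[sel]
  }
  structure(list(x = x, y = y, starts = starts, stride = stride,
                 window = window, pixel_id = ds$pixel_id),
            class = "windowed_samples")
}

#' Cut a pixel dataset into 6-month input/target windows
#'
#' Training windows slide at `train_stride` (default 1, maximizing samples);
#' validation windows tile at `val_stride` (default 6, non-overlapping) so
#' each validation month is predicted exactly once and the concatenated
#' predictions reconstruct the full validation series. Inputs are z-scored
#' per channel with training-split statistics only; NDVI targets are left
#' in NDVI units. Windows never cross the split boundary.
#'
#' @param ds A `pixel_dataset` from [filter_valid_pixels()].
#' @param train_stride,val_stride Window strides in months.
#' @return A list with `windowed_samples` elements `train` and `val`.
#' @export
window_series <- function(ds, train_stride = 1L, val_stride = 6L) {
  stopifnot(inherits(ds, "pixel_dataset"))
  n <- length(ds$ndvi)
  tr_idx <- seq_len(ds$train_months)
  va_idx <- (ds$train_months + 1L):n
  list(train = make_windows(ds, tr_idx, train_stride),
       val = make_windows(ds, va_idx, val_stride))
}
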