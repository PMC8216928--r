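#' @importFrom stats sd rnorm runif lm coef setNames median
#' @importFrom utils head tail
NULL

# Internal: monthly time table for a simulation period.
month_table <- function(n_years, start_year) {
  n <- 12L * n_years
  data.frame(
    t     = seq_len(n),
    year  = start_year + (seq_len(n) - 1L) %/% 12L,
    month = (seq_len(n) - 1L) %% 12L + 1L
  )
}

#' Grid specification for the synthetic study domain
#'
#' Defines a coarse analysis grid (the resolution at which climate is given
#' and models are fitted, emulating 0.5 degree cells) and a fine observation
#' grid for vegetation composites (emulating 0.083 degree cells), linked by
#' an integer refinement factor per axis.
#'
#' @param n_lat,n_lon Coarse grid dimensions (rows, columns), each >= 1.
#' @param fine_factor Fine cells per coarse cell per axis (default 6,
#'   emulating the 0.083 -> 0.5 degree ratio).
#' @param n_years Number of simulated years (default 34, emulating
#'   1982--2015).
#' @param start_year First calendar year of the monthly time axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_lat, n_lon, fine_factor = 6L, n_years = 34L,
                      start_year = 1982L) {
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  fine_factor <- as.integer(fine_factor)
  n_years <- as.integer(n_years); start_year <- as.integer(start_year)
  if (is.na(n_lat) || is.na(n_lon) || n_lat < 1L || n_lon < 1L)
    stop("invalid grid spec: n_lat and n_lon must be positive integers")
  if (fine_factor < 1L) stop("invalid grid spec: fine_factor must be >= 1")
  if (n_years < 1L) stop("invalid grid spec: n_years must be >= 1")
  structure(
    list(n_lat = n_lat, n_lon = n_lon, fine_factor = fine_factor,
         n_years = n_years, start_year = start_year,
         n_months = 12L * n_years,
         fine_lat = n_lat * fine_factor, fine_lon = n_lon * fine_factor,
         time = month_table(n_years, start_year)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d coarse (%d x %d fine, factor %d), %d years (%d-%d)\n",
    x$n_lat, x$n_lon, x$fine_lat, x$fine_lon, x$fine_factor,
    x$n_years, x$start_year, x$start_year + x$n_years - 1L))
  invisible(x)
}

#' Monthly climate grid
#'
#' Container for monthly temperature (degC) and precipitation (mm/month)
#' arrays with dimensions (time, lat, lon) sharing one monthly time axis.
#'
#' @param temperature,precipitation Numeric arrays, dim (n_time, n_lat, n_lon).
#' @param time Data frame with columns `t`, `year`, `month`.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(temperature, precipitation, time) {
  if (!identical(dim(temperature), dim(precipitation)))
    stop("alignment error: temperature and precipitation dims differ")
  if (dim(temperature)[1] != nrow(time))
    stop("alignment error: time axis length does not match arrays")
  if (any(precipitation < 0, na.rm = TRUE))
    stop("precipitation must be non-negative")
  structure(list(temperature = temperature, precipitation = precipitation,
                 time = time,
                 units = c(temperature = "degC", precipitation = "mm/month")),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$temperature)
  cat(sprintf("climate_grid: %d months x %d x %d (degC, mm/month)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' NDVI grid
#'
#' NDVI values per (time, lat, lon) in [-1, 1], with a per-pixel validity
#' mask and a cadence flag: `"15day"` grids carry two composites per
#' calendar month (time axis length 2 x months), `"monthly"` grids one value
#' per month.
#'
#' @param values Numeric array, dim (n_time, n_lat, n_lon); NA marks missing.
#' @param cadence `"15day"` or `"monthly"`.
#' @param time Monthly time table the grid is aligned to (for a 15-day grid
#'   each month owns two consecutive time slices).
#' @param valid Logical matrix (lat, lon); FALSE marks pixels whose whole
#'   series is invalid. Defaults to all TRUE.
#' @return An object of class `ndvi_grid`.
#' @export
ndvi_grid <- function(values, cadence = c("monthly", "15day"), time,
                      valid = NULL) {
  cadence <- match.arg(cadence)
  d <- dim(values)
  expected <- if (cadence == "15day") 2L * nrow(time) else nrow(time)
  if (d[1] != expected)
    stop(sprintf("cadence error: %s grid needs %d time slices, got %d",
                 cadence, expected, d[1]))
  if (any(abs(values) > 1, na.rm = TRUE))
    stop("NDVI values must lie in [-1, 1]")
  if (is.null(valid)) valid <- matrix(TRUE, d[2], d[3])
  if (!identical(dim(valid), d[2:3]))
    stop("alignment error: valid mask shape does not match spatial grid")
  structure(list(values = values, cadence = cadence, time = time,
                 valid = valid),
            class = "ndvi_grid")
}

#' @export
print.ndvi_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ndvi_grid (%s): %d slices x %d x %d, %d/%d pixels valid\n",
              x$cadence, d[1], d[2], d[3], sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Land-cover grid
#'
#' Categorical class codes per (lat, lon) cell under an integer scheme
#' (IGBP-style codes `1..n_classes`).
#'
#' @param codes Integer matrix (lat, lon).
#' @param n_classes Number of classes in the scheme (codes must lie in
#'   `1..n_classes`).
#' @return An object of class `landcover_grid`.
#' @export
landcover_grid <- function(codes, n_classes) {
  n_classes <- as.integer(n_classes)
  if (!all(codes %in% seq_len(n_classes)))
    stop("scheme error: land-cover codes outside 1..n_classes")
  structure(list(codes = codes, n_classes = n_classes),
            class = "landcover_grid")
}

#' @export
print.landcover_grid <- function(x, ...) {
  cat(sprintf("landcover_grid: %d x %d, %d-class scheme\n",
              nrow(x$codes), ncol(x$codes), x$n_classes))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------
# Grids travel as long-format CSV (time, lat, lon, value) so every output is
# plain text and byte-reproducible; array metadata rides in the header row.

#' Write a gridded array to long-format CSV
#'
#' Serializes a `climate_grid`, `ndvi_grid` or `landcover_grid` as tidy CSV
#' (one row per cell per time slice) with deterministic row order, so that
#' reruns under the same seed produce byte-identical files.
#'
#' @param grid A grid object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  df <- grid_to_df(grid)
  data.table::fwrite(df, path, nThread = 1L)
  invisible(path)
}

#' Flatten a grid object to a long data frame
#'
#' @param grid A `climate_grid`, `ndvi_grid` or `landcover_grid`.
#' @return A `data.frame` with one row per cell (and time slice).
#' @export
grid_to_df <- function(grid) {
  if (inherits(grid, "climate_grid")) {
    d <- dim(grid$temperature)
    idx <- expand.grid(t = seq_len(d[1]), lat = seq_len(d[2]),
                       lon = seq_len(d[3]))
    data.frame(idx,
               temperature = as.vector(grid$temperature),
               precipitation = as.vector(grid$precipitation))
  } else if (inherits(grid, "ndvi_grid")) {
    d <- dim(grid$values)
    idx <- expand.grid(t = seq_len(d[1]), lat = seq_len(d[2]),
                       lon = seq_len(d[3]))
    data.frame(idx, ndvi = as.vector(grid$values),
               valid = as.vector(grid$valid[cbind(idx$lat, idx$lon)]))
  } else if (inherits(grid, "landcover_grid")) {
    idx <- expand.grid(lat = seq_len(nrow(grid$codes)),
                       lon = seq_len(ncol(grid$codes)))
    data.frame(idx, code = as.vector(grid$codes))
  } else stop("unsupported grid class")
}
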