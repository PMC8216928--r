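# Compositing, regridding, dominant land cover, validity filtering and
# windowing against hand-computed fixtures.

make_15day_grid <- function(vals_by_month, n_lat = 1, n_lon = 1) {
  # vals_by_month: list of c(first, second) composites for one pixel
  n_m <- length(vals_by_month)
  a <- array(NA_real_, c(2 * n_m, n_lat, n_lon))
  for (m in seq_len(n_m)) {
    a[2 * m - 1, , ] <- vals_by_month[[m]][1]
    a[2 * m, , ] <- vals_by_month[[m]][2]
  }
  ndvi_grid(a, "15day", month_table_for(n_m))
}

month_table_for <- function(n_m) {
  data.frame(t = seq_len(n_m), year = 2000 + (seq_len(n_m) - 1) %/% 12,
             month = (seq_len(n_m) - 1) %% 12 + 1)
}

test_that("maximum-value compositing takes the max over available composites", {
  g <- make_15day_grid(list(c(0.3, 0.5), c(0.4, NA), c(NA, NA),
                            c(-0.2, -0.1), c(0.7, 0.7), c(0.1, 0.6)))
  mon <- mvc_composite(g)
  expect_equal(mon$cadence, "monthly")
  expect_equal(as.vector(mon$values), c(0.5, 0.4, NA, -0.1, 0.7, 0.6))

  # commutes with monotone rescaling of all composites
  g2 <- g
  g2$values <- g$values^3          # odd power: monotone, stays in [-1, 1]
  expect_equal(as.vector(mvc_composite(g2)$values),
               as.vector(mon$values)^3)

  # odd composite count is a cadence error
  bad <- g
  bad$values <- g$values[-1, , , drop = FALSE]
  expect_error(mvc_composite(bad), "cadence|time slices")
})

test_that("mean regridding averages blocks, ignoring missing cells", {
  a <- array(NA_real_, c(1, 2, 2))
  a[1, , ] <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  g <- ndvi_grid(a, "monthly", month_table_for(1))
  expect_equal(as.vector(regrid_mean(g, 2)$values), 0.5)
  expect_identical(regrid_mean(g, 1), g)

  # missing cell is ignored; all-missing block stays missing
  a[1, 1, 1] <- NA
  g2 <- ndvi_grid(a, "monthly", month_table_for(1))
  expect_equal(as.vector(regrid_mean(g2, 2)$values), mean(c(0.4, 0.6, 0.8)))
  a[1, , ] <- NA
  g3 <- ndvi_grid(a, "monthly", month_table_for(1))
  expect_true(is.na(regrid_mean(g3, 2)$values[1, 1, 1]))
  expect_error(regrid_mean(g, 3), "shape error")
})

test_that("regridding preserves the global mean on fully valid grids", {
  set.seed(31)
  a <- array(runif(5 * 6 * 9, -1, 1), c(5, 6, 9))
  g <- ndvi_grid(a, "monthly", month_table_for(5))
  coarse <- regrid_mean(g, 3)
  expect_equal(mean(coarse$values), mean(a), tolerance = 1e-12)
})

test_that("dominant land cover takes the modal class, lowest code on ties", {
  codes <- matrix(7L, 6, 6)
  codes[1:4, 1:4] <- 2L   # 16 of class 2, 20 of class 7
  lc <- landcover_grid(codes, 10)
  expect_equal(dominant_landcover(lc, 6)$codes[1, 1], 7L)

  tie <- matrix(c(rep(3L, 18), rep(9L, 18)), 6, 6)
  expect_equal(dominant_landcover(landcover_grid(tie, 10), 6)$codes[1, 1], 3L)

  expect_identical(dominant_landcover(lc, 1), lc)
  expect_error(dominant_landcover(lc, 4), "shape error")
})

test_that("strict validity filter excludes any pixel with a gap", {
  spec <- grid_spec(6, 6, fine_factor = 1, n_years = 2)
  params <- response_params(noise_sd = 0, ar_coef = 0)
  clim <- generate_climate(spec, params, seed = 9)
  nd <- mvc_composite(generate_ndvi(clim, spec, params, seed = 9)$ndvi)

  all_ds <- filter_valid_pixels(nd, clim, train_months = 12L)
  expect_length(all_ds, 36)
  expect_equal(vapply(all_ds, function(d) d$pixel_id, double(1)), 1:36)

  masked <- inject_invalid(nd, 0.25, seed = 2)
  expect_length(filter_valid_pixels(masked, clim, train_months = 12L), 27)

  # one missing month anywhere excludes the pixel
  nd$values[5, 2, 3] <- NA
  expect_length(filter_valid_pixels(nd, clim, train_months = 12L), 35)

  all_na <- nd
  all_na$values[] <- NA
  expect_error(filter_valid_pixels(all_na, clim, train_months = 12L),
               "empty-dataset")
})

test_that("windowing yields the documented counts and no split leakage", {
  spec <- grid_spec(1, 1, fine_factor = 1, n_years = 34)
  params <- response_params(noise_sd = 0, ar_coef = 0)
  clim <- generate_climate(spec, params, seed = 4)
  nd <- mvc_composite(generate_ndvi(clim, spec, params, seed = 4)$ndvi)
  ds <- filter_valid_pixels(nd, clim, train_months = 264L)[[1]]

  sw <- window_series(ds)
  expect_equal(dim(sw$train$x), c(259, 6, 2))   # 264 - 6 + 1
  expect_equal(dim(sw$val$x), c(24, 6, 2))      # 144 / 6

  sw6 <- window_series(ds, train_stride = 6L)
  expect_equal(dim(sw6$train$x)[1], 44)         # 264 / 6

  # validation tiling reconstructs the 144 months exactly once, in order
  val_y <- as.vector(t(sw$val$y))
  expect_equal(val_y, ds$ndvi[265:408])

  # train windows never reach past month 264
  expect_lte(max(sw$train$starts) + 5, 264)

  # normalization constants come from the training months only
  expect_equal(unname(ds$norm$mean["temperature"]),
               mean(ds$temperature[1:264]))
  expect_equal(unname(ds$norm$sd["precipitation"]),
               sd(ds$precipitation[1:264]))
  # and the normalized training inputs have mean ~0 under those constants
  expect_equal(mean((ds$temperature[1:264] - ds$norm$mean["temperature"]) /
                      ds$norm$sd["temperature"]), 0, tolerance = 1e-12)

  tiny <- ds
  tiny$train_months <- 405L   # validation split shorter than one window
  expect_error(window_series(tiny), "window error")
})
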