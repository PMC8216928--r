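# Synthetic generator: determinism, analytic structure, invariants.

test_that("grid_spec validates dimensions and builds the fine grid", {
  s <- grid_spec(3, 4, fine_factor = 6, n_years = 2, start_year = 1990)
  expect_equal(c(s$fine_lat, s$fine_lon), c(18, 24))
  expect_equal(s$n_months, 24)
  expect_equal(nrow(s$time), 24)
  expect_error(grid_spec(0, 4), "invalid grid spec")
  expect_error(grid_spec(2, 2, fine_factor = 0), "fine_factor")
})

test_that("climate generation is deterministic and honours the trend", {
  spec <- grid_spec(2, 2, fine_factor = 1, n_years = 34)
  params <- response_params(trend_per_year = 0.05)
  c1 <- generate_climate(spec, params, seed = 7)
  c2 <- generate_climate(spec, params, seed = 7)
  expect_identical(c1$temperature, c2$temperature)
  expect_identical(c1$precipitation, c2$precipitation)
  c3 <- generate_climate(spec, params, seed = 8)
  expect_false(identical(c1$temperature, c3$temperature))

  # no trend, no noise: every July identical at each pixel
  p0 <- response_params(trend_per_year = 0)
  c0 <- generate_climate(spec, p0, seed = 1, temp_noise_sd = 0,
                         precip_noise_sd = 0)
  julys <- c0$temperature[c0$time$month == 7, 1, 1]
  expect_equal(max(julys) - min(julys), 0)

  # 0.05 degC/yr: mean(2011-2015) - mean(1982-1986) = 0.05 * (2013 - 1984)
  cn <- generate_climate(spec, params, seed = 1, temp_noise_sd = 0,
                         precip_noise_sd = 0)
  yrs <- cn$time$year
  dtmp <- mean(cn$temperature[yrs >= 2011, 1, 1]) -
    mean(cn$temperature[yrs <= 1986, 1, 1])
  expect_equal(dtmp, 0.05 * (2013 - 1984), tolerance = 1e-12)
  expect_true(all(cn$precipitation >= 0))
})

test_that("NDVI generation couples to climate as the weights dictate", {
  spec <- grid_spec(1, 1, fine_factor = 2, n_years = 20)
  # no coupling, no noise: a pure seasonal cycle, identical across years
  p0 <- response_params(w_T = 0, w_P = 0, noise_sd = 0, ar_coef = 0)
  clim <- generate_climate(spec, p0, seed = 3)
  nd0 <- generate_ndvi(clim, spec, p0, seed = 3)$ndvi
  expect_equal(dim(nd0$values), c(2 * spec$n_months, 2, 2))
  expect_true(all(abs(nd0$values) <= 1))
  y1 <- nd0$values[1:24, 1, 1]
  for (yr in 1:(spec$n_years - 1))
    expect_equal(nd0$values[yr * 24 + 1:24, 1, 1], y1)

  # temperature-only pixel: annual NDVI tracks temperature, not precipitation
  pT <- response_params(w_T = 0.5, w_P = 0, noise_sd = 0.005, ar_coef = 0)
  ndT <- generate_ndvi(clim, spec, pT, seed = 4)
  expect_equal(ndT$truth$class, "temperature")
  mon <- mvc_composite(ndT$ndvi)
  ann <- function(x) as.numeric(tapply(x, clim$time$year, mean))
  a_n <- ann(mon$values[, 1, 1])
  a_t <- ann(clim$temperature[, 1, 1])
  a_p <- ann(clim$precipitation[, 1, 1])
  expect_gt(abs(cor(a_n, a_t)), abs(cor(a_n, a_p)))

  # determinism and shape guards
  ndT2 <- generate_ndvi(clim, spec, pT, seed = 4)
  expect_identical(ndT$ndvi$values, ndT2$ndvi$values)
  bad_spec <- grid_spec(2, 2, fine_factor = 2, n_years = 20)
  expect_error(generate_ndvi(clim, bad_spec, pT, seed = 1), "alignment")
})

test_that("truth classes follow the weight sign pattern", {
  spec <- grid_spec(2, 3, fine_factor = 1, n_years = 3)
  des <- sensitivity_design(spec, 2, 2, 2)
  params <- response_params(w_T = des$w_T, w_P = des$w_P, noise_sd = 0,
                            ar_coef = 0)
  clim <- generate_climate(spec, params, seed = 2)
  truth <- generate_ndvi(clim, spec, params, seed = 2)$truth
  expect_equal(truth$class, des$class)
  expect_true(all(truth$w_T[truth$class == "precipitation"] == 0))
  expect_true(all(truth$w_P[truth$class == "temperature"] == 0))
})

test_that("land cover is clumped, in range, and deterministic", {
  spec <- grid_spec(3, 3, fine_factor = 6, n_years = 1)
  lc1 <- generate_landcover(spec, 5, seed = 1)
  lc2 <- generate_landcover(spec, 5, seed = 1)
  expect_identical(lc1$codes, lc2$codes)
  expect_true(all(lc1$codes %in% 1:5))
  expect_error(generate_landcover(spec, 1, seed = 1), "n_classes")
  # block size spanning the whole grid: one class everywhere
  lc_one <- generate_landcover(spec, 2, seed = 3, block_size = 18L)
  expect_equal(length(unique(as.vector(lc_one$codes))), 1)
})

test_that("invalid injection marks exactly the floor count, reproducibly", {
  spec <- grid_spec(10, 10, fine_factor = 1, n_years = 2)
  params <- response_params(noise_sd = 0, ar_coef = 0)
  clim <- generate_climate(spec, params, seed = 5)
  nd <- generate_ndvi(clim, spec, params, seed = 5)$ndvi
  expect_identical(inject_invalid(nd, 0, seed = 1), nd)
  m1 <- inject_invalid(nd, 0.25, seed = 1)
  expect_equal(sum(!m1$valid), 25)
  idx <- which(!m1$valid, arr.ind = TRUE)
  expect_true(all(vapply(seq_len(nrow(idx)), function(k)
    all(is.na(m1$values[, idx[k, 1], idx[k, 2]])), logical(1))))
  m2 <- inject_invalid(nd, 0.25, seed = 1)
  expect_identical(m1$valid, m2$valid)
  expect_error(inject_invalid(nd, 1, seed = 1), "fraction")
})

test_that("seed streams are independent across stages", {
  spec <- grid_spec(2, 2, fine_factor = 1, n_years = 2)
  params <- response_params()
  c1 <- generate_climate(spec, params, seed = 42)
  # interleaving other stages must not change the climate stream
  invisible(generate_landcover(spec, 4, seed = 42))
  c2 <- generate_climate(spec, params, seed = 42)
  expect_identical(c1$temperature, c2$temperature)
})
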