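# Error-attribution factors against brute-force loops and closed-form OLS.

random_period_grids <- function(n_years = 12, seed = 23) {
  spec <- grid_spec(2, 2, fine_factor = 1, n_years = n_years)
  params <- response_params()
  clim <- generate_climate(spec, params, seed)
  nd <- mvc_composite(generate_ndvi(clim, spec, params, seed)$ndvi)
  list(spec = spec, clim = clim, nd = nd)
}

test_that("the six factors match brute-force loop arithmetic", {
  g <- random_period_grids()
  f <- compute_factors(g$clim, g$nd)
  years <- g$clim$time$year
  uy <- sort(unique(years))
  for (row in seq_len(nrow(f))) {
    i <- f$lat_idx[row]; j <- f$lon_idx[row]
    tt <- g$clim$temperature[, i, j]
    pp <- g$clim$precipitation[, i, j]
    yy <- g$nd$values[, i, j]
    at <- ap <- av <- numeric(length(uy))
    for (k in seq_along(uy)) {
      sel <- years == uy[k]
      at[k] <- mean(tt[sel]); ap[k] <- sum(pp[sel]); av[k] <- mean(yy[sel])
    }
    expect_equal(f$mat[row], mean(at), tolerance = 1e-12)
    expect_equal(f$map[row], mean(ap), tolerance = 1e-12)
    expect_equal(f$dtmp[row],
                 mean(tt[years >= max(uy) - 4]) - mean(tt[years <= min(uy) + 4]),
                 tolerance = 1e-12)
    at_cv <- if (min(at) <= 0 && max(at) >= 0) at + 273.15 else at
    expect_equal(f$iat[row], abs(sd(at_cv) / mean(at_cv)), tolerance = 1e-12)
    expect_equal(f$iap[row], sd(ap) / mean(ap), tolerance = 1e-12)
    expect_equal(f$iav[row], sd(av) / mean(av), tolerance = 1e-12)
  }
})

test_that("factors behave analytically under trend, constancy and scaling", {
  # linear 0.05 degC/yr trend, no noise, 1982-2015: dTMP = 1.45 exactly
  spec <- grid_spec(1, 1, fine_factor = 1, n_years = 34)
  params <- response_params(trend_per_year = 0.05, noise_sd = 0, ar_coef = 0)
  clim <- generate_climate(spec, params, seed = 1, temp_noise_sd = 0,
                           precip_noise_sd = 0)
  nd <- mvc_composite(generate_ndvi(clim, spec, params, seed = 1)$ndvi)
  f <- compute_factors(clim, nd)
  expect_equal(f$dtmp, 1.45, tolerance = 1e-9)

  # constant annual series: all interannual CVs are zero
  p0 <- response_params(trend_per_year = 0, w_T = 0, w_P = 0,
                        noise_sd = 0, ar_coef = 0)
  c0 <- generate_climate(spec, p0, seed = 1, temp_noise_sd = 0,
                         precip_noise_sd = 0)
  n0 <- mvc_composite(generate_ndvi(c0, spec, p0, seed = 1)$ndvi)
  f0 <- compute_factors(c0, n0)
  expect_equal(f0$iat, 0, tolerance = 1e-12)
  expect_equal(f0$iap, 0, tolerance = 1e-12)
  expect_equal(f0$iav, 0, tolerance = 1e-12)

  # doubling precipitation doubles MAP and leaves IAP unchanged
  g <- random_period_grids()
  f1 <- compute_factors(g$clim, g$nd)
  c2 <- g$clim; c2$precipitation <- 2 * c2$precipitation
  f2 <- compute_factors(c2, g$nd)
  expect_equal(f2$map, 2 * f1$map, tolerance = 1e-12)
  expect_equal(f2$iap, f1$iap, tolerance = 1e-12)

  # too short a period for the two change windows
  short <- grid_spec(1, 1, fine_factor = 1, n_years = 8)
  cs <- generate_climate(short, p0, seed = 2)
  ns <- mvc_composite(generate_ndvi(cs, short, p0, seed = 2)$ndvi)
  expect_error(compute_factors(cs, ns), "window error")
})

test_that("CV-factor regression matches closed-form OLS", {
  set.seed(41)
  n <- 30
  x <- runif(n); cvv <- 0.1 + 0.3 * x + rnorm(n, 0, 0.02)
  vals <- data.frame(pixel_id = 1:n, cv = cvv)
  factors <- data.frame(pixel_id = 1:n, iav = x)
  r <- regress_cv_on_factor(vals, factors, "iav")
  # closed-form slope/intercept
  b <- sum((x - mean(x)) * (cvv - mean(cvv))) / sum((x - mean(x))^2)
  a <- mean(cvv) - b * mean(x)
  expect_equal(r$slope, b, tolerance = 1e-12)
  expect_equal(r$intercept, a, tolerance = 1e-12)
  expect_equal(r$r_squared, cor(x, cvv)^2, tolerance = 1e-12)
  expect_lt(r$p_value, 0.05)

  # exact linearity gives R^2 = 1; zero variance is degenerate
  vals2 <- data.frame(pixel_id = 1:n, cv = 0.1 + 0.2 * x)
  expect_equal(regress_cv_on_factor(vals2, factors, "iav")$r_squared, 1)
  factors$iav <- 1
  expect_error(regress_cv_on_factor(vals, factors, "iav"), "degenerate")

  # independent factor on large n: R^2 near zero
  set.seed(52)
  n2 <- 400
  vals3 <- data.frame(pixel_id = 1:n2, cv = runif(n2))
  fac3 <- data.frame(pixel_id = 1:n2, iav = runif(n2))
  expect_lt(regress_cv_on_factor(vals3, fac3, "iav")$r_squared, 0.03)
})

test_that("land-cover strata aggregate and order by mean CV", {
  vals <- data.frame(pixel_id = 1:6, cv = c(0.1, 0.2, 0.05, 0.07, 0.3, 0.25))
  datasets <- lapply(1:6, function(i)
    structure(list(pixel_id = i, landcover = c(1L, 1L, 2L, 2L, 3L, 3L)[i]),
              class = "pixel_dataset"))
  s <- landcover_strata(vals, datasets)
  expect_equal(nrow(s), 3)
  expect_equal(s$mean_cv[s$landcover_code == 1], 0.15)
  expect_equal(s$landcover_code, c(2L, 1L, 3L))   # sorted by mean CV
  expect_equal(s$n_pixels, rep(2L, 3))
})
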