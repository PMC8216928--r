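# Shared fixtures, built in code. Heavy fitted grids are cached per session
# so several test files can reuse one training run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A tiny deterministic single-pixel dataset (fast, noise-free).
tiny_pixel <- function(n_years = 4L, seed = 11L) {
  spec <- grid_spec(1, 1, fine_factor = 1, n_years = n_years,
                    start_year = 2000L)
  params <- response_params(w_T = 0.3, w_P = 0.2, noise_sd = 0, ar_coef = 0)
  clim <- generate_climate(spec, params, seed, temp_noise_sd = 0,
                           precip_noise_sd = 0)
  nd <- generate_ndvi(clim, spec, params, seed)
  mon <- mvc_composite(nd$ndvi)
  list(spec = spec, params = params, climate = clim, monthly = mon,
       ds = filter_valid_pixels(mon, clim, train_months = 12L * (n_years - 1L))[[1]])
}

# Small fitted model on a noise-free pixel: 34-year series, reduced net.
fitted_tiny_model <- function() {
  fixture("fitted_tiny_model", function() {
    px <- tiny_pixel(n_years = 10L, seed = 5L)
    sw <- window_series(px$ds)
    cfg <- model_config(layer_dim = 16L, max_epochs = 100L, patience = 15L,
                        learning_rate = 3e-3, seed = 9L)
    mod <- train_pixel(build_model(cfg), sw$train, cfg)
    list(px = px, sw = sw, cfg = cfg, model = mod)
  })
}
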