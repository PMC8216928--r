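# The three canonical synthetic experiments the pipeline is validated on.
# Each fixes its generator conditions (they define the study, not tuning
# knobs) and exposes only the master seed and the training budget.
#
# Training configuration for these scaled runs: learning rate 3e-3 and a
# plateau stop; the noise-free task reaches its loss floor well inside the
# epoch caps used here (the convergence study is in the methods vignette).

#' Noise-free skill-limit experiment
#'
#' A 6 x 6 coarse grid over 34 years in the fully deterministic limit:
#' all stochastic components (NDVI innovation, AR memory, sub-monthly
#' composite noise, climate noise) are off, so NDVI is an exact function
#' of the observed climate and per-pixel models should approach zero
#' error. Pixels follow a 12/12/12 temperature-only / precipitation-only /
#' mixed sensitivity design.
#'
#' @param seed Master seed.
#' @param max_epochs,patience Training budget per pixel.
#' @param layer_dim Hidden dimension (default 75).
#' @return [run_pipeline()] result (sensitivity/attribution stages off).
#' @export
experiment_noise_free <- function(seed = 1L, max_epochs = 150L,
                                  patience = 12L, layer_dim = 75L) {
  spec <- grid_spec(6, 6, fine_factor = 6, n_years = 34)
  des <- sensitivity_design(spec, 12, 12, 12)
  params <- response_params(w_T = des$w_T, w_P = des$w_P,
                            noise_sd = 0, ar_coef = 0, trend_per_year = 0.03)
  cfg <- model_config(layer_dim = layer_dim, max_epochs = max_epochs,
                      patience = patience, learning_rate = 3e-3, seed = seed)
  run_pipeline(spec, params, cfg, seed,
               climate_args = list(temp_noise_sd = 0, precip_noise_sd = 0),
               run_sensitivity = FALSE, run_attribution = FALSE)
}

#' Sensitivity-class recovery experiment
#'
#' A 36-pixel grid with 12 temperature-only, 12 precipitation-only and 12
#' mixed pixels at low NDVI noise (sd 0.01). Climate is
#' fluctuation-dominated (weak seasonality, strong monthly variability):
#' permutation importance can only attribute sensitivity when the two
#' input channels are not mutually redundant, and a shared strong seasonal
#' cycle makes either channel a proxy for the calendar month and hence for
#' the other. The model still observes climate, so targets remain an
#' (almost) deterministic function of its inputs.
#'
#' @param seed Master seed.
#' @param n_repeats Permutation repeats per feature (default 50).
#' @param max_epochs,patience Training budget per pixel.
#' @param layer_dim Hidden dimension (default 75).
#' @return [run_pipeline()] result including the sensitivity stage; the
#'   `truth` element carries the generating classes.
#' @export
experiment_sensitivity <- function(seed = 1L, n_repeats = 50L,
                                   max_epochs = 60L, patience = 10L,
                                   layer_dim = 75L) {
  spec <- grid_spec(6, 6, fine_factor = 6, n_years = 34)
  des <- sensitivity_design(spec, 12, 12, 12)
  params <- response_params(w_T = des$w_T, w_P = des$w_P, season_amp = 0,
                            noise_sd = 0.01, ar_coef = 0,
                            trend_per_year = 0)
  cfg <- model_config(layer_dim = layer_dim, max_epochs = max_epochs,
                      patience = patience, learning_rate = 3e-3, seed = seed)
  run_pipeline(spec, params, cfg, seed, n_repeats = n_repeats,
               climate_args = list(temp_season_range = c(1, 1),
                                   temp_noise_sd = 4,
                                   precip_season_frac = 0.1,
                                   precip_noise_sd = 40),
               run_attribution = FALSE)
}

#' Error-attribution mechanism experiment
#'
#' A grid whose NDVI innovation noise rises across pixels, so interannual
#' vegetation variability (IAV) and model error rise together: the
#' regression of model CV on IAV should recover a positive slope.
#'
#' @param seed Master seed.
#' @param n_lat,n_lon Grid dimensions (default 4 x 5).
#' @param noise_range NDVI innovation sd at the first and last pixel
#'   (linear ramp in pixel order).
#' @param max_epochs,patience Training budget per pixel.
#' @param layer_dim Hidden dimension (default 75).
#' @return [run_pipeline()] result including the attribution stage.
#' @export
experiment_cv_iav <- function(seed = 1L, n_lat = 4L, n_lon = 5L,
                              noise_range = c(0.005, 0.12),
                              max_epochs = 60L, patience = 10L,
                              layer_dim = 75L) {
  spec <- grid_spec(n_lat, n_lon, fine_factor = 6, n_years = 34)
  n_pix <- n_lat * n_lon
  noise <- matrix(seq(noise_range[1], noise_range[2], length.out = n_pix),
                  n_lat, n_lon, byrow = TRUE)
  params <- response_params(w_T = 0.2, w_P = 0.2, noise_sd = noise,
                            ar_coef = 0.3, trend_per_year = 0.03)
  cfg <- model_config(layer_dim = layer_dim, max_epochs = max_epochs,
                      patience = patience, learning_rate = 3e-3, seed = seed)
  run_pipeline(spec, params, cfg, seed, run_sensitivity = FALSE)
}
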