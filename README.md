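# vegclim

Per-pixel recurrent modelling of vegetation greenness from monthly
climate, with permutation-importance climate-sensitivity analysis and
model-error attribution — exercised end-to-end on a synthetic gridded
generator with known sensitivity ground truth.

## The problem

How sensitive is vegetation greenness to temperature versus
precipitation, place by place? One line of attack fits an independent
sequence model at every grid cell of a long satellite record: monthly
NDVI (normalized difference vegetation index, unitless, in [−1, 1]) is
predicted from monthly temperature (°C) and precipitation (mm/month),
and the trained models are then interrogated rather than the raw data.
`vegclim` implements that pipeline for researchers in ecological remote
sensing who want the machinery — compositing, aggregation, per-pixel
training, skill scoring, sensitivity classification, error attribution —
as reusable, deterministic, tested R code.

Global satellite archives cannot ship inside a package, so `vegclim`
pairs the pipeline with a synthetic generator that emulates their
structure (15-day fine-grid NDVI composites driven by climate through
known per-pixel sensitivity weights, seasonal climate with a warming
trend, a clumped categorical land-cover layer) and uses the generator's
ground truth to validate every stage.

## The model and statistics

* **Per-pixel model** — two stacked LSTM layers (hidden dimension 75) and
  a dense head map a 6-month window of standardized (T, P) pairs to the
  same 6 months of NDVI (sequence-to-sequence). Trained with Adam on MSE,
  plateau early-stopping, best-loss checkpointing. The recurrent core and
  backpropagation through time are implemented in the package on batched
  matrix algebra and verified against finite differences.
* **Skill** — training RMSE in NDVI units; validation skill is
  CV = RMSE(y, ŷ) / ȳ over a held-out 144-month split (each month
  predicted exactly once by tiled windows). CV < 15% counts as a good
  model.
* **Sensitivity** — permutation importance on the validation split:
  PIT and PIP are the rises in validation MSE when temperature
  (respectively precipitation) is randomly permuted across months;
  PID = PIT − PIP classifies each pixel as temperature-sensitive
  (PID ≥ 0.01), precipitation-sensitive (PID ≤ −0.01) or sensitive to
  both, with biome-level (dominant land-cover) aggregation.
* **Error attribution** — six per-pixel factors (MAT, MAP, ΔTMP = last
  five years minus first five, and the interannual coefficients of
  variation IAT, IAP, IAV) regressed one at a time against model CV, plus
  land-cover stratification of skill.

## Worked example

Fit one noise-free pixel (34 years, deterministic seasonal climate) and
score it:

```r
library(vegclim)

spec    <- grid_spec(1, 1, fine_factor = 1, n_years = 34)
params  <- response_params(w_T = 0.3, w_P = 0.2, noise_sd = 0, ar_coef = 0)
climate <- generate_climate(spec, params, seed = 1,
                            temp_noise_sd = 0, precip_noise_sd = 0)
gen     <- generate_ndvi(climate, spec, params, seed = 1)
monthly <- mvc_composite(gen$ndvi)               # max-value compositing
ds      <- filter_valid_pixels(monthly, climate)[[1]]  # 264/144 split
sw      <- window_series(ds)                     # 259 train / 24 val windows

cfg   <- model_config(max_epochs = 80, patience = 10,
                      learning_rate = 3e-3, seed = 1)
model <- train_pixel(build_model(cfg), sw$train, cfg)
validate_pixel(model, ds)
```

```
train RMSE = 0.0097 (80 epochs)
validation CV = 0.044 -> good
```

The training error sits below the 0.01 threshold and the validation CV
far below 15%: with all noise off, NDVI is an exact function of the
observed climate and the model recovers it. Sensitivity analysis on a
temperature-only pixel (`w_P = 0`, fluctuation-dominated climate so the
two channels are not redundant):

```r
pit <- permutation_importance(model, sw$val, "temperature",  n_repeats = 10, seed = 1)
pip <- permutation_importance(model, sw$val, "precipitation", n_repeats = 10, seed = 2)
classify_pid(pit$pi_value, pip$pi_value)
```

```
PIT = 0.0468, PIP = -0.0002, PID = 0.0470 -> temperature
```

Permuting temperature costs 0.047 of validation MSE, permuting
precipitation costs nothing — the classification recovers the generating
class. The numbered scripts under `analysis/` run the full grid studies
(simulation → preprocessing → fitting → sensitivity → attribution) and
write their tables under `results/`; the methods vignette
(`vignettes/vegclim-methods.Rmd`) documents the model, the generator and
every open design decision.

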