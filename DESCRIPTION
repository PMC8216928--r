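Package: vegclim
Title: Per-Pixel Recurrent Modelling of Vegetation Greenness from Monthly Climate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gridded vegetation-climate modelling pipeline: synthetic
    generation of 15-day NDVI composites, monthly temperature and
    precipitation grids with known per-pixel climate-sensitivity structure;
    maximum-value compositing, spatial aggregation and strict validity
    filtering down to per-pixel monthly series; per-pixel sequence models
    (two stacked LSTM layers and a dense head over 6-month windows, trained
    with Adam on mean squared error) predicting NDVI from temperature and
    precipitation; model skill scored by RMSE and by the coefficient of
    variation of prediction error; permutation-importance sensitivity
    analysis classifying pixels as temperature-, precipitation- or
    both-sensitive; and attribution of model error to six climate and
    vegetation factors via linear regression across pixels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
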