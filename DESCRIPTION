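Package: entrocast
Title: Entropy-Weighted Combination Forecasting for Daily Air-Quality Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combination forecasting for univariate daily pollutant
    concentration series (PM2.5 and similar). Three base forecasters --
    ARIMA with automatic order selection, a lagged single-hidden-layer
    neural network, and Brown quadratic (triple) exponential smoothing --
    are fused by convex weights derived from the information entropy of
    each method's in-sample accuracy profile. Includes a six-index
    forecast-error evaluation suite (MAE, MPE, RMSE, a relative-error
    Theil inequality coefficient, bias ratio and variance ratio), seeded
    generators for PM2.5-like seasonal series and ARMA processes, a
    packaged 10-day Guangzhou PM2.5 evaluation fixture, and an
    end-to-end pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
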