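Package: pondcast
Title: Hybrid Dissolved-Oxygen Forecasting for Aquaculture Ponds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts dissolved oxygen (DO) in outdoor aquaculture ponds from
    multi-sensor time series. Simultaneous readings from several DO sensors are
    fused into one credible series by a three-layer radial basis function (RBF)
    neural network trained with K-means center selection; a least-squares
    support vector machine (LSSVM) with RBF kernel then forecasts the fused
    series one step ahead from meteorological covariates and the previous fused
    value. The LSSVM kernel width and regularization parameter are tuned by a
    particle swarm optimizer with an adaptive, fitness-proportional inertia
    weight and position mutation. Includes a synthetic pond-data generator with
    diel DO dynamics and sensor fault injection (dropouts, spikes, persistent
    bias), forecast-accuracy metrics (MAE, RMSE, MSE, MAPE, Nash-Sutcliffe
    efficiency, R^2), and an end-to-end reproducible experiment pipeline with a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
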