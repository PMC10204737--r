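Package: siftraits
Title: Retrieval of Photosynthetic Traits from Sun-Induced Chlorophyll
    Fluorescence Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semimechanistic retrieval of crop photosynthetic functional
    traits from canopy sun-induced chlorophyll fluorescence (SIF) time
    series. SIF is converted to the linear electron transport rate (ETR)
    through a nonlinear mechanism involving the fraction of open
    photosystem II reaction centers (qL, modelled as an exponential
    function of photosynthetically active radiation) and the canopy
    fluorescence escape probability (NIRv/FPAR). ETR is then converted to
    the maximum carboxylation rate (Vcmax) under the evolutionary
    optimality assumption that Rubisco-limited and electron-transport
    limited assimilation are co-limiting, and to stomatal conductance (gs)
    through electron-use efficiency and Fick's law of diffusion. The
    package also provides the simple linear SIF-to-Vcmax baseline for
    comparison, evaluation metrics (R2, MAE, RMSE, regression slope,
    accuracy improvement), a one-at-a-time parameter sensitivity analysis
    with analytic elasticity cross-checks, and a forward simulator that
    generates synthetic seasons from known trait trajectories so the whole
    chain can be tested without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
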