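Package: trapbias
Title: Bias of Count-Data Abundance Estimators Under Seasonal Detectability and Trap Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for evaluating how seasonal variation in
    detectability combined with unequal sample sizes (lost pitfall traps)
    biases estimates of relative abundance from count data. Generates
    over-dispersed seasonal trap catches from a Poisson log-normal process
    with site- and trap-level random effects, removes observations under
    targeted or random trap-loss scenarios, fits five competing analyses
    (traditional effort standardization with a Gaussian model, Gaussian and
    negative binomial models with seasonality as a known offset or a free
    factor), and summarizes log-scale bias of the treatment effect estimates
    across Monte Carlo replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
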