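Package: resilink
Title: Feed-Intake Resilience Indicators and Their Gut Microbiota Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives per-animal resilience indicators (lag-1 autocorrelation,
    log residual variance, largest negative-run area, sum of local minima)
    from daily feed-intake time series, and quantifies their association with
    gut microbial composition: centred log-ratio (CLR) transformation and
    Aitchison distances of ASV count tables, alpha diversity, distance-based
    PERMANOVA with housing and breed covariates, microbiability estimation via
    a Bayesian kernel variance-component model with MCMC diagnostics, and
    classification of within-breed resilience classes by partial least squares
    discriminant analysis with VIP-driven feature elimination. Includes a
    synthetic cohort generator with known ground truth (intake-depression
    events, variance components, informative ASVs) and a pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    biomformat,
    coda,
    mixOmics,
    pROC,
    permute,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
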