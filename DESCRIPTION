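Package: microconc
Title: Joint Modeling of Relative and Absolute Microbial Abundances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly models taxon read counts from broad-range sequencing
    (e.g., 16S rRNA amplicons) and observed concentrations for a subset of
    taxa (e.g., taxon-specific qPCR) to estimate the true concentration of
    every taxon in every sample. A hierarchical multinomial-Poisson model
    with lognormal priors accounts for taxon-specific detection efficiency
    of the sequencing assay relative to the concentration assay, and yields
    point estimates, credible intervals for latent concentrations, and
    prediction intervals for unobserved concentrations via MCMC. Also
    provides a simple scaling-factor estimator with delta-method intervals,
    a synthetic-data generator, replicated simulation studies of interval
    coverage and estimation error, and leave-one-taxon-out validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
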