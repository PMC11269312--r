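Package: cryid
Title: Individual Vocal Signatures and Distress Information in Infant Cries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how individual identity and distress level are
    encoded in infant cry acoustics. Provides a seeded synthetic cry
    synthesizer with controllable per-baby vocal signatures and a
    pain-condition effect; extraction of 22 predefined acoustic features
    (amplitude-envelope and spectral moments, autocorrelation pitch tracking
    with pitch saliency, linear-prediction formants); the modulation power
    spectrum (MPS) of the narrow-band log spectrogram with ensemble averages
    and difference maps; principal-component acoustic maps with a
    centroid-distance shrinkage test and condition-discriminant trajectories;
    supervised baby-identity classification (LDA, QDA, random forest) under
    leave-one-out and cross-condition schemes with exact Fisher and binomial
    comparisons; and a Bayesian logistic mixed model (via JAGS) of
    familiar-baby recognition by human listeners, plus a machine-listener
    protocol mirroring the psychoacoustic design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    MASS,
    lme4,
    randomForest,
    rjags,
    coda,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
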