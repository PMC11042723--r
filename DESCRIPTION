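Package: cotswatch
Title: Outbreak Surveillance and Intervention Analysis for Crown-of-Thorns Starfish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing crown-of-thorns starfish (COTS, Acanthaster cf.
    solaris) outbreak surveillance on coral reefs from manta-tow survey records and
    culling logs. Computes reef- and sector-level COTS densities with the
    max-across-programs rule, delimits sector-wide outbreak periods from density
    thresholds, classifies sector management actions and per-reef culling-effort
    strata, converts ordinal coral-cover categories to cover proportions and change
    metrics, and fits hierarchical Bayesian models (beta mixed models for sector
    cover, Gaussian mixed models for wave comparisons and culling-effort contrasts)
    plus penalized-spline trajectory smoothers. Includes a coupled predator-coral
    reefscape simulator that generates realistic synthetic survey data for testing
    every stage of the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
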