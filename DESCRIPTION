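Package: hatchwatch
Title: Identity-Preserving Tracking and Circadian Analysis of Drosophila Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying Drosophila melanogaster development from
    per-frame object detections recorded in standard rearing vials: IoU-based
    identity-preserving tracking with Hungarian assignment and dummy
    augmentation, developmental-stage smoothing, pupation and eclosion event
    extraction, 2-hour event binning with Lomb-Scargle periodogram analysis of
    eclosion rhythms, and a seeded synthetic colony simulator (rhythmic
    inhomogeneous Poisson eclosion, detector-style class confusion noise) so
    the whole pipeline is testable without imaging hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
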