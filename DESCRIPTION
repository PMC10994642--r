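Package: locognosia
Title: Touch-Localization (Locognosia) Analysis for Hand Nerve Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of digital-photograph touch-localization tests of the
    hand after median or ulnar nerve injury. Converts pixel-space target and
    response coordinates to millimetres, computes absolute localization error
    and its longitudinal/transverse decomposition per digit axis, classifies
    misreferrals (responses to the wrong digit or the palm) with the
    digit-palm crease rule, summarizes misreferral structure (confusion
    matrices, arcsine-transformed proportions, chi-squared goodness of fit
    against the unequal-sampling theoretical distribution), constructs
    nerve-territory target sets with homologous pairing and proportional
    matched controls, runs the gated statistical decision trees (Shapiro-Wilk,
    Levene/Welch, rank-test fallbacks, Bonferroni) with partial eta squared
    effect sizes, scores the modified Marsh zone test, and generates fully
    synthetic test sessions with known ground truth so every analysis stage
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    mgcv,
    car,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
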