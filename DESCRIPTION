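Package: hklpi
Title: Hip-Knee Line Angle Screening for Pelvic Incidence Classification
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating and applying a noninvasive screen of
    pelvic incidence (PI) class from lateral-view body-surface landmarks.
    Computes the five hip-knee line (HKL) angle variants and the palpation
    surrogate-PI angle from 2-D sagittal coordinates, derives quartile-based
    S/M/L PI labels and their dichotomies, builds sensitivity/specificity/
    Youden cut-off grids with trapezoidal ROC AUC, applies a cut-off
    acceptance procedure (sensitivity and specificity floor, Youden-maximum
    containment, minimum threshold separation), and assesses intra- and
    inter-rater reliability of the resulting S/M/L screening tool (correct
    rates, Cohen's kappa with analytic confidence intervals, quadratic-
    weighted multi-rater kappa with bootstrap intervals, paired t-tests,
    Landis-Koch bands).  A synthetic-cohort module generates landmark sets
    with known latent PI and HKL angles, and simulated raters with
    configurable confusion structure, so the whole pipeline can be exercised
    and validated without any subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
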