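Package: normdev
Title: Normative Deviation Modelling of Regional Brain Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-region normative models of cortical thickness and
    subcortical volume on a reference cohort using warped Bayesian linear
    regression (sinh-arcsinh likelihood warping) with age and sex covariates
    and additive site effects, recalibrates the fitted models to new scanning
    sites from local control data, and converts patient measurements into
    deviation z-scores. Downstream tools binarize deviations into atrophy
    outliers, compute total outlier counts, regional outlier proportions and
    Hamming-distance dissimilarity, and run age- and sex-adjusted group
    comparisons and clinical-association tests with false discovery rate
    control. A multi-site synthetic cohort generator with known ground truth
    supports calibration and parameter-recovery testing without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
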