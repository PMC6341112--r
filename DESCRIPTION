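Package: morphosite
Title: Multi-Site Brain-Morphometry Classification with Leakage-Free
    Harmonization and Global-Signal Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control classification of regional brain
    morphometry measures pooled across acquisition sites. Implements
    propensity-score matching, a two-step training-only covariate
    normalization (within-dataset age/age^2/sex/ICV residualization with
    cross-cohort coefficient averaging, then between-dataset scanner
    vendor and field-strength adjustment), site-stratified random-forest
    and cost-tuned linear SVM classifiers with leave-site-out,
    within-site out-of-bag and external-specificity evaluation, backward
    feature elimination under the minimum-error-plus-one-standard-
    deviation rule, permutation tests of cross-disorder feature-importance
    overlap, and decomposition of the classifiable signal into global
    grey-matter summary measures. Includes a synthetic multi-site cohort
    generator with known covariate effects, site and vendor batch shifts
    and latent global factors, so the whole pipeline can be exercised
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
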