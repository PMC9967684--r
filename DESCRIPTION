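Package: vitdval
Title: Validation of a Vitamin D Food-Frequency Questionnaire by the
    Method of Triads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relative-validation studies of a vitamin D
    food-frequency questionnaire (FFQ) against a seven-day food record
    and serum 25-hydroxyvitamin D.  Converts item-level questionnaire
    and food-record responses into daily vitamin D intakes, scores a
    15-item sun-exposure questionnaire, and implements the agreement
    battery used in such studies: Wilcoxon signed-rank test with effect
    size, Bland-Altman analysis with the BA index and proportional-bias
    regression, quartile cross-classification with weighted kappa,
    banded Spearman correlations, and the method of triads with
    percentile-bootstrap confidence intervals and covariate-adjusted
    (partial Spearman) variants.  A seed-reproducible synthetic cohort
    generator with a known latent true intake, plus predictive linear
    models of vitamin D status with variance-inflation screening, allow
    every estimator to be exercised against ground truth end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    lmtest,
    nortest,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
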