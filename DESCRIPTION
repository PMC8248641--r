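Package: grainscore
Title: Whole-Grain Intake Classification, Diet-Quality Scoring and
    Survey-Weighted Dietary Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing 24-hour dietary recall data by
    whole-grain (WG) food intake, following the conventions of the 2015
    Canadian Community Health Survey (CCHS) - Nutrition. Classifies foods
    into Canada Food Guide (CFG) groups and tiers, aggregates per-participant
    nutrient and food-group intakes, stratifies participants into four WG
    intake groups by age-specific tertiles among consumers, computes a
    modified Nutrient Rich Food Index (NRF) 9.3 diet-quality score for the
    total diet per 2000 kcal, estimates survey-weighted covariate-adjusted
    least-squares means with bootstrap replicate-weight variance, ordinal
    linear-trend tests, design-corrected chi-squared tests and Tukey-Kramer
    contrasts, and ranks top food sources of whole grain by Bureau of
    Nutritional Sciences (BNS) food group. Includes a synthetic survey
    generator with known ground-truth structure so the whole pipeline is
    testable without access to restricted survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
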