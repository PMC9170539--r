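Package: sdmensemble
Title: Performance-Weighted Ensemble Species Distribution Models with
    Climate-Predictability Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building ensemble species distribution models for
    drought-adapted (CAM/succulent) plants from presence-only occurrence
    records.  Includes derived climate-predictability predictors (annual
    precipitation aggregation, the Hellmann-Eberle wettest/driest-year
    quotient, an Ellenberg-style low-and-unpredictable-rainfall flag,
    aridity and R indices), surface-range-envelope pseudo-absence design
    with multiple seeded realizations, boosted-tree and random-forest
    learners combined by performance-weighted averaging with
    coefficient-of-variation uncertainty, true-skill-statistic and ROC
    evaluation with optimal binary cutoffs, shuffle-based permutation
    variable importance, latitude-aware suitable-area accounting, and a
    synthetic-data generator with a known true niche for end-to-end
    recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
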