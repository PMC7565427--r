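Package: coxen
Title: Enhanced Co-Expression Extrapolation Gene Selection for Multi-Drug
    Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene selection for building general (multi-drug) anti-cancer drug
    response prediction models by co-expression extrapolation (COXEN). Ranks
    genes by their power to predict normalized dose-response AUC for each drug,
    pools the union of top predictive genes across drugs, and keeps the genes
    whose co-expression patterns are best preserved between two sets of cancer
    cases, scored by Lin's concordance correlation coefficient. Also provides
    the original single-pool COXEN selector, three-parameter Hill dose-response
    fitting with dose-range-normalized AUC, between-/within-class variance
    decomposition of drug response, performance-improvement-percentage (PIP)
    summaries, cell-line-disjoint repeated cross-validation benchmarking with a
    pluggable gradient-boosting regressor, and a latent-factor synthetic data
    generator with planted predictive genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml, minpack.lm, xgboost
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
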