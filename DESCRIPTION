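Package: rpsurv
Title: Rank-Product Consensus Detection of Influential Observations in
    Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies observations that are consistently flagged as
    outlying (long-term survivors or early deaths) across several Cox
    proportional hazards sub-models fitted to high-dimensional survival
    data. Martingale residuals from each sub-model are converted to
    per-observation outlyingness ranks, combined with the rank product
    statistic, and assessed against the uniform-rankings null by exact
    counting, recursive upper/lower bounds with a geometric-mean
    approximation, a gamma approximation, or permutation. Includes
    penalized (lasso/elastic-net) and stepwise-AIC sub-model
    construction, Benjamini-Hochberg q-values, a resampling consensus
    over random gene subsets, a synthetic cohort generator with planted
    outliers, and an end-to-end pipeline driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
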