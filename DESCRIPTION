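Package: pupildyn
Title: Dynamical Pupillary Indices and Outcome Prognosis for TBI Coma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-course analysis of categorical bedside pupillary observations
    (size and photo-reactivity, assessed every two hours) in traumatic brain
    injury coma patients. Computes four dynamical indices (jump rates and
    normal-state occupancy percentages) on arbitrary time windows, runs
    pre/post-sedation mixed repeated-measures ANOVA with Bonferroni post-hocs
    and summary-statistic clinical-covariate tests, and performs day-by-day
    outcome prognosis via point-biserial screening, exhaustive logistic model
    selection (likelihood-ratio p-value, BIC, leave-one-out cross-validated
    accuracy, with Firth-penalized fallback under separation) and ROC/AUC
    evaluation. Includes a regime-switching Markov-chain generator of
    synthetic cohorts emulating the data structure of such studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    pROC,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
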