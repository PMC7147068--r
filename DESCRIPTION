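Package: mmlca
Title: Age-Stratified Latent Class Clustering of Multimorbid Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies clusters of multimorbid patients from binary
    long-term-condition indicators using latent class analysis fitted by
    EM with multiple random restarts, stratified by age group. Provides
    model selection (BIC, sample-size-adjusted BIC, parametric bootstrap
    likelihood-ratio test, relative entropy), cluster profiling and
    labelling by most distinctive conditions, hold-out stability
    validation via Jensen-Shannon distance and profile correlation,
    outcome regression (adjusted incidence rate ratios for service use,
    odds ratios for mortality), and a synthetic electronic-health-record
    cohort simulator with known latent-class ground truth for testing
    every stage without access to licensed patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
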