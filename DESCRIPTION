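Package: shellplan
Title: Automated Robotic Radiosurgery Planning with Individualized
    Dose-Spillage Shell Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step automated inverse planning for non-coplanar robotic
    radiosurgery of vestibular schwannoma at desk scale. Generates seeded
    synthetic head phantoms, assembles sparse dose-influence matrices for
    cone-collimated non-coplanar beams, builds distance-transform shells
    around the target, runs a prioritized (lexicographic epsilon-constraint)
    wish-list optimization that minimizes maximum shell doses, extracts
    individualized shell constraints and re-plans under them, and evaluates
    plans with DVH metrics, conformity indices, dose-bath volumes and paired
    exact Wilcoxon signed-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
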