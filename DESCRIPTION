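Package: p3dif
Title: Digital-Filter Observer Models of Trial-by-Trial P300 Amplitudes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Observer models of trial-by-trial P300 amplitude fluctuations in
    serial two-choice tasks. Implements a digital-filter (DIF) observer that
    tracks subjective stimulus probabilities with a short-term IIR low-pass
    filter, a dynamically sharpening long-term IIR low-pass filter, and a
    fourth-order FIR high-pass filter for alternation expectancy, together
    with two competitor observers: an ideal Bayesian event counter without
    forgetting (MAR) and the classic expectancy model of Squires and
    colleagues (SQU). Shannon surprise from each observer enters a
    three-level hierarchical linear-Gaussian model fitted by parametric
    empirical Bayes (EM over variance hyperparameters), yielding log model
    evidence, log-Bayes factors, and goodness of fit. Includes a coordinate
    grid search for the DIF parameters, sequence-history (tree) averaging of
    amplitudes, and a synthetic multi-participant P300 generator for
    parameter- and model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
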