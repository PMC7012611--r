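Package: optobalance
Title: Balanced Cortical Circuit Models of Optogenetic Interneuron Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling and analyzing the response of balanced
    excitatory-inhibitory cortical networks to optogenetic stimulation of
    inhibitory interneurons. Implements the large-N,K balance-equation
    theory for two- and four-population circuits (PC, PV, SOM, VIP/X),
    including piecewise-linear rate solutions under increasing optogenetic
    drive, susceptibility matrices, and criteria for the paradoxical
    effect; a finite-size leaky integrate-and-fire network simulator with
    sparse random connectivity and exponential synapses; spike-train
    analysis of optogenetic recordings (unit classification by spike
    width, normalized spike rates, bootstrap uncertainty, response
    slopes and response-category fractions); and a synthetic-recording
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
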