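Package: epiresect
Title: Epidemic-Model Seizure Propagation and Virtual Resection on Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individualized susceptible-infected-recovered (SIR) models of
    seizure propagation on weighted brain networks. Provides density
    thresholding and exponential-distance-rule surrogate connectomes,
    a discrete-time SIR engine with pattern aggregation, goodness-of-fit
    of simulated seizures against intracranial-EEG activation orders with
    grid fitting of the global density and recovery parameters, multimodal
    seed-probability maps, virtual resections with simulated-annealing
    optimization of seed efficiency, optimal and disconnecting resection
    search, and ROC / exact rank-sum / cross-validated outcome
    classification, exercisable end to end on synthetic patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
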