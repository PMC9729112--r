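Package: flycompass
Title: Ring-Attractor Learning and Compass-Circuit Analysis for the Fly
    Head-Direction System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Drosophila ellipsoid-body head-direction circuit as
    a ring attractor with Hebbian plasticity at visual (ER) to compass (EPG)
    synapses, where the plasticity rate is gated by the fly's rotational
    speed (a dopamine-like "when-to-learn" signal). Provides generators for
    synthetic walking-fly behaviour, closed- and open-loop visual cue
    streams, eight-wedge calcium-imaging bump data and single-cell voltage
    traces; and the matching analysis tools: population-vector averages,
    cue-bump offset and mutual information (Kraskov k-nearest-neighbour
    estimator), circular tuning statistics (Rayleigh, Watson-Williams,
    circular correlation), spike detection, and locomotor regression models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
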