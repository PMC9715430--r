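Package: paleosweep
Title: Hard Selective Sweep Detection in Ancient DNA Allele-Frequency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Composite-likelihood-ratio scans for fixed hard selective sweeps
    in pseudohaploid ancient-genome allele-frequency data, with gene-level
    outlier statistics, cross-population sweep-region aggregation, Weir-
    Cockerham divergence tests, closed-form sweep-origin theory validated
    against a Wright-Fisher Monte-Carlo oracle, and a forward simulation
    framework (multi-branch demography with admixture pulses, additive
    selection, pseudohaploidisation, missingness, panel ascertainment) used
    for power and false-discovery-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
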