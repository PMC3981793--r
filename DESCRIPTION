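Package: thermoscan
Title: Sliding-Window Detection of RNA Thermometers by Two-Temperature
    Structure Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates candidate RNA thermometers in long RNA sequences
    (typically 5' UTRs) by sliding windows of a range of sizes over the
    sequence, predicting the secondary structure of every window at two
    temperatures, and scoring the structural change by base-pair distance.
    Dense dark clusters in the resulting dot plot flag segments whose fold
    is temperature sensitive.  Ships a self-contained reduced
    nearest-neighbor folding engine (minimum-free-energy structures by
    dynamic programming, equilibrium base-pair probabilities by a
    partition-function recursion, and centroid structures), a brute-force
    structure enumerator used as a test oracle, an adapter contract for
    external thermodynamic folders such as RNAfold, a seeded generator of
    synthetic thermometer sequences with known melting behaviour, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ggplot2,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
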