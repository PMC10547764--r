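Package: bindscape
Title: Exhaustive Relative Binding-Energy Landscapes from Randomized-Library Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes transcription-factor binding specificity landscapes from
    paired-end sequencing of a randomized-core double-stranded DNA library.
    Reads from an input (random pool) library and a protein-bound library are
    reduced to counts over all 4^n core sequences after a reverse-complement
    pair-consistency filter; relative binding energies are derived as the
    negative log2 ratio of bound to input proportions, arranged on a recursive
    quadrant K-mer grid for visualization, and summarized as position weight
    matrix sequence logos. A simulation module generates ground-truth assays
    and synthetic paired-end reads, and evaluates estimator accuracy as a
    function of sequencing depth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    lattice,
    rlang,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
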