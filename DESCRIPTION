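Package: mitophylogeo
Title: Whole-Mitogenome Phylogeography of Structured Marine Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for phylogeographic analysis of whole
    mitochondrial genome alignments: microarray base calling with
    differential signal-to-noise thresholds, variable-site classification,
    haplotype collapsing, haplotype and nucleotide diversity, AMOVA variance
    decomposition with permutation inference (Phi-ST, Phi-CT, Phi-SC),
    spatially constrained SAMOVA group search by simulated annealing,
    pairwise Phi-ST matrices with a modified false-discovery-rate critical
    level, Mantel tests of isolation by distance, principal coordinate
    analysis, neighbor-joining trees with bootstrap and outgroup-calibrated
    strict-clock node dating, statistical-parsimony haplotype networks with
    a probability-based connection limit, mismatch distributions with
    sudden-expansion dating, and a Monte Carlo randomization test of
    phylogeographic structure based on Fitch parsimony length. A
    structured-coalescent simulator with known truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
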