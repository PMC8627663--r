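Package: linsyn
Title: Synteny, Rearrangement and Pan-Genome Dynamics of Linear Bacterial
    Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics of linear bacterial chromosomes such as
    those of Streptomyces. Implements fragment-based average nucleotide
    identity (ANIb) with species-level dereplication, terminal inverted
    repeat detection and trimming, reciprocal-best-hit orthology, gene
    family construction with pan/core-genome rarefaction and Heap's-law
    fitting, core-region delimitation, sliding-window synteny indexes
    (orthology rate, gene order conservation, neighbour orthologue
    conservation), double-cut-and-join (DCJ) rearrangement distances on
    shared markers, and portion-wise evolutionary-rate regressions against
    cophenetic distance. A gradient-based simulator of linear-chromosome
    evolution along a phylogeny (telomere-biased inversions, gene gains
    and losses over a conserved central skeleton) provides fully
    ground-truthed data for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
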