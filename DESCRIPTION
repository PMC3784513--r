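Package: mutmotif
Title: Sequence-Context Analysis of Single-Base Substitutions at G:C Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies single-base substitutions at G:C base pairs into
    canonical 5'-NGNN-3' tetranucleotide motifs (the mutated guanine fixed at
    the second position, reverse-strand events folded in by reverse
    complementation), normalizes mutated-motif counts by mappable genome
    content, and computes enrichment and asymmetry statistics: CpG and
    3'-purine group contrasts, recurrent-site motif enrichment, tissue shares,
    transcription-strand ratios, splice-junction positional profiles, and
    log-linear correlations of mutation fractions with embedded
    physicochemical descriptors (vertical ionization potentials of G-centered
    trimers and base-stacking free energies). A synthetic-data module
    generates genomes, gene models, mappability masks and context-biased
    mutation catalogs with known parameters so that every pipeline stage is
    recovery-testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    stringi,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    ape,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    fgsea
Config/testthat/edition: 3
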