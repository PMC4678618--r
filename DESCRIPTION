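Package: mobilomr
Title: Mobilome Mining, Classification and Amplification Dynamics of DNA Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for annotating the mobile fraction of a
    genome assembly, centred on Tc1-mariner DNA transposons. Provides
    transposase-homology mining of element copies (seed-and-extend translated
    search, hit chaining, greedy identity clustering, majority-rule consensus,
    TIR/TSD characterisation and activity calls), de novo discovery of
    miniature inverted-repeat transposable elements (MITEs) from genome
    self-comparison, variable-metric ascending hierarchical classification
    (UPGM-VM) of element families, lineage-through-time amplification-dynamics
    analysis with S/E/L/C shape calls, horizontal-transfer screening with
    synteny-based contamination control, breakpoint analysis of rearranged
    copies, and a truth-bearing synthetic-genome simulator so that every stage
    of the pipeline can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    ape,
    Biostrings,
    IRanges,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
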