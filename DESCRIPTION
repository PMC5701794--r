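Package: tcrarep
Title: TCR-Alpha Repertoire Annotation, Overlap Statistics and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing T cell receptor alpha (TCRa) chain
    repertoires from junction-spanning cDNA reads: germline TRAV/TRAJ
    reference handling with duplication-aware collapsing of
    indistinguishable subfamily members, V/J assignment with
    germline-based sequencing-error correction outside a protected
    junction window, CDR3a extraction and N-region (untemplated base)
    inference, clonotype abundance tables, species accumulation curves
    and Chao1 richness, Jaccard and Chao abundance-based (Chao-Jaccard)
    overlap indices, log2 counts-per-10^4 segment-usage distances with
    hierarchical ordering, cohort-level within- versus between-genotype
    comparisons, and a fully seeded V(D)J rearrangement-and-selection
    simulator that emits reads with complete ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
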