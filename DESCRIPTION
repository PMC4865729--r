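Package: PTMTransfer
Title: Homology-Based Transfer of Post-Translational Modification Sites
    Between Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts post-translational modification (PTM) sites in a query
    proteome by homology to experimentally verified sites in a known
    proteome. Peptide windows centered on annotated sites are searched
    with a local-alignment engine (built-in Smith-Waterman with
    Karlin-Altschul E-value statistics, or an external blastp backend),
    and each candidate transfer is accepted only when the parent proteins
    are reciprocal best hits in the opposing proteomes (the cross-promotion
    E-value benchmark). Includes model construction from FASTA/TSV inputs,
    whole-proteome prediction, precision/recall evaluation with organism
    hold-out, and a synthetic proteome simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Proteomics, Alignment, SequenceMatching, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
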