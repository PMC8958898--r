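Package: taxodiag
Title: Diagnostic DNA Characters, Barcode Divergence and Monophyly Tests
    for Genomic Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers clade-diagnostic DNA characters from annotated
    multi-locus exon alignments, with coverage-aware ranking, a
    sister-clade complement procedure for clades of one or two specimens,
    and bounded disjunctive barcode formulas. Also computes uncorrected
    COI-barcode p-distances with pairwise deletion, clade-vs-clade
    divergence summaries, neighbor-joining trees for desk-scale checks,
    and monophyly tests, and renders taxonomic diagnosis blocks. Includes
    a seeded simulator that plants synapomorphies on a phylogeny with
    museomics-style missing data and per-position read depth, so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
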