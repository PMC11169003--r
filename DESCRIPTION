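Package: dyadscan
Title: Detection and Evolutionary Analysis of CpG Codon Dyads in Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting CpG dinucleotides that span adjacent codons
    (NNC|GNN "codon dyads") in protein-coding sequences and for analysing their
    evolution across species. Provides dyad scanning and density scoring of
    single coding sequences, cross-species conservation calling on codon-aware
    ortholog alignments, a codon-usage null model with a site-level proportion
    test, positional distributions of dyads along the CDS, phylogenetic-signal
    tests (Pagel's lambda and Blomberg's K) of per-species dyad totals, gene-body
    methylation overlays from bedMethyl tracks, developmental expression trend
    tests, and a fully seeded synthetic-data generator that produces codon
    alignments with planted conserved dyad sites, trees, traits, methylation
    tracks and staged expression matrices with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
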