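Package: mora
Title: Oscillating Multi-Omic Patterns and Motifs on Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects oscillating multi-omic patterns on gene-ordered
    sequences and anti-dyadic motifs on protein-centric metabolic
    networks, coupling the two views through multi-layered structures
    (MLS).  Implements dual (organism-wide and pathway-local) z-score
    normalization with binary discretization of protein abundance,
    codon adaptation index and treatment-induced protein variation;
    alternation and similarity scores for discretized patterns; the
    dyadic/anti-dyadic effect model with exact and Monte-Carlo
    placement nulls; the MORA reciprocal-influence algorithm bounded
    by the network average path length; operon compression and
    oscillation-guided path extension of MLSs; and an end-to-end
    pipeline classifying pathways as combined or competitor.  A
    seeded synthetic-organism generator makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
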