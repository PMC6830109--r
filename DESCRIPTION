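Package: retroscan
Title: Retroelement-Linked Enhancer Regulation Scores for Genes and Pathways
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores genes and molecular pathways by the fraction of
    enhancer-associated H3K4me1 ChIP-seq signal that falls on retroelements
    (LINE, SINE, LTR, SVA) within the 10-kb neighborhood of each gene's
    reference transcription start site.  Provides absolute (GRE) and
    relative (NGRE) gene enrichment scores, pathway involvement indices
    (PII/NPII), a zero-intercept trend-line model that isolates the genes
    and pathways most enriched or deficient in retroelement-linked
    regulation, exact hypergeometric over/under-representation tests for
    non-coding RNA gene classes, internal term-enrichment tests (standard
    and EASE variants), a permutation-based empirical q-value control for
    functional annotations, and a synthetic epigenome generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
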