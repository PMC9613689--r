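Package: parawasp
Title: Comparative Genomics of Parasitoid Wasp Venom and Transposon Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for comparative genomics of parasitoid wasps
    (Anastatus and relatives): dating of LTR retrotransposon insertions from
    paired-LTR Kimura two-parameter divergence, small-RNA and piRNA profiling
    with Ping-Pong overlap spectra and Z-scores, venom gene calling from
    venom-gland expression (N90 rule) plus proteomic peptide support,
    classification of venom gene evolutionary origins on gene trees, Wagner
    parsimony dating of orthogroup ages on a time tree, detection of
    non-coding rapidly evolving regions (NRERs) from pairwise whole-genome
    alignment with expression-shift enrichment tests, and weighted gene
    coexpression network analysis of the venom-related module (VRM) including
    cross-species module conservation and shift. Every pipeline stage can be
    exercised on synthetic data with known ground truth via the bundled
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
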