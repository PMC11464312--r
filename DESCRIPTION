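Package: erfnet
Title: AP2/ERF Gene-Family Annotation, Promoter Cis-Element Scanning,
    and Treatment-Response Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide analysis of the plant AP2/ERF
    transcription-factor superfamily: subfamily classification from
    protein-domain evidence (AP2/B3 architectures and the diagnostic
    residues at domain positions 14 and 19), tandem-duplication detection,
    neighbor-joining phylogenies from Poisson-corrected pairwise-deletion
    distances with bootstrap support, strand-aware promoter extraction,
    cis-element scanning for the GCC box and DRE/CRT core in both exact
    IUPAC-consensus and exact-p-value position-weight-matrix modes,
    two-treatment differential-expression calling, partitioning of
    responsive factors into ethylene-dependent, demethylation-dependent
    and shared classes, correlation-based regulator-to-target edge
    inference, hub scoring, and hypergeometric term enrichment. Includes
    a seeded synthetic-data generator with planted ground truth (genome,
    gene models, domain hits, promoter motifs, expression effects and
    regulatory edges) so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    methods,
    yaml,
    ape,
    Biostrings,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
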