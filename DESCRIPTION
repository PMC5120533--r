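Package: hybridexpr
Title: Hybrid-Versus-Parent Transcriptome Analysis of Heterosis
Version: 0.1.0
Authors@R:
    person("Maize", "Transcriptomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for comparing an F1 hybrid's transcriptome
    with its two inbred parents: RPKM quantification and expression binning,
    exact-test differential expression, classification of hybrid expression
    inheritance against the mid-parent value (additive, dominance,
    over-/under-dominance, conserved), allele-specific expression testing at
    transcribed SNPs, cis/trans regulatory decomposition of parental
    expression divergence, and mid-parent/best-parent heterosis statistics.
    Includes a negative-binomial count and allele-count simulator with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
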