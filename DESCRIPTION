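Package: lncherit
Title: Identification, Characterization and Expression Inheritance of Long
    Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for genome-wide discovery of long non-coding
    RNAs (lncRNAs) from transcript catalogs: size and open-reading-frame
    filtering, protein-similarity and coding-potential screening, elimination
    of housekeeping RNAs, and separation of small-RNA precursors from
    high-confidence lncRNAs. Downstream modules characterize lncRNA loci
    (strand inference by the GT-AG rule, gene-proximity anatomy, chromosomal
    bin densities, permutation tests of cross-species sequence conservation),
    profile tissue-specific expression (RPKM, Shannon entropy, Ward
    clustering, metagene epigenetic profiles), and dissect expression
    inheritance in a biparental recombinant-inbred-line panel by composite
    interval mapping with permutation thresholds, 1-LOD support intervals and
    cis/trans classification. Seeded synthetic-data generators emulate every
    input with known ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
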