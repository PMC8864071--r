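Package: longamp
Title: Long-Amplicon Nanopore Variant Calling for Single-Gene Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rapid single-gene genetic testing by
    long-amplicon nanopore sequencing. Provides a gene model with
    genomic/coding coordinate conversion and HGVS parsing, a nanopore-like
    diploid read simulator with homopolymer- and tandem-repeat-inflated
    indel errors, a built-in semi-global aligner with per-strand pileups,
    a frequency-based variant caller with strand bias and binomial
    significance, the exclusion filters used in amplicon diagnostics
    (single-strand calls, tandem-repeat indels with a Fisher exact test
    justification), zygosity classification from variant allele frequency,
    protein consequence prediction including frameshift stop scanning, and
    per-sample diagnostic reports annotated against a recorded-variant
    catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
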