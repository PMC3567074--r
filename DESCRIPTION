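Package: traScan
Title: Splicing-Regulatory Motif Analysis of Sex-Specifically Spliced
    transformer-Like Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of the sex-specifically spliced
    first intron of dipteran transformer (tra) genes and similar loci.
    Represents annotated gene models and their male/female transcript
    isoforms, scans sequences for degenerate IUPAC consensi and position
    frequency matrices (TRA/TRA2, RBP1 and related splicing-enhancer
    elements), builds information-content profiles of aligned binding-site
    windows, scores splice donor sites against the splice-site consensus and
    the 5' end of U1 snRNA, and performs pairwise conservation analysis
    (global alignment identity and similarity, Pustell-style dot matrices,
    conserved blocks and insertion calls, motif-cluster architecture). A
    seeded synthetic-gene generator plants the full regulatory architecture
    so every pipeline stage can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
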