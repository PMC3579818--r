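Package: krabkit
Title: Census, Expression and Chromatin Analysis of KRAB Zinc-Finger Protein Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational analysis of the KRAB zinc-finger
    protein (KRAB-ZFP) gene family: a protein-domain census that scans
    amino-acid sequences for C2H2 zinc fingers and classifies KRAB-containing
    genes as KRAB-ZFP or KRAB-only, detection of genomic gene clusters,
    cross-species ortholog calling from zinc-finger-array homology,
    NanoString nCounter count normalization (negative-probe background
    correction, geNorm reference-gene stability, normalization factors) with
    expression calls and group-wise non-parametric differential analysis,
    ChIP-seq interval statistics over promoters and binned gene bodies with
    nearest-ERV distance tests, and delta-delta-CT quantification of qPCR
    data. A seeded synthetic-data generator produces inputs with known
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
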