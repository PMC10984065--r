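Package: skipscreen
Title: Detection of Exon-Skipping Transcripts and Their Genomic Lesions from
    Gene-Specific cDNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for screening a single gene for
    exon-skipping alternative transcripts from full-length cDNA amplicon
    sequencing, and for identifying the genomic lesion that explains them.
    Includes a gene-model coordinate system with HGVS c. annotation of
    intronic positions, a split-read aligner for spliced reads with
    microhomology-aware junction placement, per-subject isoform fraction
    quantification with cohort-level candidate flagging, trio-based calling
    of multi-exon deletions (discordant pairs plus split reads) and
    splice-region single-nucleotide variants with de novo classification,
    and a repeat-element breakpoint intersection step that classifies the
    deletional mechanism (for example Alu-mediated recombination). A
    synthetic-data module generates a PLCG2-like locus, isoform mixtures,
    cohort amplicon reads and trio genomic reads with machine-readable
    truth files, so the whole pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    stringi,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    Rsamtools,
    GenomicAlignments,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
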