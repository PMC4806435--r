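Package: ampliscreen
Title: Batch CRISPR/Cas9 Guide Design and Amplicon-Sequencing Indel Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running batch CRISPR/Cas9 mutagenesis screens from
    guide design through germline screening. Discovers and scores sgRNA
    target sites (GGN19GG and N21GG consensi), enumerates genomic
    off-target matches up to a mismatch budget, selects tail-to-tail
    guide pairs, designs nested screening amplicons with barcoded
    three-round PCR library structure, and quantifies induced indel
    alleles from amplicon deep-sequencing reads with a native
    semiglobal affine-gap aligner, left-alignment normalisation and
    per-sample allele-frequency estimation. Includes screening
    analytics (plate maps, germline-versus-soma concordance, rank-sum
    efficiency comparisons) and a ground-truth simulator for mosaic
    samples and multiplexed libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    generics,
    methods,
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    yaml,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
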