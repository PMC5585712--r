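Package: tnseqr
Title: Conditional Fitness Analysis for Mariner Transposon-Insertion Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for Tn-Seq experiments built on mariner
    (Himar1) transposon libraries, which insert exclusively at TA
    dinucleotides. Enumerates insertable TA sites from a genome, processes
    barcoded MmeI junction reads into per-site count tables (demultiplexing,
    tag trimming, a 16-bp minimum-length rule, zero-mismatch unique mapping
    with ambiguous-read exclusion), and derives per-feature statistics:
    depth-normalized read counts, insertion-site densities, dual-criterion
    essentiality calls, conditional log2 fitness ratios, and apparent
    doubling times under an exponential-growth model. Includes a synthetic
    mariner-library simulator (colony-selection bottleneck, two-arm
    electrode/fumarate outgrowth design, multinomial sequencing of 20-bp
    junction fragments) so every stage is testable against known ground
    truth without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
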