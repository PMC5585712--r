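# TSV / BED / wiggle export of site-count tables

#' Write per-sample site counts as TSV
#'
#' Columns: `sample_id`, `replicon`, `pos0` (0-based), `reads_plus`,
#' `reads_minus`.
#'
#' @param counts Site counts tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tn_write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-count TSV written by [tn_write_counts_tsv()]
#' @param path Input path.
#' @return Site counts tibble.
#' @export
tn_read_counts_tsv <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

counts_to_granges <- function(counts, genome) {
  reads <- counts$reads_plus + counts$reads_minus
  gr <- GenomicRanges::GRanges(
    counts$replicon,
    # BED and browser tracks are 0-based half-open; GRanges is 1-based
    IRanges::IRanges(start = counts$pos0 + 1L, width = 2L),
    score = reads
  )
  GenomeInfoDb::seqlengths(gr) <- genome$length[GenomeInfoDb::seqlevels(gr)]
  gr
}

#' Export one sample's site counts as a BED track
#'
#' Each TA site becomes a 2-bp BED interval (0-based half-open) scored by its
#' total read count.
#'
#' @param counts Site counts tibble for a single sample.
#' @param genome A [tn_genome()].
#' @param path Output path (`.bed`).
#' @return `path`, invisibly.
#' @export
tn_write_counts_bed <- function(counts, genome, path) {
  stopifnot(dplyr::n_distinct(counts$sample_id) <= 1)
  gr <- counts_to_granges(counts, genome)
  names(gr) <- sprintf("ta_%d", counts$pos0)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Export one sample's site counts as a wiggle track
#'
#' Read counts at each TA site's T position, variableStep, for genome
#' browsers.
#'
#' @inheritParams tn_write_counts_bed
#' @param path Output path (`.wig`).
#' @return `path`, invisibly.
#' @export
tn_write_counts_wig <- function(counts, genome, path) {
  stopifnot(dplyr::n_distinct(counts$sample_id) <= 1)
  gr <- GenomicRanges::GRanges(
    counts$replicon,
    IRanges::IRanges(start = counts$pos0 + 1L, width = 1L),
    score = counts$reads_plus + counts$reads_minus
  )
  GenomeInfoDb::seqlengths(gr) <- genome$length[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}

#' Write a generic tibble as TSV
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tn_write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
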