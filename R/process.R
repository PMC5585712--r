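#' Demultiplex barcoded junction reads and trim the transposon tag
#'
#' Applies the fixed-layout rules for MmeI junction libraries: the sample
#' barcode must match exactly (in the FASTQ header comment as `BC:Z:<barcode>`
#' for `layout = "header"`, or as the first bases of the read for
#' `layout = "inline"`); the transposon tag must follow at its expected offset
#' (read start for header layout, immediately after the barcode for inline).
#' The remaining genomic portion is kept only if it is at least `min_len`
#' bases; portions longer than `max_len` are truncated from the junction end
#' (adaptor read-through). Reads failing barcode or tag recognition are
#' tallied as `undemultiplexed`; every input read is accounted for.
#'
#' @param fastq Path to a FASTQ file (reads from any mix of samples).
#' @param barcode_table Tibble with `sample_id` and `barcode` columns;
#'   barcodes must be distinct and of equal length.
#' @param transposon_tag The fixed transposon-end sequence to trim.
#' @param min_len Minimum genomic length retained after trimming (default 16).
#' @param max_len Maximum genomic length kept before mapping (default 21;
#'   MmeI fragments are 20 +/- 1 nt).
#' @param layout Barcode layout: `"header"` or `"inline"`.
#' @return List with `reads` (tibble `sample_id`, `read_id`, `seq`) and
#'   `tallies` (tibble `sample_id`, `n_assigned`, `too_short`, plus one
#'   `"<undemultiplexed>"` row) and `n_input`.
#' @export
tn_demultiplex <- function(fastq, barcode_table, transposon_tag,
                           min_len = 16L, max_len = 21L,
                           layout = c("header", "inline")) {
  layout <- match.arg(layout)
  check_barcode_table2(barcode_table)
  if (!nzchar(transposon_tag)) stop_tn("`transposon_tag` must be non-empty")
  if (!file.exists(fastq)) stop_tn("FASTQ not found: ", fastq)

  recs <- Biostrings::readBStringSet(fastq, format = "fastq")
  n_input <- length(recs)
  if (n_input == 0) {
    return(list(
      reads = tibble(sample_id = character(), read_id = character(), seq = character()),
      tallies = tibble(sample_id = character(), n_assigned = integer(),
                       too_short = integer(), undemultiplexed = integer()),
      n_input = 0L
    ))
  }
  seqs <- unname(toupper(as.character(recs)))
  ids <- names(recs)
  bl <- nchar(barcode_table$barcode[1])
  tl <- nchar(transposon_tag)

  if (layout == "header") {
    has_bc <- grepl("BC:Z:", ids, fixed = TRUE)
    bc <- ifelse(has_bc, sub(".*BC:Z:([ACGTN]+).*", "\\1", ids), NA_character_)
    body <- seqs
    tag_off <- 0L
  } else {
    bc <- substr(seqs, 1L, bl)
    body <- substring(seqs, bl + 1L)
    tag_off <- bl
  }
  sample_id <- barcode_table$sample_id[match(bc, barcode_table$barcode)]
  tag_ok <- startsWith(body, transposon_tag)
  assigned <- !is.na(sample_id) & tag_ok

  genomic <- substring(body[assigned], tl + 1L)
  too_short <- nchar(genomic) < min_len
  genomic <- substr(genomic, 1L, max_len)

  reads <- tibble(
    sample_id = sample_id[assigned][!too_short],
    read_id = sub("\\s.*$", "", ids[assigned][!too_short]),
    seq = genomic[!too_short]
  )
  tallies <- tibble(sample_id = sample_id[assigned], short = too_short) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_assigned = sum(!.data$short),
                     too_short = sum(.data$short), .groups = "drop")
  tallies$undemultiplexed <- 0L
  n_undemux <- sum(!assigned)
  if (n_undemux > 0) {
    # reads assignable to no sample are accounted under a pseudo-sample
    tallies <- dplyr::bind_rows(
      tallies,
      tibble(sample_id = "<undemultiplexed>", n_assigned = 0L,
             too_short = 0L, undemultiplexed = n_undemux)
    )
  }
  list(reads = reads, tallies = tallies, n_input = n_input)
}

check_barcode_table2 <- function(barcode_table) {
  stopifnot(all(c("sample_id", "barcode") %in% names(barcode_table)))
  bc <- barcode_table$barcode
  if (anyDuplicated(bc)) stop_tn("barcode collision: ", bc[duplicated(bc)][1])
  if (length(unique(nchar(bc))) != 1) stop_tn("barcodes must have equal length")
  invisible(barcode_table)
}

#' Build a zero-mismatch mapping index over both strands
#'
#' The index supports exact full-length matching of short junction reads
#' against every replicon on both strands (seed length `seed_len` equals the
#' minimum read length, with full-length verification, so the semantics are
#' exact zero-mismatch matching). Matching is performed with Aho-Corasick
#' dictionary search over the read set.
#'
#' @param genome A [tn_genome()].
#' @param seed_len Seed length (default 16, the minimum retained read length).
#' @return A `tn_index` object.
#' @export
tn_build_index <- function(genome, seed_len = 16L) {
  stopifnot(inherits(genome, "tn_genome"))
  subjects <- lapply(genome$seq, function(s) Biostrings::DNAString(gsub("N", "-", s)))
  structure(list(genome = genome, seed_len = as.integer(seed_len),
                 subjects = subjects),
            class = "tn_index")
}

# exact full-length hits of a set of sequences against both strands.
# Returns tibble: qidx, replicon, start1, end1, strand.
index_hits <- function(index, seqs) {
  stopifnot(length(seqs) > 0)
  widths <- nchar(seqs)
  out <- vector("list", 0)
  for (w in unique(widths)) {
    sel <- which(widths == w)
    qset <- Biostrings::DNAStringSet(seqs[sel])
    pd_fwd <- Biostrings::PDict(qset)
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(qset))
    for (repl in names(index$subjects)) {
      subj <- index$subjects[[repl]]
      mf <- Biostrings::matchPDict(pd_fwd, subj)
      mr <- Biostrings::matchPDict(pd_rev, subj)
      sf <- Biostrings::startIndex(mf)
      sr <- Biostrings::startIndex(mr)
      nf <- lengths(sf)
      nr <- lengths(sr)
      if (sum(nf) > 0) {
        out[[length(out) + 1]] <- tibble(
          qidx = rep(sel, nf), replicon = repl,
          start1 = unlist(sf[nf > 0]), strand = "+"
        )
      }
      if (sum(nr) > 0) {
        out[[length(out) + 1]] <- tibble(
          qidx = rep(sel, nr), replicon = repl,
          start1 = unlist(sr[nr > 0]), strand = "-"
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(qidx = integer(), replicon = character(),
                  start1 = integer(), end1 = integer(), strand = character()))
  }
  hits <- dplyr::bind_rows(out)
  hits$end1 <- hits$start1 + nchar(seqs)[hits$qidx] - 1L
  hits
}

# locate the TA site key for a unique alignment, or NA if off-TA.
# + orientation: read starts at the T (site pos0 = start1 - 1);
# - orientation: read's junction end is the A at end1 (site pos0 = end1 - 2).
site_from_alignment <- function(genome, replicon, start1, end1, strand) {
  pos0 <- ifelse(strand == "+", start1 - 1L, end1 - 2L)
  din <- substring(genome$seq[replicon], pos0 + 1L, pos0 + 2L)
  ifelse(din == "TA", pos0, NA_integer_)
}

#' Map junction reads with zero mismatches
#'
#' Each read is matched full-length and exactly against both strands of every
#' replicon. Exactly one genomic locus makes the read `unique` (orientation
#' from the matched strand); two or more make it `ambiguous` (excluded from
#' site assignment but retained in totals, which depth normalization uses);
#' zero make it `unmapped`. Unique alignments are inverted to the canonical TA
#' site key via the junction-geometry convention; a unique alignment not
#' adjacent to any TA is flagged `off_ta` and excluded from site counts.
#'
#' @param reads Tibble with `sample_id` and `seq` (from [tn_demultiplex()]).
#' @param index A [tn_build_index()] object.
#' @return Tibble with one row per read: `sample_id`, `status` (`unique`,
#'   `ambiguous`, `unmapped`, `off_ta`), `replicon`, `pos0`, `orientation`,
#'   `n_candidates`. The set of TA sites adjacent to ambiguous alignments is
#'   attached as attribute `"ambiguous_sites"` (tibble `replicon`, `pos0`),
#'   feeding the per-feature ambiguity flag.
#' @export
tn_map_reads <- function(reads, index) {
  empty_sites <- tibble(replicon = character(), pos0 = integer())
  if (nrow(reads) == 0) {
    out <- tibble(sample_id = character(), status = character(),
                  replicon = character(), pos0 = integer(),
                  orientation = character(), n_candidates = integer())
    attr(out, "ambiguous_sites") <- empty_sites
    return(out)
  }
  useq <- unique(reads$seq)
  hits <- index_hits(index, useq)
  ncand <- tabulate(hits$qidx, nbins = length(useq))

  uniq <- hits[ncand[hits$qidx] == 1L, ]
  upos0 <- site_from_alignment(index$genome, uniq$replicon,
                               uniq$start1, uniq$end1, uniq$strand)
  per_seq <- tibble(
    seq = useq,
    status = dplyr::case_when(ncand == 0L ~ "unmapped",
                              ncand >= 2L ~ "ambiguous",
                              TRUE ~ "unique"),
    replicon = NA_character_, pos0 = NA_integer_,
    orientation = NA_character_, n_candidates = ncand
  )
  per_seq$replicon[uniq$qidx] <- uniq$replicon
  per_seq$pos0[uniq$qidx] <- upos0
  per_seq$orientation[uniq$qidx] <- uniq$strand
  per_seq$status[per_seq$status == "unique" & is.na(per_seq$pos0)] <- "off_ta"

  # TA sites adjacent to any candidate locus of an ambiguous read
  amb <- hits[ncand[hits$qidx] >= 2L, ]
  if (nrow(amb) > 0) {
    apos0 <- site_from_alignment(index$genome, amb$replicon,
                                 amb$start1, amb$end1, amb$strand)
    amb_sites <- tibble(replicon = amb$replicon, pos0 = apos0) |>
      dplyr::filter(!is.na(.data$pos0)) |>
      dplyr::distinct()
  } else {
    amb_sites <- empty_sites
  }

  out <- reads |>
    dplyr::select("sample_id", "seq") |>
    dplyr::left_join(per_seq, by = "seq") |>
    dplyr::select(-"seq")
  attr(out, "ambiguous_sites") <- amb_sites
  out
}

#' Map a single junction read
#'
#' Convenience wrapper around the bulk mapper for one sequence.
#'
#' @param seq A single read sequence (>= 16 nt).
#' @param index A [tn_build_index()] object.
#' @return One-row tibble: `status`, `replicon`, `pos0`, `orientation`,
#'   `n_candidates`.
#' @export
tn_map_read <- function(seq, index) {
  stopifnot(length(seq) == 1)
  out <- tn_map_reads(tibble(sample_id = "query", seq = seq), index)
  dplyr::select(out, -"sample_id")
}

#' Tabulate mapping outcomes into per-site count tables
#'
#' @param mapped Output of [tn_map_reads()].
#' @param tallies Demultiplexing tallies from [tn_demultiplex()] (optional;
#'   zero `too_short`/`undemultiplexed` assumed when absent).
#' @return List with `counts` (tibble `sample_id`, `replicon`, `pos0`,
#'   `reads_plus`, `reads_minus`), `totals` (tibble per sample:
#'   `unique_mapped`, `ambiguous`, `unmapped`, `off_ta`, `too_short`,
#'   `undemultiplexed`, `n_input`; one `"<undemultiplexed>"` row carries reads
#'   assignable to no sample) and `ambiguous_sites`. The accounting invariant
#'   holds: the six category totals sum to `n_input` over all rows.
#' @export
tn_tabulate <- function(mapped, tallies = NULL) {
  counts <- mapped |>
    dplyr::filter(.data$status == "unique") |>
    dplyr::count(.data$sample_id, .data$replicon, .data$pos0, .data$orientation) |>
    tidyr::pivot_wider(names_from = "orientation", values_from = "n",
                       values_fill = 0L) |>
    dplyr::rename_with(~ dplyr::recode(.x, `+` = "reads_plus", `-` = "reads_minus"))
  for (col in c("reads_plus", "reads_minus")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts |>
    dplyr::select("sample_id", "replicon", "pos0", "reads_plus", "reads_minus") |>
    dplyr::arrange(.data$sample_id, .data$replicon, .data$pos0)

  totals <- mapped |>
    dplyr::count(.data$sample_id, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
  for (col in c("unique", "ambiguous", "unmapped", "off_ta")) {
    if (!col %in% names(totals)) totals[[col]] <- 0L
  }
  totals <- dplyr::rename(totals, unique_mapped = "unique")
  if (!is.null(tallies)) {
    totals <- dplyr::full_join(totals, tallies, by = "sample_id") |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ dplyr::coalesce(.x, 0L)))
  } else {
    totals$too_short <- 0L
    totals$undemultiplexed <- 0L
  }
  totals <- totals |>
    dplyr::mutate(n_input = .data$unique_mapped + .data$ambiguous +
                    .data$unmapped + .data$off_ta + .data$too_short +
                    .data$undemultiplexed) |>
    dplyr::select("sample_id", "unique_mapped", "ambiguous", "unmapped",
                  "off_ta", "too_short", "undemultiplexed", "n_input")

  list(counts = counts, totals = totals,
       ambiguous_sites = attr(mapped, "ambiguous_sites") %||%
         tibble(replicon = character(), pos0 = integer()))
}

#' Process barcoded junction FASTQ files into site-count tables
#'
#' Full read-processing chain: demultiplex and trim, zero-mismatch map,
#' assign to TA sites, tabulate. Multiple FASTQ files are processed against
#' the same barcode table and their tables combined.
#'
#' @param fastqs Character vector of FASTQ paths.
#' @param genome A [tn_genome()].
#' @param barcode_table Tibble `sample_id`, `barcode`.
#' @param transposon_tag Transposon-end sequence to trim.
#' @inheritParams tn_demultiplex
#' @param index Optional prebuilt [tn_build_index()].
#' @return As [tn_tabulate()], with per-sample rows aggregated across files.
#' @export
tn_count_reads <- function(fastqs, genome, barcode_table, transposon_tag,
                           min_len = 16L, max_len = 21L,
                           layout = c("header", "inline"), index = NULL) {
  layout <- match.arg(layout)
  index <- index %||% tn_build_index(genome)
  parts <- lapply(fastqs, function(f) {
    dm <- tn_demultiplex(f, barcode_table, transposon_tag,
                         min_len = min_len, max_len = max_len, layout = layout)
    mp <- tn_map_reads(dm$reads, index)
    tn_tabulate(mp, dm$tallies)
  })
  counts <- dplyr::bind_rows(lapply(parts, `[[`, "counts")) |>
    dplyr::group_by(.data$sample_id, .data$replicon, .data$pos0) |>
    dplyr::summarise(reads_plus = sum(.data$reads_plus),
                     reads_minus = sum(.data$reads_minus), .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$replicon, .data$pos0)
  totals <- dplyr::bind_rows(lapply(parts, `[[`, "totals")) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum), .groups = "drop")
  amb <- dplyr::distinct(dplyr::bind_rows(lapply(parts, `[[`, "ambiguous_sites")))
  list(counts = counts, totals = totals, ambiguous_sites = amb)
}
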