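#' Construct a genome object from in-memory sequences
#'
#' A `tn_genome` holds one or more replicons (chromosome plus any plasmids) as
#' uppercase DNA strings. Mariner (Himar1) transposons insert only at TA
#' dinucleotides, so the genome sequence fully determines the set of possible
#' insertion sites (see [ta_sites()]).
#'
#' @param seqs Named character vector of DNA sequences, one per replicon.
#'   Lowercase input is uppercased.
#' @param on_ambiguous How to treat `N` bases: `"error"` (default) rejects the
#'   sequence; `"mask"` keeps them, which silently removes any insertion site
#'   or read alignment overlapping them (exact matching is undefined over N).
#' @return A `tn_genome`: list with `seq` (named character vector) and
#'   `length` (named integer vector of replicon lengths).
#' @export
tn_genome <- function(seqs, on_ambiguous = c("error", "mask")) {
  on_ambiguous <- match.arg(on_ambiguous)
  if (length(seqs) == 0) stop_tn("no sequences supplied (empty genome)")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("replicon_", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  allowed <- if (on_ambiguous == "mask") "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    stop_tn(sprintf(
      "record '%s' contains characters outside {%s}%s",
      names(seqs)[bad][1], paste(strsplit(allowed, "")[[1]], collapse = ","),
      if (on_ambiguous == "error") " (use on_ambiguous = \"mask\" to keep N)" else ""
    ))
  }
  structure(
    list(seq = seqs, length = vapply(seqs, nchar, integer(1))),
    class = "tn_genome"
  )
}

#' @export
print.tn_genome <- function(x, ...) {
  cat(sprintf("<tn_genome> %d replicon(s), %s bp total\n",
              length(x$seq), format(sum(x$length), big.mark = ",")))
  for (id in names(x$seq)) cat(sprintf("  %s: %s bp\n", id, format(x$length[[id]], big.mark = ",")))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Multi-record FASTA files are treated as separate replicons; downstream site
#' keys are (replicon, position) pairs.
#'
#' @param path Path to a FASTA file.
#' @inheritParams tn_genome
#' @return A [tn_genome()] object.
#' @export
tn_read_genome <- function(path, on_ambiguous = c("error", "mask")) {
  if (!file.exists(path)) stop_tn(sprintf("genome FASTA not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop_tn(sprintf("empty FASTA file: %s", path))
  seqs <- as.character(ss)
  # record id = first whitespace-delimited token of the header
  names(seqs) <- sub("\\s.*$", "", names(ss))
  tn_genome(seqs, on_ambiguous = on_ambiguous)
}

#' Write a genome to FASTA
#' @param genome A [tn_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tn_write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Enumerate TA dinucleotide insertion sites
#'
#' Every mariner-insertable position in the genome: offsets `p` (0-based, on
#' the forward strand) with `T` at `p` and `A` at `p + 1`. TA is its own
#' reverse complement, so one forward-strand key canonically identifies a site
#' regardless of which junction side a read later comes from. Overlapping
#' occurrences are impossible for TA, but adjacent ones ("TATA") both count.
#'
#' @param genome A [tn_genome()].
#' @return Tibble with columns `replicon`, `pos0` (0-based offset of the T)
#'   and `context` (the trinucleotide starting at the site, `NA` at a replicon
#'   end), sorted by replicon and position.
#' @export
ta_sites <- function(genome) {
  stopifnot(inherits(genome, "tn_genome"))
  purrr::map_dfr(names(genome$seq), function(id) {
    s <- genome$seq[[id]]
    hits <- Biostrings::matchPattern("TA", Biostrings::DNAString(s), fixed = TRUE)
    p1 <- Biostrings::start(hits) # 1-based T position
    tibble(
      replicon = id,
      pos0 = p1 - 1L,
      context = ifelse(p1 + 2L <= nchar(s), substring(s, p1, p1 + 2L), NA_character_)
    )
  })
}

#' Read feature annotation from a GFF3 file
#'
#' @param path Path to a GFF3 file.
#' @param genome A [tn_genome()]; features must lie within its replicons.
#' @param feature_type GFF3 `type` column value(s) to keep (default `"gene"`).
#' @return Tibble with columns `feature_id`, `replicon`, `start`, `end`
#'   (1-based inclusive), `strand`, `length_bp`, `product`.
#' @export
tn_read_features <- function(path, genome, feature_type = "gene") {
  if (!file.exists(path)) stop_tn(sprintf("annotation GFF3 not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (length(gr) == 0) stop_tn(sprintf("no rows of type %s in %s",
                                       paste(feature_type, collapse = "/"), path))
  ids <- as.character(gr$ID)
  if (!is.null(gr$Name)) ids[is.na(ids)] <- as.character(gr$Name)[is.na(ids)]
  if (anyNA(ids)) stop_tn("feature rows without an ID or Name attribute")
  feats <- tibble(
    feature_id = ids,
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if (is.null(gr$product)) NA_character_ else as.character(gr$product)
  )
  validate_features(feats, genome, path = path)
}

validate_features <- function(feats, genome, path = NULL) {
  dup <- feats$feature_id[duplicated(feats$feature_id)]
  if (length(dup) > 0) stop_tn(sprintf("duplicate feature id: %s", dup[1]))
  unknown <- setdiff(feats$replicon, names(genome$seq))
  if (length(unknown) > 0) stop_tn(sprintf("feature on unknown replicon: %s", unknown[1]))
  glen <- genome$length[feats$replicon]
  bad <- which(feats$start < 1 | feats$end < feats$start | feats$end > glen)
  if (length(bad) > 0) {
    i <- bad[1]
    where <- if (is.null(path)) "" else {
      ln <- grep(feats$feature_id[i], readLines(path), fixed = TRUE)[1]
      if (is.na(ln)) "" else sprintf(" (%s line %d)", path, ln)
    }
    stop_tn(sprintf("feature '%s' has invalid coordinates %d..%d on %s (length %d)%s",
                    feats$feature_id[i], feats$start[i], feats$end[i],
                    feats$replicon[i], glen[i], where))
  }
  feats$strand[!feats$strand %in% c("+", "-")] <- "+"
  feats$length_bp <- feats$end - feats$start + 1L
  dplyr::relocate(as_tibble(feats), "feature_id", "replicon", "start", "end",
                  "strand", "length_bp", "product")
}

#' Write feature annotation to GFF3
#' @param features Feature tibble as returned by [tn_read_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tn_write_features <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$replicon,
    IRanges::IRanges(features$start, features$end),
    strand = features$strand
  )
  gr$type <- "gene"
  gr$ID <- features$feature_id
  gr$product <- features$product %||% NA_character_
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Assign TA sites to features under the 5'-end exclusion rule
#'
#' Insertions in the first fraction of a coding feature frequently fail to
#' disrupt function, so sites in a 5'-proximal window are discounted from all
#' per-feature statistics. A site belongs to a feature when its strand-aware
#' first base (the T for a `+` feature, the A for a `-` feature) lies within
#' `[start, end]`; this convention is exactly symmetric under
#' reverse-complementation of the genome. The excluded window spans
#' `floor(exclusion_fraction * length)` bases from the feature's 5' end (the
#' high-coordinate end for `-` features).
#'
#' @param features Feature tibble (see [tn_read_features()]).
#' @param ta TA-site tibble from [ta_sites()].
#' @param exclusion_fraction Fraction of the feature length excluded at the
#'   5' end (default 0.05). Must satisfy `0 <= exclusion_fraction < 1`.
#' @return Tibble with one row per (feature, overlapping TA site):
#'   `feature_id`, `replicon`, `pos0`, `offset5` (distance of the site's first
#'   base from the 5' end) and `available` (logical; `FALSE` inside the
#'   excluded window).
#' @export
available_sites <- function(features, ta, exclusion_fraction = 0.05) {
  if (!is.numeric(exclusion_fraction) || exclusion_fraction < 0 || exclusion_fraction >= 1) {
    stop_tn("`exclusion_fraction` must be in [0, 1)")
  }
  hits <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    s <- ta[ta$replicon == f$replicon, ]
    if (f$strand == "+") {
      first1 <- s$pos0 + 1L          # 1-based position of the T
      keep <- first1 >= f$start & first1 <= f$end
      offset5 <- first1[keep] - f$start
    } else {
      first1 <- s$pos0 + 2L          # 1-based position of the A
      keep <- first1 >= f$start & first1 <= f$end
      offset5 <- f$end - first1[keep]
    }
    if (!any(keep)) return(NULL)
    tibble(
      feature_id = f$feature_id, replicon = f$replicon,
      pos0 = s$pos0[keep], offset5 = pmax(offset5, 0L)
    )
  })
  if (nrow(hits) == 0) {
    return(tibble(feature_id = character(), replicon = character(),
                  pos0 = integer(), offset5 = integer(), available = logical()))
  }
  win <- floor(exclusion_fraction * features$length_bp)
  names(win) <- features$feature_id
  hits$available <- unname(hits$offset5 >= win[hits$feature_id])
  hits
}

#' Count available sites per feature
#'
#' @param features Feature tibble.
#' @param avail Output of [available_sites()].
#' @return Tibble `feature_id`, `n_available` (sites beyond the excluded
#'   window), `n_overlapping` (all TA sites in the feature). Features with no
#'   overlapping sites get zeros.
#' @export
n_available_sites <- function(features, avail) {
  counts <- avail |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(n_available = sum(.data$available),
                     n_overlapping = dplyr::n(), .groups = "drop")
  features |>
    dplyr::select("feature_id") |>
    dplyr::left_join(counts, by = "feature_id") |>
    dplyr::mutate(dplyr::across(c("n_available", "n_overlapping"),
                                ~ dplyr::coalesce(.x, 0L)))
}

#' Dump the TA-site index as TSV
#' @param ta TA-site tibble from [ta_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
tn_write_ta_tsv <- function(ta, path) {
  utils::write.table(ta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
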