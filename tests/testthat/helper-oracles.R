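# Brute-force oracles and tiny fixture builders, independent of the package's
# own matching machinery.

# position-by-position TA scan (0-based offsets of the T)
bf_ta_scan <- function(seq) {
  n <- nchar(seq)
  if (n < 2) return(integer(0))
  hits <- integer(0)
  for (p in seq_len(n - 1)) {
    if (substr(seq, p, p + 1) == "TA") hits <- c(hits, p - 1L)
  }
  hits
}

bf_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# full-text scan of a read over both strands of every replicon; returns a
# data.frame of loci (replicon, start1, strand)
bf_map_scan <- function(read, seqs) {
  out <- NULL
  w <- nchar(read)
  rc <- bf_revcomp(read)
  for (repl in names(seqs)) {
    s <- seqs[[repl]]
    for (i in seq_len(nchar(s) - w + 1)) {
      sub <- substr(s, i, i + w - 1)
      if (sub == read) out <- rbind(out, data.frame(replicon = repl, start1 = i, strand = "+"))
      if (sub == rc) out <- rbind(out, data.frame(replicon = repl, start1 = i, strand = "-"))
    }
  }
  out
}

# random DNA of length n at 50% GC
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# a small but complete simulation configuration for fast end-to-end tests
small_config <- function(seed = 7L, genome_length = 6e4, n_features = 45L,
                         n_insertions = 600L, depth = 60000L, ...) {
  tn_sim_config(
    seed = seed,
    genome_length = genome_length,
    n_features = n_features,
    feature_length_range = c(500L, 1500L),
    n_insertions = n_insertions,
    depth = depth,
    ...
  )
}

# one-sample sheet used by unit tests
one_sample_sheet <- function() {
  tibble::tibble(sample_id = "s1", barcode = "ACGTAC",
                 condition = "fumarate", replicate = 1L)
}

# write a FASTQ by hand (header layout): ids without '@', seqs
write_fastq <- function(path, ids, seqs) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}
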