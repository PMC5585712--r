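bc_table <- tibble::tibble(sample_id = c("A", "B"),
                           barcode = c("ACGTAC", "CAGTCA"))
TAG <- "ACAGGTTGGATG"

test_that("demultiplexing assigns by exact barcode, trims the tag, enforces 16 bp", {
  set.seed(31)
  fq <- withr::local_tempfile(fileext = ".fastq")
  g20 <- rand_dna(20)
  g15 <- rand_dna(15)
  write_fastq(fq, c("r1 BC:Z:ACGTAC", "r2 BC:Z:ACGTAC", "r3 BC:Z:GGGGGG",
                    "r4 BC:Z:CAGTCA", "r5"),
              c(paste0(TAG, g20), paste0(TAG, g15), paste0(TAG, g20),
                paste0("TTTT", g20), paste0(TAG, g20)))
  dm <- tn_demultiplex(fq, bc_table, TAG)
  expect_equal(dm$n_input, 5L)
  # r1: assigned to A with a 20-nt junction
  expect_equal(dm$reads$sample_id, "A")
  expect_equal(nchar(dm$reads$seq), 20L)
  # r2: too short after trimming; r3: unknown barcode; r4: tag absent; r5: no barcode
  tl <- dm$tallies
  expect_equal(tl$too_short[tl$sample_id == "A"], 1L)
  expect_equal(sum(tl$undemultiplexed), 3L)
  expect_equal(sum(tl$n_assigned) + sum(tl$too_short) + sum(tl$undemultiplexed), 5L)
})

test_that("inline layout reads the barcode from the sequence itself", {
  set.seed(32)
  fq <- withr::local_tempfile(fileext = ".fastq")
  g20 <- rand_dna(20)
  write_fastq(fq, c("r1", "r2"),
              c(paste0("ACGTAC", TAG, g20), paste0("CAGTCA", TAG, g20)))
  dm <- tn_demultiplex(fq, bc_table, TAG, layout = "inline")
  expect_equal(sort(dm$reads$sample_id), c("A", "B"))
  expect_equal(unique(dm$reads$seq), g20)
})

test_that("barcode collisions are rejected at load", {
  bad <- tibble::tibble(sample_id = c("A", "B"), barcode = c("ACGTAC", "ACGTAC"))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(fq, "r1 BC:Z:ACGTAC", paste0(TAG, strrep("A", 20)))
  expect_error(tn_demultiplex(fq, bad, TAG), "collision")
})

test_that("remainders longer than 21 nt are truncated from the junction end", {
  set.seed(33)
  fq <- withr::local_tempfile(fileext = ".fastq")
  g30 <- rand_dna(30)
  write_fastq(fq, "r1 BC:Z:ACGTAC", paste0(TAG, g30))
  dm <- tn_demultiplex(fq, bc_table, TAG)
  expect_equal(dm$reads$seq, substr(g30, 1, 21))
})

test_that("the exact-match mapper agrees with a brute-force full-text scan", {
  set.seed(34)
  seqs <- c(chr = rand_dna(3000), plasmid = rand_dna(1500))
  g <- tn_genome(seqs)
  idx <- tn_build_index(g)
  # reads sampled from the genome (both strands) plus unmappable ones
  reads <- character(0)
  for (i in 1:60) {
    repl <- sample(names(seqs), 1)
    w <- sample(16:21, 1)
    s1 <- sample(nchar(seqs[[repl]]) - w + 1, 1)
    r <- substr(seqs[[repl]], s1, s1 + w - 1)
    if (i %% 2 == 0) r <- bf_revcomp(r)
    reads <- c(reads, r)
  }
  reads <- c(reads, replicate(10, rand_dna(20)))
  got <- tn_map_reads(tibble::tibble(sample_id = "A", seq = reads), idx)
  for (i in seq_along(reads)) {
    bf <- bf_map_scan(reads[i], seqs)
    n_bf <- if (is.null(bf)) 0L else nrow(bf)
    expect_equal(got$n_candidates[i], n_bf, label = sprintf("read %d candidates", i))
    if (n_bf == 1) {
      expect_true(got$status[i] %in% c("unique", "off_ta"))
      expect_equal(got$replicon[i], bf$replicon[1])
      expect_equal(got$orientation[i], bf$strand[1])
    } else if (n_bf == 0) {
      expect_equal(got$status[i], "unmapped")
    } else {
      expect_equal(got$status[i], "ambiguous")
    }
  }
})

test_that("tandem duplication converts unique reads to ambiguous", {
  set.seed(35)
  block <- rand_dna(400)
  sep <- rand_dna(200)
  g_single <- tn_genome(c(chr = paste0(rand_dna(300), block, sep)))
  g_dup <- tn_genome(c(chr = paste0(rand_dna(300), block, sep, block, rand_dna(100))))
  reads <- vapply(1:20, function(i) {
    s1 <- sample(400 - 20 + 1, 1)
    substr(block, s1, s1 + 19)
  }, character(1))
  tb <- tibble::tibble(sample_id = "A", seq = reads)
  before <- tn_map_reads(tb, tn_build_index(g_single))
  after <- tn_map_reads(tb, tn_build_index(g_dup))
  expect_true(all(before$status %in% c("unique", "off_ta")))
  expect_true(all(after$status == "ambiguous"))
  expect_true(all(after$n_candidates >= 2))
})

test_that("a single substitution makes a read unmappable under zero mismatches", {
  set.seed(36)
  seqs <- c(chr = rand_dna(5000))
  g <- tn_genome(seqs)
  idx <- tn_build_index(g)
  s1 <- 1000
  r <- substr(seqs[["chr"]], s1, s1 + 19)
  mutated <- r
  orig <- substr(mutated, 10, 10)
  substr(mutated, 10, 10) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  got <- tn_map_reads(tibble::tibble(sample_id = "A", seq = c(r, mutated)), idx)
  expect_true(got$status[1] %in% c("unique", "off_ta"))
  expect_equal(got$status[2], "unmapped")
})

test_that("junction geometry inverts to the same canonical TA key on both strands", {
  # genome with one TA placed mid-sequence, flanks unique and TA-free
  set.seed(37)
  repeat {
    left <- rand_dna(40); right <- rand_dna(40)
    s <- paste0(left, "TA", right)
    if (length(bf_ta_scan(s)) == 1) break
  }
  g <- tn_genome(c(chr = s))
  idx <- tn_build_index(g)
  pos0 <- 40L  # 0-based offset of the planted T
  plus_read <- substr(s, pos0 + 1, pos0 + 20)
  minus_read <- bf_revcomp(substr(s, pos0 + 2 - 19, pos0 + 2))
  got <- tn_map_reads(tibble::tibble(sample_id = "A",
                                     seq = c(plus_read, minus_read)), idx)
  expect_equal(got$status, c("unique", "unique"))
  expect_equal(got$pos0, c(pos0, pos0))
  expect_equal(got$orientation, c("+", "-"))

  # an alignment not adjacent to any TA is flagged off-TA
  off <- substr(s, 5, 24)
  expect_equal(tn_map_read(off, idx)$status, "off_ta")
})

test_that("tabulation preserves the accounting invariant", {
  mapped <- tibble::tibble(
    sample_id = "A",
    status = c(rep("unique", 90), rep("ambiguous", 6), rep("unmapped", 4)),
    replicon = c(rep("chr", 90), rep(NA, 10)),
    pos0 = c(rep(c(10L, 20L, 30L), 30), rep(NA, 10)),
    orientation = c(rep(c("+", "-", "+"), 30), rep(NA, 10)),
    n_candidates = c(rep(1L, 90), rep(2L, 6), rep(0L, 4))
  )
  tallies <- tibble::tibble(sample_id = "A", n_assigned = 100L, too_short = 0L,
                            undemultiplexed = 0L)
  tab <- tn_tabulate(mapped, tallies)
  expect_equal(tab$totals$unique_mapped, 90L)
  expect_equal(tab$totals$ambiguous, 6L)
  expect_equal(tab$totals$unmapped, 4L)
  expect_equal(tab$totals$n_input, 100L)
  expect_equal(sum(tab$counts$reads_plus + tab$counts$reads_minus), 90L)

  # empty input gives an all-zero table
  empty <- tn_tabulate(mapped[0, ])
  expect_equal(nrow(empty$counts), 0L)
})

test_that("error-free simulated FASTQ round-trips to the exact truth counts", {
  for (seed in c(101L, 202L)) {
    cfg <- small_config(seed = seed)
    sim <- withr::local_tempdir()
    run <- tn_simulate(cfg, sim)
    got <- tn_count_reads(run$paths$fastqs, run$genome,
                          cfg$samples[, c("sample_id", "barcode")],
                          cfg$transposon_tag)
    expect_equal(got$totals$unique_mapped, rep(cfg$depth, 4))
    expect_equal(got$totals$n_input, rep(cfg$depth, 4))
    truth <- dplyr::arrange(run$truth_counts, sample_id, replicon, pos0)
    counts <- dplyr::arrange(got$counts, sample_id, replicon, pos0)
    expect_identical(
      dplyr::select(counts, sample_id, replicon, pos0, reads_plus, reads_minus),
      dplyr::select(truth, sample_id, replicon, pos0, reads_plus, reads_minus)
    )
  }
})

test_that("substitution errors surface as unmapped reads at the expected rate", {
  cfg <- small_config(seed = 9L, depth = 20000L, substitution_error_rate = 0.01)
  exp <- sim_experiment(cfg)
  fq <- withr::local_tempfile(fileext = ".fastq")
  res <- sim_sequence_reads(exp$populations[[1]], exp$genome, cfg, "fumarate_1", fq)
  got <- tn_count_reads(fq, exp$genome, cfg$samples[, c("sample_id", "barcode")],
                        cfg$transposon_tag)
  mappable <- attr(res, "mappable_fraction")
  row <- got$totals[got$totals$sample_id == "fumarate_1", ]
  frac_unique <- row$unique_mapped / cfg$depth
  # errors in the tag surface as undemultiplexed, in the junction as unmapped
  expect_lt(frac_unique, 1)
  expect_equal(frac_unique, mappable, tolerance = 0.05)
})
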