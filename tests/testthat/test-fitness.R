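mk_counts <- function(sample_id, pos0, reads, replicon = "chr") {
  tibble::tibble(sample_id = sample_id, replicon = replicon, pos0 = pos0,
                 reads_plus = reads, reads_minus = 0L)
}

test_that("normalization scales by unique + ambiguous totals", {
  counts <- mk_counts("s1", c(10L, 20L, 30L), c(100L, 50L, 0L))
  totals <- tibble::tibble(sample_id = "s1", unique_mapped = 150L,
                           ambiguous = 0L, unmapped = 0L, off_ta = 0L,
                           too_short = 0L, undemultiplexed = 0L, n_input = 150L)
  # denominator 20M at reference 40M doubles every count
  totals$unique_mapped <- 19999000L
  totals$ambiguous <- 1000L
  norm <- tn_normalize(counts, totals, reference_total = 4e7)
  expect_equal(norm$norm_reads, c(200, 100, 0))

  # a sample already at the reference total is unchanged
  totals$unique_mapped <- 4e7 - 1000L
  norm2 <- tn_normalize(counts, totals, reference_total = 4e7)
  expect_equal(norm2$norm_reads, c(100, 50, 0))

  # equal unique counts but different ambiguous totals scale differently
  t2 <- dplyr::bind_rows(
    tibble::tibble(sample_id = "a", unique_mapped = 100L, ambiguous = 0L),
    tibble::tibble(sample_id = "b", unique_mapped = 100L, ambiguous = 100L)
  )
  c2 <- dplyr::bind_rows(mk_counts("a", c(1L, 5L, 9L), c(60L, 30L, 10L)),
                         mk_counts("b", c(1L, 5L, 9L), c(60L, 30L, 10L)))
  n2 <- tn_normalize(c2, t2, reference_total = 400)
  expect_equal(n2$norm_reads[n2$sample_id == "a"], c(240, 120, 40))
  expect_equal(n2$norm_reads[n2$sample_id == "b"], c(120, 60, 20))

  t2$unique_mapped[1] <- 0L
  t2$ambiguous[1] <- 0L
  expect_error(tn_normalize(c2, t2), "denominator")

  # rank order of sites is preserved within a sample
  expect_equal(order(n2$norm_reads[n2$sample_id == "a"]),
               order(c2$reads_plus[c2$sample_id == "a"]))
})

# a hand-built two-feature genome for aggregation tests:
# featA 1..1000 (+) with TA at 30 (window), 201, 401, 601 (available)
# featB 1101..1300 (+), 200 bp, with a single TA at 1201
agg_fixture <- function() {
  s <- strrep("G", 1500)
  for (p in c(30, 201, 401, 601, 1201)) substr(s, p, p + 1) <- "TA"
  g <- tn_genome(c(chr = s))
  feats <- tibble::tibble(
    feature_id = c("featA", "featB"), replicon = "chr",
    start = c(1L, 1101L), end = c(1000L, 1300L), strand = "+",
    length_bp = c(1000L, 200L), product = NA_character_
  )
  list(genome = g, features = feats, ta = ta_sites(g),
       avail = available_sites(feats, ta_sites(g)))
}

test_that("per-feature aggregation honors the 5' exclusion and density units", {
  fx <- agg_fixture()
  # reads: 10 in featA's window site, 5+5 at two available sites, 7 in featB
  counts <- mk_counts("s1", c(29L, 200L, 400L, 1200L), c(10L, 5L, 5L, 7L))
  totals <- tibble::tibble(sample_id = "s1", unique_mapped = 27L, ambiguous = 0L)
  norm <- tn_normalize(counts, totals, reference_total = 27)
  stats <- tn_feature_stats(norm, fx$features, fx$avail)
  a <- stats[stats$feature_id == "featA", ]
  expect_equal(a$raw_reads, 10)     # window site's 10 reads discounted
  expect_equal(a$sites_hit, 2)
  expect_equal(a$sites_per_kb, 2)   # 2 sites over 1 kb
  b <- stats[stats$feature_id == "featB", ]
  expect_equal(b$raw_reads, 7)
  expect_equal(b$sites_per_kb, 5)   # 1 site over 0.2 kb

  # all reads in the window: zero reads, zero sites
  counts0 <- mk_counts("s1", 29L, 100L)
  norm0 <- tn_normalize(counts0, totals, reference_total = 27)
  stats0 <- tn_feature_stats(norm0, fx$features, fx$avail)
  expect_equal(stats0$raw_reads[stats0$feature_id == "featA"], 0)
  expect_equal(stats0$sites_hit[stats0$feature_id == "featA"], 0)

  # 8 distinct sites on a 1-kb feature = 8 sites/kb
  s8 <- strrep("G", 1000)
  for (p in seq(101, 801, by = 100)) substr(s8, p, p + 1) <- "TA"
  g8 <- tn_genome(c(chr = s8))
  f8 <- tibble::tibble(feature_id = "f", replicon = "chr", start = 1L,
                       end = 1000L, strand = "+", length_bp = 1000L,
                       product = NA_character_)
  av8 <- available_sites(f8, ta_sites(g8))
  c8 <- mk_counts("s1", seq(100L, 800L, by = 100L), rep(3L, 8))
  n8 <- tn_normalize(c8, tibble::tibble(sample_id = "s1", unique_mapped = 24L,
                                        ambiguous = 0L), reference_total = 24)
  st8 <- tn_feature_stats(n8, f8, av8)
  expect_equal(st8$sites_per_kb, 8)

  # ambiguity flag propagates from affected sites to their feature
  statsA <- tn_feature_stats(norm, fx$features, fx$avail,
                             ambiguous_sites = tibble::tibble(replicon = "chr",
                                                              pos0 = 200L))
  expect_true(statsA$contains_ambiguous_sites[statsA$feature_id == "featA"])
  expect_false(statsA$contains_ambiguous_sites[statsA$feature_id == "featB"])
})

test_that("essentiality calls follow the dual-criterion rule and its guards", {
  base <- tibble::tibble(
    feature_id = c("ess", "noness", "empty", "tiny"),
    sample_id = "s1",
    raw_reads = c(250, 8100, 0, 10000),
    norm_reads = c(250, 8100, 0, 10000),
    sites_hit = c(3, 10, 0, 1),
    sites_per_kb = c(3.5, 10, 0, 3),
    n_available = c(20L, 50L, 15L, 1L),
    length_bp = c(1000L, 1000L, 1000L, 200L),
    few_available_sites = c(FALSE, FALSE, FALSE, TRUE),
    contains_ambiguous_sites = FALSE
  )
  both <- tn_classify_essential(base, mode = "both")
  expect_equal(both$call, c("essential", "nonessential", "essential", "low-confidence"))
  either <- tn_classify_essential(base, mode = "either")
  expect_equal(either$call, c("essential", "nonessential", "essential", "low-confidence"))

  # a feature failing only one criterion: essential under "either" only
  one <- base[1, ]
  one$norm_reads <- 250
  one$sites_per_kb <- 6
  expect_equal(tn_classify_essential(one, mode = "both")$call, "nonessential")
  expect_equal(tn_classify_essential(one, mode = "either")$call, "essential")

  # "either" is always a superset of "both"
  set.seed(41)
  rnd <- tibble::tibble(
    feature_id = sprintf("f%d", 1:200), sample_id = "s1",
    raw_reads = stats::runif(200, 0, 1000),
    norm_reads = stats::runif(200, 0, 1000),
    sites_hit = stats::rpois(200, 4),
    sites_per_kb = stats::runif(200, 0, 12),
    n_available = 10L, length_bp = 1000L,
    few_available_sites = FALSE, contains_ambiguous_sites = FALSE
  )
  e_both <- tn_classify_essential(rnd, mode = "both")
  e_either <- tn_classify_essential(rnd, mode = "either")
  expect_true(all(e_both$feature_id[e_both$call == "essential"] %in%
                    e_either$feature_id[e_either$call == "essential"]))

  # the read threshold scales linearly with the reference total
  scaled <- tn_classify_essential(base, reference_total = 4e6)
  expect_equal(attr(scaled, "reads_threshold"), 30)
})

test_that("log2 ratios use the pseudocount and reproduce forced arithmetic", {
  expect_equal(tn_log2_ratio(500, 500), 0)
  expect_equal(tn_log2_ratio(1000, 4000, pseudocount = 0), -2)
  expect_equal(tn_log2_ratio(0, 1000, pseudocount = 1), log2(1 / 1001))
  expect_true(is.finite(tn_log2_ratio(0, 1000)))
  expect_equal(tn_log2_ratio(0, 1000), -9.97, tolerance = 0.001)
})

test_that("apparent doubling time reproduces the exponential-growth model", {
  # the central conversion: L = -2 over 6 generations at 10 h -> 15 h
  expect_equal(tn_doubling_time(-2)$td_h, 15)
  expect_equal(tn_doubling_time(0)$td_h, 10)
  expect_equal(tn_doubling_time(-3)$td_h, 20)  # 60 / 3
  # percent change at the defect cutoff is +50% in doubling time
  expect_equal(tn_doubling_time(-2)$percent_td_change, 50)
  # a net-declining mutant has no finite doubling time
  fumB <- tn_doubling_time(-8)
  expect_true(fumB$declining)
  expect_true(is.na(fumB$td_h))
  # absolute-time override
  expect_equal(tn_doubling_time(-2, total_time_h = 72)$td_h, 72 / 5.2)
})

test_that("apparent doubling time is strictly decreasing in L on its domain", {
  L <- seq(-5.9, 4, by = 0.1)
  td <- tn_doubling_time(L)$td_h
  expect_true(all(diff(td) < 0))
  expect_equal(tn_doubling_time(0)$td_h, 10)
})

test_that("growth classification uses the -2 / +1 cutoffs", {
  expect_equal(tn_classify_defect(c(-3.3, -2, -1, 0, 1.5)),
               c("defective", "defective", "below-threshold",
                 "below-threshold", "enriched"))
})

test_that("library summary arithmetic matches the headline bookkeeping", {
  rec <- tn_recovery_stats(33257, 55000, 4e7)
  expect_equal(rec$ta_recovery_pct, 64)
  expect_equal(rec$reads_per_insertion_display, 1200)
  expect_equal(rec$ta_recovery_pct_nodiscount, 60)

  # on actual tables, both viable-site conventions are exposed
  fx <- agg_fixture()
  counts <- mk_counts("s1", c(200L, 400L, 1200L), c(5L, 5L, 7L))
  summ <- tn_library_summary(counts, fx$ta, fx$features, fx$genome,
                             lethal_features = "featB")
  expect_equal(summ$n_unique_insertions, 3L)
  expect_equal(summ$frac_in_features, 1)
  expect_equal(summ$viable_ta_whole_gene, nrow(fx$ta) - 1L)
  expect_equal(summ$viable_ta_beyond_window, nrow(fx$ta) - 1L)
  expect_equal(summ$insertions_per_kb, 3 / 1.5)

  # empty table: all zeros
  empty <- tn_library_summary(counts[0, ], fx$ta, fx$features, fx$genome)
  expect_equal(empty$n_unique_insertions, 0L)
  expect_equal(empty$total_reads, 0L)
})

test_that("replicate correlation is scale-invariant and guarded", {
  a <- tibble::tibble(feature_id = sprintf("f%d", 1:10),
                      norm_reads = c(0, 5, 10, 0, 3, 8, 2, 7, 1, 4))
  expect_equal(tn_replicate_correlation(a, a), 1)
  b <- a
  b$norm_reads <- 3.7 * a$norm_reads
  expect_equal(tn_replicate_correlation(a, b), 1)
  expect_error(tn_replicate_correlation(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("tn_fitness composes ratios, doubling times and classes per feature", {
  fx <- agg_fixture()
  sheet <- tibble::tibble(
    sample_id = c("ctrl_1", "ctrl_2", "test_1", "test_2"),
    condition = c("fumarate", "fumarate", "electrode", "electrode"),
    replicate = c(1L, 2L, 1L, 2L)
  )
  # featA: 4000 -> 1000 normalized (L ~ -2); featB: unchanged
  counts <- dplyr::bind_rows(
    mk_counts("ctrl_1", c(200L, 400L, 1200L), c(2000L, 2000L, 500L)),
    mk_counts("ctrl_2", c(200L, 400L, 1200L), c(2000L, 2000L, 500L)),
    mk_counts("test_1", c(200L, 400L, 1200L), c(500L, 500L, 500L)),
    mk_counts("test_2", c(200L, 400L, 1200L), c(500L, 500L, 500L))
  )
  totals <- tibble::tibble(sample_id = unique(counts$sample_id),
                           unique_mapped = 100L, ambiguous = 0L)
  norm <- tn_normalize(counts, totals, reference_total = 100)
  stats <- tn_feature_stats(norm, fx$features, fx$avail)
  fit <- tn_fitness(stats, sheet, condition = "electrode", control = "fumarate",
                    pseudocount = 0)
  td <- tidy(fit)
  a <- td[td$feature_id == "featA", ]
  expect_equal(a$L, -2)
  expect_equal(a$td_h, 15)
  expect_equal(a$growth_class, "defective")
  b <- td[td$feature_id == "featB", ]
  expect_equal(b$L, 0)
  expect_equal(b$td_h, 10)
  expect_equal(b$growth_class, "below-threshold")

  g <- glance(fit)
  expect_equal(g$n_features, 2L)
  expect_equal(g$n_defective, 1L)

  # replicate-consistency filter: a defect driven by one replicate is demoted.
  # featA control mean stays 4000; test_1 drops to 100 (L1 ~ -5.3) while
  # test_2 only drops to 1100 (L2 ~ -1.86 > -2), so the mean L ~ -2.74 would
  # be called defective without the filter.
  counts2 <- counts
  counts2$reads_plus[counts2$sample_id == "test_1" & counts2$pos0 %in% c(200L, 400L)] <- 50L
  counts2$reads_plus[counts2$sample_id == "test_2" & counts2$pos0 %in% c(200L, 400L)] <- 550L
  norm2 <- tn_normalize(counts2, totals, reference_total = 100)
  stats2 <- tn_feature_stats(norm2, fx$features, fx$avail)
  fit2 <- tn_fitness(stats2, sheet, pseudocount = 0)
  a2 <- tidy(fit2)[tidy(fit2)$feature_id == "featA", ]
  expect_lt(a2$L, -2)
  expect_equal(a2$growth_class, "below-threshold")
  fit3 <- tn_fitness(stats2, sheet, pseudocount = 0, replicate_filter = FALSE)
  a3 <- tidy(fit3)[tidy(fit3)$feature_id == "featA", ]
  expect_equal(a3$growth_class, "defective")

  # autoplot returns a ggplot without error
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_insertion_density(stats), "ggplot")
})
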