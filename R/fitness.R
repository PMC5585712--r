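#' Depth-normalize site counts between barcoded libraries
#'
#' Scales every site count so that each sample's total mapped reads equal a
#' common reference total. The denominator is `unique_mapped + ambiguous`:
#' ambiguous reads are excluded from site assignment but are genuine library
#' molecules, so they count toward sequencing depth.
#'
#' @param counts Site counts tibble (`sample_id`, `replicon`, `pos0`,
#'   `reads_plus`, `reads_minus`) from [tn_tabulate()].
#' @param totals Per-sample totals tibble from [tn_tabulate()].
#' @param reference_total Reference read total (default 4e7, the depth at
#'   which the classification thresholds are defined).
#' @return The counts tibble with added columns `reads` (plus + minus) and
#'   `norm_reads`; the scaling factors and `reference_total` are attached as
#'   attributes.
#' @export
tn_normalize <- function(counts, totals, reference_total = 4e7) {
  denom <- totals$unique_mapped + totals$ambiguous
  if (any(denom <= 0 & totals$sample_id %in% counts$sample_id)) {
    bad <- totals$sample_id[denom <= 0][1]
    stop_tn("zero normalization denominator for sample ", bad)
  }
  factors <- stats::setNames(reference_total / denom, totals$sample_id)
  out <- counts |>
    dplyr::mutate(
      reads = .data$reads_plus + .data$reads_minus,
      norm_reads = unname(.data$reads * factors[.data$sample_id])
    )
  attr(out, "norm_factors") <- factors
  attr(out, "reference_total") <- reference_total
  out
}

#' Per-feature aggregation under the 5' exclusion rule
#'
#' Sums raw and normalized reads over each feature's available TA sites only
#' (sites in the 5' window are discounted entirely), counts distinct sites
#' hit, and computes the insertion density per kb of full feature length.
#' Features overlapping TA sites affected by ambiguous-read exclusion are
#' flagged, as are features with fewer than 3 available sites; both guards
#' mark essentiality calls as low-confidence.
#'
#' @param norm Normalized counts from [tn_normalize()].
#' @param features Feature tibble.
#' @param avail Site-to-feature assignment from [available_sites()].
#' @param ambiguous_sites Optional tibble (`replicon`, `pos0`) of TA sites
#'   adjacent to ambiguous alignments (from [tn_tabulate()]).
#' @return Tibble with one row per feature x sample: `feature_id`,
#'   `sample_id`, `raw_reads`, `norm_reads`, `sites_hit`, `sites_per_kb`,
#'   `n_available`, `length_bp`, `few_available_sites`,
#'   `contains_ambiguous_sites`. Every feature appears for every sample.
#' @export
tn_feature_stats <- function(norm, features, avail, ambiguous_sites = NULL) {
  samples <- unique(norm$sample_id)
  av <- dplyr::filter(avail, .data$available)
  per_site <- av |>
    dplyr::inner_join(norm, by = c("replicon", "pos0"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$feature_id, .data$sample_id) |>
    dplyr::summarise(
      raw_reads = sum(.data$reads),
      norm_reads = sum(.data$norm_reads),
      sites_hit = sum(.data$reads > 0),
      .groups = "drop"
    )
  n_av <- n_available_sites(features, avail)
  amb_flag <- rep(FALSE, nrow(features))
  if (!is.null(ambiguous_sites) && nrow(ambiguous_sites) > 0) {
    amb_feats <- avail |>
      dplyr::semi_join(ambiguous_sites, by = c("replicon", "pos0")) |>
      dplyr::pull("feature_id") |>
      unique()
    amb_flag <- features$feature_id %in% amb_feats
  }
  grid <- tidyr::expand_grid(
    feature_id = features$feature_id,
    sample_id = samples
  )
  out <- grid |>
    dplyr::left_join(per_site, by = c("feature_id", "sample_id")) |>
    dplyr::mutate(dplyr::across(c("raw_reads", "norm_reads", "sites_hit"),
                                ~ dplyr::coalesce(.x, 0))) |>
    dplyr::left_join(
      dplyr::bind_cols(
        features[, c("feature_id", "length_bp")],
        contains_ambiguous_sites = amb_flag
      ),
      by = "feature_id"
    ) |>
    dplyr::left_join(n_av[, c("feature_id", "n_available")], by = "feature_id") |>
    dplyr::mutate(
      sites_per_kb = .data$sites_hit / (.data$length_bp / 1000),
      few_available_sites = .data$n_available < 3L
    ) |>
    dplyr::select("feature_id", "sample_id", "raw_reads", "norm_reads",
                  "sites_hit", "sites_per_kb", "n_available", "length_bp",
                  "few_available_sites", "contains_ambiguous_sites")
  attr(out, "reference_total") <- attr(norm, "reference_total")
  out
}

#' Pool replicate samples at the site level
#'
#' Averages normalized reads (and sums raw reads) across the given samples,
#' returning a single pooled pseudo-sample. A site hit in any replicate counts
#' as hit in the pool.
#'
#' @param norm Normalized counts from [tn_normalize()].
#' @param sample_ids Samples to pool.
#' @param pooled_id Name for the pooled pseudo-sample.
#' @return A normalized-counts tibble with one sample.
#' @export
tn_pool_samples <- function(norm, sample_ids, pooled_id = "pooled") {
  n <- length(sample_ids)
  out <- norm |>
    dplyr::filter(.data$sample_id %in% sample_ids) |>
    dplyr::group_by(.data$replicon, .data$pos0) |>
    dplyr::summarise(
      reads_plus = sum(.data$reads_plus), reads_minus = sum(.data$reads_minus),
      reads = sum(.data$reads), norm_reads = sum(.data$norm_reads) / n,
      .groups = "drop"
    ) |>
    dplyr::mutate(sample_id = pooled_id) |>
    dplyr::relocate("sample_id")
  attr(out, "reference_total") <- attr(norm, "reference_total")
  out
}

#' Dual-criterion essentiality classification
#'
#' A feature is deemed important for growth (essential) when its read count
#' and insertion-site density fall below fixed thresholds: fewer than
#' `reads_threshold` normalized reads per feature and fewer than
#' `density_threshold` insertion sites per kb. Requiring both criteria
#' (`mode = "both"`, the default) corrects for small genes with few TA sites
#' and for large genes that tolerate insertions between domains; `"either"`
#' reads the rule as an OR and yields a superset of calls. The read threshold
#' is defined at a reference depth of 4e7 mapped reads and scales linearly
#' with the normalization reference actually used; the density threshold does
#' not scale (site density saturates with depth). Features with fewer than 3
#' available sites or containing ambiguity-affected sites are called
#' `low-confidence` instead.
#'
#' @param stats Feature stats from [tn_feature_stats()] (typically on the
#'   pooled control condition).
#' @param reads_threshold Reads-per-feature threshold (default 300 at 4e7).
#' @param density_threshold Insertion-site density threshold (default 4 / kb).
#' @param mode `"both"` or `"either"`.
#' @param reference_total Depth at which `norm_reads` are expressed; defaults
#'   to the attribute carried by `stats`, else 4e7.
#' @return `stats` with added columns `reads_criterion_met`,
#'   `density_criterion_met` and `call` (`essential`, `nonessential`,
#'   `low-confidence`).
#' @export
tn_classify_essential <- function(stats, reads_threshold = 300,
                                  density_threshold = 4,
                                  mode = c("both", "either"),
                                  reference_total = NULL) {
  mode <- match.arg(mode)
  reference_total <- reference_total %||% attr(stats, "reference_total") %||% 4e7
  thr <- reads_threshold * reference_total / 4e7
  out <- stats |>
    dplyr::mutate(
      reads_criterion_met = .data$norm_reads < thr,
      density_criterion_met = .data$sites_per_kb < density_threshold,
      essential_by_criteria = if (mode == "both") {
        .data$reads_criterion_met & .data$density_criterion_met
      } else {
        .data$reads_criterion_met | .data$density_criterion_met
      },
      call = dplyr::case_when(
        .data$few_available_sites | .data$contains_ambiguous_sites ~ "low-confidence",
        .data$essential_by_criteria ~ "essential",
        TRUE ~ "nonessential"
      )
    ) |>
    dplyr::select(-"essential_by_criteria")
  attr(out, "mode") <- mode
  attr(out, "reads_threshold") <- thr
  attr(out, "density_threshold") <- density_threshold
  out
}

#' Log2 fitness ratio
#'
#' `log2((condition + pseudocount) / (parent + pseudocount))` on normalized
#' reads. A fully growth-arrested mutant loses a factor of 2 in relative
#' abundance per generation, i.e. a ratio of -1 per generation.
#'
#' @param condition_reads,parent_reads Normalized read counts (vectors).
#' @param pseudocount Added to numerator and denominator (default 1) so that
#'   zero-read features under the test condition remain finite.
#' @return Numeric vector of log2 ratios.
#' @export
tn_log2_ratio <- function(condition_reads, parent_reads, pseudocount = 1) {
  stopifnot(all(condition_reads >= 0), all(parent_reads >= 0))
  log2((condition_reads + pseudocount) / (parent_reads + pseudocount))
}

#' Apparent doubling time from a log2 fitness ratio
#'
#' Under exponential growth, a mutant's read ratio after elapsed time `T`
#' satisfies `ratio = 2^(T/x) / 2^(T/td_p)`, so a log2 ratio `L` implies an
#' apparent doubling time `x = T / (L + T/td_p)`. With the default time base
#' `T = parent_generations * parent_doubling_h` this reduces to
#' `x = T / (G_p + L)`: a ratio of -2 after 6 generations at 10 h gives
#' 60 / 4 = 15 h. When `G_p + L <= 0` the mutant shows a net loss over the
#' experiment and no finite doubling time exists; it is flagged `declining`.
#'
#' @param L Log2 ratio(s).
#' @param parent_doubling_h Parent doubling time td_p in hours (> 0).
#' @param parent_generations Elapsed parent generations G_p (> 0).
#' @param total_time_h Optional absolute elapsed time override (hours).
#' @return Tibble: `L`, `td_h` (apparent doubling time, `NA` when declining),
#'   `declining`, `percent_td_change` (100 x (td - td_p) / td_p).
#' @export
tn_doubling_time <- function(L, parent_doubling_h = 10, parent_generations = 6,
                             total_time_h = NULL) {
  if (parent_doubling_h <= 0 || parent_generations <= 0) {
    stop_tn("`parent_doubling_h` and `parent_generations` must be positive")
  }
  T_h <- total_time_h %||% (parent_generations * parent_doubling_h)
  denom <- L + T_h / parent_doubling_h
  td <- ifelse(denom > 0, T_h / denom, NA_real_)
  tibble(
    L = L,
    td_h = td,
    declining = denom <= 0,
    percent_td_change = 100 * (td - parent_doubling_h) / parent_doubling_h
  )
}

#' Classify conditional growth phenotypes from log2 ratios
#'
#' @param L Finite log2 ratio(s).
#' @param defect_cutoff Ratios at or below this are `defective` (default -2,
#'   equivalent to a 50% longer apparent doubling time over 6 generations).
#' @param enrich_cutoff Ratios at or above this are `enriched` (default +1).
#' @return Character vector: `defective`, `below-threshold`, or `enriched`.
#' @export
tn_classify_defect <- function(L, defect_cutoff = -2, enrich_cutoff = 1) {
  stopifnot(all(is.finite(L)))
  dplyr::case_when(
    L <= defect_cutoff ~ "defective",
    L >= enrich_cutoff ~ "enriched",
    TRUE ~ "below-threshold"
  )
}

#' Conditional fitness estimation for all features
#'
#' Compares per-feature normalized read abundance between a test condition
#' and its parallel control, computing the log2 ratio, the apparent doubling
#' time under the exponential-growth model, and a growth classification.
#' When both conditions have >= 2 replicates with matching replicate numbers,
#' per-replicate ratios are also computed and a consistency filter (on by
#' default) only calls `defective` when every replicate pair is at or below
#' the cutoff.
#'
#' @param stats Feature stats from [tn_feature_stats()] covering both
#'   conditions' samples.
#' @param sample_sheet Tibble `sample_id`, `condition`, `replicate`.
#' @param condition,control Condition labels to compare.
#' @param pseudocount Pseudocount for [tn_log2_ratio()].
#' @param parent_doubling_h,parent_generations,total_time_h Passed to
#'   [tn_doubling_time()].
#' @param defect_cutoff,enrich_cutoff Passed to [tn_classify_defect()].
#' @param replicate_filter Apply the replicate-consistency filter when
#'   possible (default `TRUE`).
#' @return A `tn_fitness` object; see [tidy.tn_fitness()], [glance.tn_fitness()]
#'   and [autoplot.tn_fitness()].
#' @export
tn_fitness <- function(stats, sample_sheet,
                       condition = "electrode", control = "fumarate",
                       pseudocount = 1,
                       parent_doubling_h = 10, parent_generations = 6,
                       total_time_h = NULL,
                       defect_cutoff = -2, enrich_cutoff = 1,
                       replicate_filter = TRUE) {
  ss <- sample_sheet
  cond_samples <- ss$sample_id[ss$condition == condition]
  ctrl_samples <- ss$sample_id[ss$condition == control]
  if (length(cond_samples) == 0 || length(ctrl_samples) == 0) {
    stop_tn(sprintf("no samples for condition '%s' and/or control '%s'",
                    condition, control))
  }
  wide <- stats |>
    dplyr::filter(.data$sample_id %in% c(cond_samples, ctrl_samples)) |>
    dplyr::left_join(ss[, c("sample_id", "condition", "replicate")], by = "sample_id")

  per_feature <- wide |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      reads_condition = mean(.data$norm_reads[.data$condition == !!condition]),
      reads_control = mean(.data$norm_reads[.data$condition == !!control]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      L = tn_log2_ratio(.data$reads_condition, .data$reads_control, pseudocount)
    )

  td <- tn_doubling_time(per_feature$L, parent_doubling_h, parent_generations,
                         total_time_h)
  per_feature$td_h <- td$td_h
  per_feature$declining <- td$declining
  per_feature$percent_td_change <- td$percent_td_change

  # per-replicate ratios (paired by replicate number where possible)
  reps <- intersect(ss$replicate[ss$condition == condition],
                    ss$replicate[ss$condition == control])
  rep_L <- NULL
  if (length(reps) >= 1) {
    rep_L <- purrr::map_dfr(reps, function(r) {
      sc <- ss$sample_id[ss$condition == condition & ss$replicate == r][1]
      sk <- ss$sample_id[ss$condition == control & ss$replicate == r][1]
      x <- stats[stats$sample_id == sc, c("feature_id", "norm_reads")]
      y <- stats[stats$sample_id == sk, c("feature_id", "norm_reads")]
      dplyr::inner_join(x, y, by = "feature_id", suffix = c("_cond", "_ctrl")) |>
        dplyr::transmute(
          feature_id = .data$feature_id, replicate = r,
          L = tn_log2_ratio(.data$norm_reads_cond, .data$norm_reads_ctrl, pseudocount)
        )
    })
  }

  cls <- tn_classify_defect(per_feature$L, defect_cutoff, enrich_cutoff)
  if (replicate_filter && !is.null(rep_L) && length(reps) >= 2) {
    consistent <- rep_L |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::summarise(all_defective = all(.data$L <= defect_cutoff), .groups = "drop")
    ok <- consistent$all_defective[match(per_feature$feature_id, consistent$feature_id)]
    cls[cls == "defective" & !dplyr::coalesce(ok, FALSE)] <- "below-threshold"
  }
  no_data <- per_feature$reads_condition == 0 & per_feature$reads_control == 0
  cls[no_data] <- "no-data"
  per_feature$growth_class <- cls
  per_feature$L_display <- round(per_feature$L, 1)
  per_feature$td_display <- round(per_feature$td_h, 1)

  structure(
    list(
      features = per_feature,
      replicate_L = rep_L,
      params = list(
        condition = condition, control = control, pseudocount = pseudocount,
        parent_doubling_h = parent_doubling_h,
        parent_generations = parent_generations,
        total_time_h = total_time_h %||% parent_generations * parent_doubling_h,
        defect_cutoff = defect_cutoff, enrich_cutoff = enrich_cutoff,
        replicate_filter = replicate_filter,
        n_replicate_pairs = length(reps)
      )
    ),
    class = "tn_fitness"
  )
}

#' @export
print.tn_fitness <- function(x, ...) {
  p <- x$params
  cat(sprintf("<tn_fitness> %s vs %s: %d features\n",
              p$condition, p$control, nrow(x$features)))
  cat(sprintf("  model: td = %g h x %g generations (T = %g h), pseudocount %g\n",
              p$parent_doubling_h, p$parent_generations, p$total_time_h,
              p$pseudocount))
  print(table(x$features$growth_class))
  invisible(x)
}

#' Library summary arithmetic
#'
#' The bookkeeping behind a library's headline statistics, usable directly on
#' printed inputs: TA recovery is the fraction of viable TA sites carrying an
#' insertion after discounting the 5' windows
#' (`100 * n_unique / (viable * (1 - exclusion_fraction))`, rounded to the
#' nearest integer; also reported without the discount), and the mean reads
#' per insertion (displayed rounded to the nearest hundred).
#'
#' @param n_unique_insertions Unique insertion sites observed (>= 1 read).
#' @param viable_ta_sites TA sites able to yield viable mutants.
#' @param total_reads Total mapped reads.
#' @param exclusion_fraction 5'-window fraction (default 0.05).
#' @return One-row tibble: `ta_recovery_pct`, `ta_recovery_pct_nodiscount`,
#'   `reads_per_insertion`, `reads_per_insertion_display`.
#' @export
tn_recovery_stats <- function(n_unique_insertions, viable_ta_sites,
                              total_reads, exclusion_fraction = 0.05) {
  rpi <- if (n_unique_insertions > 0) total_reads / n_unique_insertions else 0
  tibble(
    ta_recovery_pct = if (viable_ta_sites > 0) {
      round(100 * n_unique_insertions / (viable_ta_sites * (1 - exclusion_fraction)))
    } else 0,
    ta_recovery_pct_nodiscount = if (viable_ta_sites > 0) {
      round(100 * n_unique_insertions / viable_ta_sites)
    } else 0,
    reads_per_insertion = rpi,
    reads_per_insertion_display = round(rpi / 100) * 100
  )
}

#' Summarize an insertion library
#'
#' Per-sample headline statistics: unique insertion sites with at least one
#' read, the fraction inside annotated features, insertions per kb of genome,
#' mean reads per insertion, and TA recovery under both viable-site
#' conventions (netting out lethal features' whole TA complement, or only
#' their beyond-window sites, when a lethal feature set is supplied).
#'
#' @param counts Site counts tibble (one or more samples).
#' @param ta TA-site tibble from [ta_sites()].
#' @param features Feature tibble.
#' @param genome A [tn_genome()] (for genome length).
#' @param exclusion_fraction 5'-window fraction (default 0.05).
#' @param viable_ta_sites Optional externally known viable TA-site count; by
#'   default derived from `ta` (minus lethal features' sites when given).
#' @param lethal_features Optional character vector of lethal feature ids.
#' @param avail Optional precomputed [available_sites()] table.
#' @return Tibble with one row per sample: `sample_id`, `n_unique_insertions`,
#'   `frac_in_features`, `insertions_per_kb`, `total_reads`,
#'   `reads_per_insertion`, `reads_per_insertion_display`,
#'   `viable_ta_whole_gene`, `viable_ta_beyond_window`, `ta_recovery_pct`,
#'   `ta_recovery_pct_nodiscount`.
#' @export
tn_library_summary <- function(counts, ta, features, genome,
                               exclusion_fraction = 0.05,
                               viable_ta_sites = NULL,
                               lethal_features = NULL,
                               avail = NULL) {
  genome_kb <- sum(genome$length) / 1000
  avail <- avail %||% available_sites(features, ta, exclusion_fraction)

  n_ta <- nrow(ta)
  if (!is.null(lethal_features)) {
    lethal_tab <- avail[avail$feature_id %in% lethal_features, ]
    v_whole <- n_ta - dplyr::n_distinct(lethal_tab[, c("replicon", "pos0")])
    v_beyond <- n_ta - dplyr::n_distinct(
      lethal_tab[lethal_tab$available, c("replicon", "pos0")]
    )
  } else {
    v_whole <- v_beyond <- n_ta
  }
  v_used <- viable_ta_sites %||% v_whole

  in_feature_sites <- dplyr::distinct(avail[, c("replicon", "pos0")])

  samples <- unique(counts$sample_id)
  if (length(samples) == 0) samples <- NA_character_
  purrr::map_dfr(samples, function(s) {
    cc <- counts[!is.na(s) & counts$sample_id %in% s, ]
    cc$reads <- cc$reads_plus + cc$reads_minus
    cc <- cc[cc$reads > 0, ]
    n_unique <- nrow(dplyr::distinct(cc[, c("replicon", "pos0")]))
    total_reads <- sum(cc$reads)
    in_feat <- nrow(dplyr::semi_join(cc, in_feature_sites,
                                     by = c("replicon", "pos0")))
    rec <- tn_recovery_stats(n_unique, v_used, total_reads, exclusion_fraction)
    tibble(
      sample_id = s,
      n_unique_insertions = n_unique,
      frac_in_features = if (n_unique > 0) in_feat / n_unique else 0,
      insertions_per_kb = n_unique / genome_kb,
      total_reads = total_reads,
      reads_per_insertion = rec$reads_per_insertion,
      reads_per_insertion_display = rec$reads_per_insertion_display,
      viable_ta_whole_gene = v_whole,
      viable_ta_beyond_window = v_beyond,
      ta_recovery_pct = rec$ta_recovery_pct,
      ta_recovery_pct_nodiscount = rec$ta_recovery_pct_nodiscount
    )
  })
}

#' Pearson correlation of per-feature reads between replicates
#'
#' @param stats_a,stats_b Feature stats for two replicate samples (same
#'   feature set); features with zero reads in both are included.
#' @return Pearson's r over per-feature normalized reads.
#' @export
tn_replicate_correlation <- function(stats_a, stats_b) {
  m <- dplyr::inner_join(stats_a[, c("feature_id", "norm_reads")],
                         stats_b[, c("feature_id", "norm_reads")],
                         by = "feature_id", suffix = c("_a", "_b"))
  if (nrow(m) < 3) stop_tn("need at least 3 shared features for a correlation")
  stats::cor(m$norm_reads_a, m$norm_reads_b, method = "pearson")
}
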