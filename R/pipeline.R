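# Pipeline orchestration: simulate -> process -> analyze, with run manifests.

write_manifest <- function(outdir, stage, seed, params, files, counts,
                           elapsed_s) {
  manifest <- list(
    stage = stage,
    tool = "tnseqr",
    version = as.character(utils::packageVersion("tnseqr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    record_counts = counts,
    elapsed_s = round(elapsed_s, 2)
  )
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a complete synthetic Tn-Seq dataset to disk
#'
#' Runs the full synthetic experiment ([sim_experiment()]) and writes genome
#' FASTA, feature GFF3, one barcoded junction FASTQ per sample, the per-site
#' truth count tables, the per-feature fitness truth, the TA-site index, the
#' sample sheet, and a JSON run manifest (tool version, seed, parameters, file
#' checksums, record counts) sufficient to reproduce the run bit-identically.
#'
#' @param config A [tn_sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list: `config`, `outdir`, `genome`, `features`,
#'   `truth`, `truth_counts` (all samples), `paths`.
#' @export
tn_simulate <- function(config, outdir) {
  t0 <- Sys.time()
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  exp <- sim_experiment(config)

  paths <- list(
    genome = file.path(outdir, "genome.fasta"),
    features = file.path(outdir, "features.gff3"),
    ta = file.path(outdir, "ta_sites.tsv"),
    truth_counts = file.path(outdir, "truth_counts.tsv"),
    truth_fitness = file.path(outdir, "truth_fitness.tsv"),
    sample_sheet = file.path(outdir, "samples.tsv")
  )
  tn_write_genome(exp$genome, paths$genome)
  tn_write_features(exp$features, paths$features)
  tn_write_ta_tsv(ta_sites(exp$genome), paths$ta)
  tn_write_tsv(exp$truth, paths$truth_fitness)

  truth_counts <- vector("list", nrow(config$samples))
  fastqs <- character(nrow(config$samples))
  for (i in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[i]
    fq <- file.path(outdir, paste0(sid, ".fastq"))
    res <- sim_sequence_reads(exp$populations[[sid]], exp$genome, config,
                              sid, fq)
    truth_counts[[i]] <- res$truth
    fastqs[i] <- fq
  }
  truth_counts <- dplyr::bind_rows(truth_counts)
  tn_write_tsv(truth_counts, paths$truth_counts)
  sheet <- dplyr::mutate(config$samples,
                         fastq = fastqs,
                         transposon_tag = config$transposon_tag)
  tn_write_tsv(sheet, paths$sample_sheet)
  paths$fastqs <- fastqs

  write_manifest(
    outdir, "simulate", config$seed,
    params = unclass(config)[setdiff(names(config), "samples")],
    files = c(paths[c("genome", "features", "truth_counts", "truth_fitness")],
              as.list(fastqs)),
    counts = list(n_features = nrow(exp$features),
                  n_clones = nrow(exp$parent$clones),
                  reads_per_sample = config$depth),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  invisible(list(config = config, outdir = outdir, genome = exp$genome,
                 features = exp$features, truth = exp$truth,
                 parent = exp$parent, truth_counts = truth_counts,
                 sample_sheet = sheet, paths = paths))
}

#' Process junction FASTQ files into site-count tables on disk
#'
#' Demultiplexes, trims, maps with zero mismatches, and tabulates per-TA-site
#' counts; writes the combined counts TSV, per-sample BED and wiggle tracks,
#' mapping statistics, and a run manifest. Real data enters the pipeline here.
#'
#' @param genome_path Genome FASTA path.
#' @param sample_sheet Tibble with `sample_id`, `barcode`, `fastq` (and
#'   optionally `condition`, `replicate`); or the path of a TSV with those
#'   columns (as written by [tn_simulate()]).
#' @param transposon_tag Transposon-end sequence to trim (defaults to a
#'   `transposon_tag` column in the sheet, if present).
#' @param outdir Output directory (created if missing).
#' @param min_len,max_len,layout Passed to [tn_demultiplex()].
#' @return Invisibly, a list: `counts`, `totals`, `ambiguous_sites`, `genome`,
#'   `paths`.
#' @export
tn_process <- function(genome_path, sample_sheet, transposon_tag = NULL,
                       outdir, min_len = 16L, max_len = 21L,
                       layout = c("header", "inline")) {
  t0 <- Sys.time()
  layout <- match.arg(layout)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.character(sample_sheet) && length(sample_sheet) == 1) {
    sample_sheet <- as_tibble(utils::read.delim(sample_sheet,
                                                stringsAsFactors = FALSE))
  }
  transposon_tag <- transposon_tag %||% sample_sheet$transposon_tag[1]
  if (is.null(transposon_tag)) stop_tn("`transposon_tag` is required")
  genome <- tn_read_genome(genome_path)
  missing_fq <- !file.exists(sample_sheet$fastq)
  if (any(missing_fq)) stop_tn("FASTQ not found: ", sample_sheet$fastq[missing_fq][1])

  res <- tn_count_reads(unique(sample_sheet$fastq), genome,
                        sample_sheet[, c("sample_id", "barcode")],
                        transposon_tag, min_len = min_len, max_len = max_len,
                        layout = layout)

  paths <- list(counts = file.path(outdir, "site_counts.tsv"),
                stats = file.path(outdir, "mapping_stats.tsv"))
  tn_write_counts_tsv(res$counts, paths$counts)
  tn_write_tsv(res$totals, paths$stats)
  for (sid in unique(res$counts$sample_id)) {
    cc <- res$counts[res$counts$sample_id == sid, ]
    tn_write_counts_bed(cc, genome, file.path(outdir, paste0(sid, ".bed")))
    tn_write_counts_wig(cc, genome, file.path(outdir, paste0(sid, ".wig")))
  }

  write_manifest(
    outdir, "process", NA,
    params = list(transposon_tag = transposon_tag, min_len = min_len,
                  max_len = max_len, layout = layout, genome = genome_path),
    files = paths,
    counts = as.list(stats::setNames(res$totals$n_input, res$totals$sample_id)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  invisible(list(counts = res$counts, totals = res$totals,
                 ambiguous_sites = res$ambiguous_sites, genome = genome,
                 paths = paths))
}

#' Analyze site-count tables into essentiality and fitness results
#'
#' Normalizes counts, aggregates per feature under the 5' rule, classifies
#' essentiality on the pooled control condition, estimates conditional fitness
#' (log2 ratios, apparent doubling times, growth classes) for every non-control
#' condition, and writes per-feature and summary TSVs plus a run manifest.
#'
#' @param counts,totals,ambiguous_sites Output of [tn_process()] /
#'   [tn_count_reads()].
#' @param genome A [tn_genome()].
#' @param features Feature tibble.
#' @param sample_sheet Tibble `sample_id`, `condition`, `replicate`.
#' @param control Condition label of the parent/control arm.
#' @param outdir Output directory (created if missing).
#' @param reference_total,exclusion_fraction Passed to [tn_normalize()] and
#'   [available_sites()].
#' @param reads_threshold,density_threshold,mode Passed to
#'   [tn_classify_essential()].
#' @param pseudocount,parent_doubling_h,parent_generations,total_time_h Passed
#'   to [tn_fitness()] / [tn_doubling_time()].
#' @param defect_cutoff,enrich_cutoff,replicate_filter Passed to
#'   [tn_fitness()].
#' @return Invisibly, a list: `stats` (per sample), `essentiality` (pooled
#'   control), `fitness` (named list of [tn_fitness()] objects, one per
#'   non-control condition; empty when only the control is present),
#'   `summary` (per-sample library summary), `feature_table` (the combined
#'   per-feature TSV), `paths`.
#' @export
tn_analyze <- function(counts, totals, genome, features, sample_sheet,
                       ambiguous_sites = NULL, control = "fumarate",
                       outdir, reference_total = 4e7,
                       exclusion_fraction = 0.05,
                       reads_threshold = 300, density_threshold = 4,
                       mode = c("both", "either"), pseudocount = 1,
                       parent_doubling_h = 10, parent_generations = 6,
                       total_time_h = NULL, defect_cutoff = -2,
                       enrich_cutoff = 1, replicate_filter = TRUE) {
  t0 <- Sys.time()
  mode <- match.arg(mode)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (!control %in% sample_sheet$condition) {
    stop_tn(sprintf("control condition '%s' not present in the sample sheet",
                    control))
  }
  ta <- ta_sites(genome)
  avail <- available_sites(features, ta, exclusion_fraction)
  norm <- tn_normalize(counts, totals, reference_total)
  stats <- tn_feature_stats(norm, features, avail, ambiguous_sites)

  # essentiality on the pooled control condition
  ctrl_samples <- sample_sheet$sample_id[sample_sheet$condition == control]
  pooled <- tn_pool_samples(norm, ctrl_samples, pooled_id = control)
  pooled_stats <- tn_feature_stats(pooled, features, avail, ambiguous_sites)
  essentiality <- tn_classify_essential(pooled_stats, reads_threshold,
                                        density_threshold, mode,
                                        reference_total)

  conditions <- setdiff(unique(sample_sheet$condition), control)
  fits <- lapply(conditions, function(cond) {
    tn_fitness(stats, sample_sheet, condition = cond, control = control,
               pseudocount = pseudocount,
               parent_doubling_h = parent_doubling_h,
               parent_generations = parent_generations,
               total_time_h = total_time_h, defect_cutoff = defect_cutoff,
               enrich_cutoff = enrich_cutoff,
               replicate_filter = replicate_filter)
  })
  names(fits) <- conditions

  summary_tbl <- tn_library_summary(counts, ta, features, genome,
                                    exclusion_fraction, avail = avail)

  feature_table <- essentiality |>
    dplyr::select("feature_id", "norm_reads", "raw_reads", "sites_hit",
                  "sites_per_kb", "n_available",
                  "reads_criterion_met", "density_criterion_met", "call",
                  "few_available_sites", "contains_ambiguous_sites")
  for (cond in conditions) {
    f <- fits[[cond]]$features |>
      dplyr::select("feature_id", "L", "td_h", "declining",
                    "percent_td_change", "growth_class")
    names(f)[-1] <- paste0(names(f)[-1], "_", cond)
    feature_table <- dplyr::left_join(feature_table, f, by = "feature_id")
  }

  paths <- list(features = file.path(outdir, "feature_table.tsv"),
                summary = file.path(outdir, "library_summary.tsv"))
  tn_write_tsv(feature_table, paths$features)
  tn_write_tsv(summary_tbl, paths$summary)

  write_manifest(
    outdir, "analyze", NA,
    params = list(control = control, reference_total = reference_total,
                  exclusion_fraction = exclusion_fraction,
                  reads_threshold = reads_threshold,
                  density_threshold = density_threshold, mode = mode,
                  pseudocount = pseudocount,
                  parent_doubling_h = parent_doubling_h,
                  parent_generations = parent_generations,
                  total_time_h = total_time_h,
                  defect_cutoff = defect_cutoff,
                  enrich_cutoff = enrich_cutoff,
                  replicate_filter = replicate_filter),
    files = paths,
    counts = list(n_features = nrow(features),
                  n_samples = nrow(sample_sheet)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  invisible(list(stats = stats, essentiality = essentiality, fitness = fits,
                 summary = summary_tbl, feature_table = feature_table,
                 paths = paths))
}
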