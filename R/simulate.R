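#' Simulation configuration for a synthetic mariner Tn-Seq experiment
#'
#' Bundles every parameter of the synthetic study: a random genome with tiled
#' features, a pooled insertion library subjected to a colony-selection
#' bottleneck, two-arm propagation (test condition for the stated number of
#' parent generations, then a shared fumarate outgrowth in both arms so it
#' cancels in read ratios), and multinomial sequencing of 20-bp MmeI junction
#' fragments with per-sample barcodes.
#'
#' Defaults emulate the study conditions: a parent doubling time of 10 h, 6
#' generations of selective growth plus 6 of outgrowth, 20-bp junction reads,
#' two fumarate-control and two electrode samples.
#'
#' @param seed Integer seed; every random stage derives its stream from it.
#' @param genome_length Replicon length in bp (>= 10 kb).
#' @param gc_content Proportion G+C of the random genome.
#' @param n_features Number of non-overlapping features to tile (~85% genome
#'   coverage with the default length range).
#' @param feature_length_range Integer range feature lengths are drawn from.
#' @param n_insertions Target number of unique insertion clones K sampled
#'   without replacement from the TA sites (before the selection bottleneck).
#' @param depth Sequencing depth D: reads emitted per sample.
#' @param read_length Genomic junction length in nt (MmeI releases 20 bp).
#' @param read_length_jitter If `TRUE`, junction lengths are drawn uniformly
#'   from 19-21 nt (MmeI cuts 20 +/- 1 in practice); default off.
#' @param transposon Only `"mariner"` (TA-specific) is supported; anything
#'   else (e.g. Tn5) is rejected.
#' @param parent_doubling_h Parent-library doubling time td_p in hours.
#' @param parent_generations Generations of selective growth G_p.
#' @param outgrowth_generations Fumarate outgrowth generations applied to both
#'   arms after selection.
#' @param fraction_lethal_fumarate Fraction of features lethal on fumarate;
#'   clones disrupting them never form colonies and are removed at pooling.
#' @param fraction_electrode_defective Fraction of (non-lethal) features whose
#'   disruption slows electrode growth.
#' @param electrode_defective_doubling_h Doubling time (h) of
#'   electrode-defective mutants under electrode conditions; `Inf` allowed.
#' @param samples Sample sheet tibble: `sample_id`, `barcode` (distinct, equal
#'   length), `condition` (`"fumarate"` or `"electrode"`), `replicate`.
#' @param transposon_tag Fixed transposon-end sequence prefixed to every read.
#' @param read_layout `"header"` (barcode carried in the FASTQ header, read =
#'   tag + junction) or `"inline"` (read = barcode + tag + junction).
#' @param substitution_error_rate Per-base substitution probability (default
#'   0; any substitution makes a read unmappable under zero-mismatch mapping).
#' @param exclusion_fraction 5'-window fraction used both for the selection
#'   bottleneck and downstream statistics.
#' @param total_time_h Optional absolute elapsed time override; by default the
#'   exponential-growth model uses `parent_generations * parent_doubling_h`.
#' @return A `tn_sim_config` list.
#' @export
tn_sim_config <- function(seed = 1L,
                          genome_length = 5e5,
                          gc_content = 0.60,
                          n_features = 400L,
                          feature_length_range = c(500L, 1600L),
                          n_insertions = 5000L,
                          depth = 2e6,
                          read_length = 20L,
                          read_length_jitter = FALSE,
                          transposon = "mariner",
                          parent_doubling_h = 10,
                          parent_generations = 6,
                          outgrowth_generations = 6,
                          fraction_lethal_fumarate = 0.10,
                          fraction_electrode_defective = 0.05,
                          electrode_defective_doubling_h = 15,
                          samples = NULL,
                          transposon_tag = "ACAGGTTGGATG",
                          read_layout = c("header", "inline"),
                          substitution_error_rate = 0,
                          exclusion_fraction = 0.05,
                          total_time_h = NULL) {
  if (!identical(transposon, "mariner")) {
    stop_tn("only the TA-specific mariner transposon is supported (got ", transposon, ")")
  }
  read_layout <- match.arg(read_layout)
  assert_proportion(gc_content, "gc_content")
  assert_proportion(fraction_lethal_fumarate, "fraction_lethal_fumarate")
  assert_proportion(fraction_electrode_defective, "fraction_electrode_defective")
  assert_proportion(substitution_error_rate, "substitution_error_rate")
  if (genome_length < 1e4) stop_tn("`genome_length` must be >= 10 kb for meaningful simulations")
  if (depth <= 0) stop_tn("`depth` must be positive")
  if (parent_doubling_h <= 0) stop_tn("`parent_doubling_h` must be positive")
  if (is.null(samples)) {
    samples <- tibble(
      sample_id = c("fumarate_1", "fumarate_2", "electrode_1", "electrode_2"),
      barcode = c("ACGTAC", "CAGTCA", "GTCAGT", "TGACTG"),
      condition = c("fumarate", "fumarate", "electrode", "electrode"),
      replicate = c(1L, 2L, 1L, 2L)
    )
  }
  check_barcode_table(samples)
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    gc_content = gc_content, n_features = as.integer(n_features),
    feature_length_range = as.integer(feature_length_range),
    n_insertions = as.integer(n_insertions), depth = as.integer(depth),
    read_length = as.integer(read_length), read_length_jitter = read_length_jitter,
    parent_doubling_h = parent_doubling_h,
    parent_generations = parent_generations,
    outgrowth_generations = outgrowth_generations,
    fraction_lethal_fumarate = fraction_lethal_fumarate,
    fraction_electrode_defective = fraction_electrode_defective,
    electrode_defective_doubling_h = electrode_defective_doubling_h,
    samples = samples, transposon_tag = toupper(transposon_tag),
    read_layout = read_layout,
    substitution_error_rate = substitution_error_rate,
    exclusion_fraction = exclusion_fraction,
    total_time_h = total_time_h
  )
  structure(cfg, class = "tn_sim_config")
}

check_barcode_table <- function(samples) {
  stopifnot(all(c("sample_id", "barcode", "condition", "replicate") %in% names(samples)))
  bc <- samples$barcode
  if (anyDuplicated(bc)) stop_tn("barcode collision in sample sheet: ", bc[duplicated(bc)][1])
  if (length(unique(nchar(bc))) != 1) stop_tn("barcodes must all have the same length")
  if (anyDuplicated(samples$sample_id)) stop_tn("duplicate sample_id in sample sheet")
  invisible(samples)
}

#' Simulate a random genome with tiled features
#'
#' Generates a seeded random replicon at the configured GC content and tiles
#' `n_features` non-overlapping features (random strand, random intergenic
#' gaps). Every feature is guaranteed at least two TA sites beyond its
#' 5'-exclusion window: violating features have two TA dinucleotides planted
#' locally inside their available region.
#'
#' @param config A [tn_sim_config()].
#' @return List with `genome` (a [tn_genome()]) and `features` (tibble).
#' @export
sim_genome <- function(config) {
  L <- config$genome_length
  rng <- config$feature_length_range
  mean_len <- mean(rng)
  if (config$n_features * mean_len > 0.9 * L) {
    stop_tn(sprintf("infeasible layout: %d features of ~%d bp do not fit in %d bp",
                    config$n_features, round(mean_len), L))
  }
  set.seed(sub_seed(config$seed, 0L))
  at <- (1 - config$gc_content) / 2
  gc <- config$gc_content / 2
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(at, gc, gc, at)), collapse = "")

  lens <- sample(rng[1]:rng[2], config$n_features, replace = TRUE)
  slack <- L - sum(lens)
  # distribute slack over n_features + 1 intergenic gaps
  cuts <- sort(sample.int(slack + 1L, config$n_features, replace = TRUE) - 1L)
  gaps <- diff(c(0L, cuts, slack))
  starts <- cumsum(gaps[-length(gaps)] + c(0L, lens[-length(lens)])) + 1L
  feats <- tibble(
    feature_id = sprintf("feat_%04d", seq_len(config$n_features)),
    replicon = "chr",
    start = starts,
    end = starts + lens - 1L,
    strand = sample(c("+", "-"), config$n_features, replace = TRUE),
    length_bp = lens,
    product = "hypothetical protein"
  )

  # guarantee >= 2 available TA sites per feature by local planting
  genome <- tn_genome(c(chr = seq))
  avail <- available_sites(feats, ta_sites(genome), config$exclusion_fraction)
  n_av <- n_available_sites(feats, avail)
  short <- n_av$feature_id[n_av$n_available < 2]
  if (length(short) > 0) {
    for (fid in short) {
      f <- feats[feats$feature_id == fid, ]
      win <- floor(config$exclusion_fraction * f$length_bp)
      # plant two TA sites well inside the available region (either strand's
      # window leaves the central half of the feature available)
      mid <- f$start + max(win, 2L)
      for (q in c(mid, mid + 4L)) {
        substr(seq, q, q + 1L) <- "TA"
      }
    }
    genome <- tn_genome(c(chr = seq))
  }
  list(genome = genome, features = feats)
}

#' Draw per-feature fitness ground truth
#'
#' Samples which features are fumarate-lethal (no colonies after pooling) and
#' which are electrode-defective (slowed doubling under electrode conditions);
#' the two sets are disjoint. All other features grow at the parent doubling
#' time in both conditions, as do intergenic insertions.
#'
#' @param features Feature tibble from [sim_genome()].
#' @param config A [tn_sim_config()].
#' @return Tibble `feature_id`, `lethal_fumarate`, `td_fumarate_h`,
#'   `td_electrode_h`.
#' @export
sim_fitness_truth <- function(features, config) {
  set.seed(sub_seed(config$seed, 1L))
  n <- nrow(features)
  n_lethal <- round(config$fraction_lethal_fumarate * n)
  n_def <- round(config$fraction_electrode_defective * n)
  lethal <- sample(features$feature_id, n_lethal)
  defective <- sample(setdiff(features$feature_id, lethal), n_def)
  td_p <- config$parent_doubling_h
  tibble(
    feature_id = features$feature_id,
    lethal_fumarate = features$feature_id %in% lethal,
    td_fumarate_h = ifelse(features$feature_id %in% lethal, Inf, td_p),
    td_electrode_h = dplyr::case_when(
      features$feature_id %in% lethal ~ Inf,
      features$feature_id %in% defective ~ config$electrode_defective_doubling_h,
      TRUE ~ td_p
    )
  )
}

#' Construct the pooled insertion library
#'
#' Samples K distinct TA sites uniformly without replacement, then applies the
#' colony-selection bottleneck: clones whose insertion lies beyond the
#' 5'-window of a fumarate-lethal feature never form colonies and are removed.
#' Survivors are pooled at equal abundance. Only sites far enough from the
#' replicon ends for both junction orientations to yield full-length reads are
#' eligible (the replicon is treated as linear).
#'
#' @param genome,features Output of [sim_genome()].
#' @param truth Fitness truth from [sim_fitness_truth()].
#' @param config A [tn_sim_config()].
#' @return A `tn_population`: list with `clones` tibble (`replicon`, `pos0`,
#'   `host_feature`, `region` in available/window/intergenic, `abundance`),
#'   `condition = "parent"` and `generations = 0`.
#' @export
sim_library <- function(genome, features, truth, config) {
  ta <- ta_sites(genome)
  rl <- config$read_length + as.integer(config$read_length_jitter)
  glen <- genome$length[ta$replicon]
  eligible <- ta[ta$pos0 >= (rl - 2L) & ta$pos0 <= (glen - rl), ]
  if (config$n_insertions > nrow(eligible)) {
    stop_tn(sprintf("requested %d insertions but only %d eligible TA sites",
                    config$n_insertions, nrow(eligible)))
  }
  set.seed(sub_seed(config$seed, 2L))
  picked <- eligible[sample.int(nrow(eligible), config$n_insertions), c("replicon", "pos0")]

  avail <- available_sites(features, ta, config$exclusion_fraction)
  clones <- picked |>
    dplyr::left_join(avail, by = c("replicon", "pos0")) |>
    dplyr::mutate(
      region = dplyr::case_when(
        is.na(.data$feature_id) ~ "intergenic",
        .data$available ~ "available",
        TRUE ~ "window"
      ),
      host_feature = .data$feature_id,
      abundance = 1
    ) |>
    dplyr::select("replicon", "pos0", "host_feature", "region", "abundance") |>
    dplyr::arrange(.data$replicon, .data$pos0)

  lethal <- truth$feature_id[truth$lethal_fumarate]
  clones <- clones[!(clones$region == "available" & clones$host_feature %in% lethal), ]
  structure(list(clones = clones, condition = "parent", generations = 0),
            class = "tn_population")
}

#' @export
print.tn_population <- function(x, ...) {
  cat(sprintf("<tn_population> %d clones, condition '%s', %g generations elapsed\n",
              nrow(x$clones), x$condition, x$generations))
  invisible(x)
}

#' Propagate a clone population under exponential growth
#'
#' Each clone's abundance is multiplied by `2^(T / td_i)` where
#' `T = generations * parent_doubling_h` is the elapsed time and `td_i` is the
#' clone's host-feature doubling time under `condition` (the parent doubling
#' time for intergenic clones, clones inside the 5' window, and unaffected
#' features). An infinite `td_i` yields a factor of 1 (static, no growth).
#' Propagation is deterministic; the only stochastic stage is sequencing.
#'
#' @param pop A `tn_population`.
#' @param condition `"fumarate"` or `"electrode"`.
#' @param generations Parent-equivalent generations (>= 0).
#' @param truth Fitness truth tibble.
#' @param config A [tn_sim_config()].
#' @return The propagated `tn_population`.
#' @export
sim_propagate <- function(pop, condition = c("fumarate", "electrode"),
                          generations, truth, config) {
  condition <- match.arg(condition)
  if (generations < 0) stop_tn("`generations` must be >= 0")
  td_p <- config$parent_doubling_h
  T_h <- generations * td_p
  td_col <- paste0("td_", condition, "_h")
  td <- truth[[td_col]][match(pop$clones$host_feature, truth$feature_id)]
  td[is.na(td) | pop$clones$region != "available"] <- td_p
  pop$clones$abundance <- pop$clones$abundance * 2^(T_h / td)
  pop$condition <- condition
  pop$generations <- pop$generations + generations
  pop
}

#' Run the two-arm selection experiment
#'
#' Reproduces the study design: a pooled parent library is split into an
#' electrode arm (selective growth for `parent_generations`) and a parallel
#' fumarate-control arm grown for the same number of generations; both arms
#' then receive the same fumarate outgrowth (needed in the original protocol
#' to recover biomass from biofilms), which therefore cancels in read ratios.
#'
#' @param config A [tn_sim_config()].
#' @return List with `genome`, `features`, `truth`, `parent` (post-selection
#'   library), and `populations`: a named list with one propagated population
#'   per sample in `config$samples`.
#' @export
sim_experiment <- function(config) {
  gen <- sim_genome(config)
  truth <- sim_fitness_truth(gen$features, config)
  parent <- sim_library(gen$genome, gen$features, truth, config)
  arm <- function(condition) {
    sim_propagate(parent, condition, config$parent_generations, truth, config) |>
      sim_propagate("fumarate", config$outgrowth_generations, truth, config)
  }
  arms <- list(fumarate = arm("fumarate"), electrode = arm("electrode"))
  pops <- lapply(config$samples$condition, function(cond) arms[[cond]])
  names(pops) <- config$samples$sample_id
  list(genome = gen$genome, features = gen$features, truth = truth,
       parent = parent, populations = pops)
}

#' Sequence a clone population into barcoded junction reads
#'
#' Draws `depth` reads multinomially with probability proportional to clone
#' abundance. Each read picks one of the two junction orientations with equal
#' probability. For orientation `+` the junction is the `read_length` bases
#' starting at the TA site's T going rightward on the forward strand; for
#' orientation `-`, the `read_length` bases ending at the A going leftward,
#' reverse-complemented. The transposon tag is prepended and the sample
#' barcode carried per the configured layout. Substitution errors (if any) are
#' applied to the full emitted sequence; under zero-mismatch mapping every
#' substituted read becomes unmappable, so the expected mappable fraction
#' `(1 - rate)^nchar(read)` is attached as an attribute.
#'
#' @param pop A `tn_population`.
#' @param genome A [tn_genome()].
#' @param config A [tn_sim_config()].
#' @param sample_id Sample to emit; must appear in `config$samples`.
#' @param path Output FASTQ path.
#' @param seed Seed for this sample's sequencing draw (defaults to a stream
#'   derived from `config$seed` and the sample's position in the sheet).
#' @return List with `path`, `truth` (tibble `sample_id`, `replicon`, `pos0`,
#'   `reads_plus`, `reads_minus` of the exact counts emitted) and `n_reads`.
#' @export
sim_sequence_reads <- function(pop, genome, config, sample_id, path, seed = NULL) {
  if (nrow(pop$clones) == 0) stop_tn("cannot sequence an empty population")
  srow <- match(sample_id, config$samples$sample_id)
  if (is.na(srow)) stop_tn("unknown sample_id: ", sample_id)
  barcode <- config$samples$barcode[srow]
  seed <- seed %||% sub_seed(config$seed, 100L + srow)
  set.seed(seed)

  D <- config$depth
  cl <- pop$clones
  n_per_clone <- as.vector(stats::rmultinom(1, D, prob = cl$abundance))
  n_plus <- stats::rbinom(nrow(cl), n_per_clone, 0.5)
  n_minus <- n_per_clone - n_plus

  rl <- config$read_length
  seqs <- genome$seq[cl$replicon]
  t1 <- cl$pos0 + 1L
  junct_plus <- substring(seqs, t1, t1 + rl - 1L)
  junct_minus <- revcomp(substring(seqs, t1 + 2L - rl, t1 + 1L))

  prefix <- if (config$read_layout == "inline") paste0(barcode, config$transposon_tag) else config$transposon_tag
  if (config$read_length_jitter) {
    # per-read jittered lengths 19-21; built per read (small runs only)
    idx <- c(rep(seq_len(nrow(cl)), n_plus), rep(seq_len(nrow(cl)), n_minus))
    ori <- rep(c("+", "-"), c(sum(n_plus), sum(n_minus)))
    jlen <- sample(19:21, length(idx), replace = TRUE)
    reads <- ifelse(
      ori == "+",
      substring(seqs[idx], t1[idx], t1[idx] + jlen - 1L),
      revcomp(substring(seqs[idx], t1[idx] + 2L - jlen, t1[idx] + 1L))
    )
    reads <- paste0(prefix, reads)
  } else {
    reads <- c(rep(paste0(prefix, junct_plus), n_plus),
               rep(paste0(prefix, junct_minus), n_minus))
  }

  ord <- sample.int(length(reads))
  reads <- reads[ord]

  if (config$substitution_error_rate > 0) {
    nerr <- stats::rbinom(length(reads), nchar(reads), config$substitution_error_rate)
    hit <- which(nerr > 0)
    for (i in hit) {
      pos <- sample.int(nchar(reads[i]), nerr[i])
      for (p in pos) {
        orig <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
      }
    }
  }

  ids <- sprintf("@%s_%07d BC:Z:%s", sample_id, seq_along(reads), barcode)
  quals <- strrep("I", nchar(reads))
  writeLines(as.vector(rbind(ids, reads, "+", quals)), path)

  truth <- tibble(
    sample_id = sample_id, replicon = cl$replicon, pos0 = cl$pos0,
    reads_plus = n_plus, reads_minus = n_minus
  ) |>
    dplyr::filter(.data$reads_plus + .data$reads_minus > 0) |>
    dplyr::arrange(.data$replicon, .data$pos0)

  structure(list(path = path, truth = truth, n_reads = length(reads)),
            mappable_fraction = (1 - config$substitution_error_rate)^
              (nchar(prefix) + rl))
}
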