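#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a conditional-fitness fit
#'
#' @param x A [tn_fitness()] object.
#' @param ... Unused.
#' @return Tibble with one row per feature: normalized reads in each
#'   condition, `L` (log2 ratio), `td_h` (apparent doubling time),
#'   `declining`, `percent_td_change`, `growth_class`, and display-rounded
#'   `L_display` / `td_display` (1 decimal, as conventionally reported;
#'   classification always uses unrounded values).
#' @method tidy tn_fitness
#' @export
tidy.tn_fitness <- function(x, ...) {
  as_tibble(x$features)
}

#' One-row summary of a conditional-fitness fit
#'
#' @param x A [tn_fitness()] object.
#' @param ... Unused.
#' @return One-row tibble: feature and class counts plus model parameters.
#' @method glance tn_fitness
#' @export
glance.tn_fitness <- function(x, ...) {
  f <- x$features
  p <- x$params
  tibble(
    n_features = nrow(f),
    n_defective = sum(f$growth_class == "defective"),
    n_enriched = sum(f$growth_class == "enriched"),
    n_declining = sum(f$declining, na.rm = TRUE),
    n_no_data = sum(f$growth_class == "no-data"),
    condition = p$condition, control = p$control,
    parent_doubling_h = p$parent_doubling_h,
    parent_generations = p$parent_generations,
    total_time_h = p$total_time_h,
    pseudocount = p$pseudocount,
    defect_cutoff = p$defect_cutoff, enrich_cutoff = p$enrich_cutoff
  )
}

#' Fitness-ratio overview plot
#'
#' Log2 condition/control ratio against control abundance (an MA-style view),
#' colored by growth class, with dashed lines at the defect and enrichment
#' cutoffs.
#'
#' @param object A [tn_fitness()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tn_fitness
#' @export
autoplot.tn_fitness <- function(object, ...) {
  f <- object$features
  p <- object$params
  ggplot2::ggplot(f, ggplot2::aes(
    x = log10(.data$reads_control + 1),
    y = .data$L, colour = .data$growth_class
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(p$defect_cutoff, p$enrich_cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = sprintf("log10 normalized reads (%s) + 1", p$control),
      y = sprintf("log2 %s / %s", p$condition, p$control),
      colour = "growth class",
      title = "Conditional fitness of insertion mutants"
    ) +
    ggplot2::theme_minimal()
}

#' Insertion-density histogram
#'
#' Distribution of per-feature insertion-site densities with the essentiality
#' density threshold marked; features left of the line are candidates for
#' being required under the growth condition.
#'
#' @param stats Feature stats from [tn_feature_stats()] (one sample).
#' @param density_threshold Threshold to mark (default 4 sites/kb).
#' @param binwidth Histogram bin width (default 1).
#' @return A ggplot object.
#' @export
plot_insertion_density <- function(stats, density_threshold = 4, binwidth = 1) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$sites_per_kb)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = density_threshold, linetype = "dashed") +
    ggplot2::labs(x = "insertion sites per kb", y = "features",
                  title = "Per-feature insertion density") +
    ggplot2::theme_minimal()
}
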