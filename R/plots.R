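#' @importFrom ggplot2 ggplot aes geom_col geom_boxplot geom_line geom_point
#'   geom_segment labs scale_fill_brewer theme_minimal autoplot
#' @export
ggplot2::autoplot

#' Stacked topology-frequency barplot per panel size
#'
#' The share of iterations supporting each topology label (`#1` matching
#' the population tree, `#2`/`#3` alternative arrangements, `#4` polytomy)
#' as the number of concatenated proteins grows.
#'
#' @param x An `iterative_analysis` or its `$topology` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_topology_frequencies <- function(x, ...) {
  tab <- if (inherits(x, "iterative_analysis")) x$topology else as_tibble(x)
  ggplot(tab, aes(x = factor(.data$N), y = .data$frequency,
                  fill = .data$label)) +
    geom_col() +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "proteins in concatenation (N)", y = "fraction of iterations",
         fill = "topology") +
    theme_minimal()
}

#' @rdname plot_topology_frequencies
#' @param object An `iterative_analysis`.
#' @export
autoplot.iterative_analysis <- function(object, ...) {
  plot_topology_frequencies(object, ...)
}

#' Ingroup-variant distributions per panel size
#'
#' Box-and-whisker display of the informative-site counts behind each
#' concatenation size, using the precomputed type-7 quartiles and
#' 1.5-IQR whiskers.
#'
#' @param x An `iterative_analysis` or its `$variants` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_variant_counts <- function(x, ...) {
  tab <- if (inherits(x, "iterative_analysis")) x$variants else as_tibble(x)
  ggplot(tab, aes(x = factor(.data$N))) +
    geom_boxplot(aes(ymin = pmax(.data$whisker_lo, .data$min),
                     lower = .data$q25, middle = .data$median,
                     upper = .data$q75,
                     ymax = pmin(.data$whisker_hi, .data$max)),
                 stat = "identity") +
    labs(x = "proteins in concatenation (N)", y = "ingroup variants") +
    theme_minimal()
}

#' Conservation ranking barplot
#'
#' @param ranking Output of [rank_loci()].
#' @param ... Unused.
#' @return A ggplot with loci ordered by decreasing score.
#' @export
plot_conservation_ranking <- function(ranking, ...) {
  tab <- mutate(as_tibble(ranking),
                locus = factor(.data$locus, levels = .data$locus))
  ggplot(tab, aes(x = .data$locus, y = .data$score)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "conservation score") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Per-site profile of a conservation profile
#'
#' @param object A `conservation_profile`.
#' @param ... Unused.
#' @return A ggplot of score against site.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$site, y = .data$score)) +
    geom_line(colour = "grey40") +
    labs(x = "alignment position",
         y = paste0(object$metric,
                    if (object$metric == "entropy") " (bits)" else ""),
         title = paste0(object$locus, " [", object$data_type, "]")) +
    theme_minimal()
}

#' Track-style plot of introgressed segments over a gene
#'
#' One horizontal segment per introgressed haplotype, grouped by
#' continental region and sorted by length, with the gene interval
#' underneath.
#'
#' @param report Output of [segment_report()].
#' @param gene Gene interval (list with `chromosome`, `start`, `end` and
#'   optionally `gene`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_segment_report <- function(report, gene, ...) {
  tab <- mutate(as_tibble(report), row = dplyr::row_number())
  g <- as_gene_interval(gene)
  ggplot(tab) +
    geom_segment(aes(x = .data$start, xend = .data$end, y = .data$row,
                     yend = .data$row, colour = .data$region)) +
    ggplot2::annotate("segment", x = g$start, xend = g$end,
                      y = -1, yend = -1, linewidth = 2) +
    labs(x = paste0("position on ", g$chromosome), y = "haplotype",
         colour = "region") +
    theme_minimal()
}
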