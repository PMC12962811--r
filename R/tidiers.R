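#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted quartet into one row per branch
#'
#' @param x A `quartet_fit`.
#' @param ... Unused.
#' @return A tibble with `term` (four pendant branches plus `internal`)
#'   and `estimate` (substitutions/site).
#' @export
tidy.quartet_fit <- function(x, ...) {
  tibble(term = names(x$branch_lengths),
         estimate = unname(x$branch_lengths))
}

#' One-row summary of a fitted quartet
#'
#' @param x A `quartet_fit`.
#' @param ... Unused.
#' @export
glance.quartet_fit <- function(x, ...) {
  tibble(topology = x$topology, is_polytomy = x$is_polytomy,
         logLik = x$logLik, support = x$support, n_sites = x$n_sites,
         model = x$model)
}

#' Per-site scores of a conservation profile
#'
#' @param x A `conservation_profile`.
#' @param ... Unused.
#' @return A tibble `site`, `score`, `flagged` (all-gap sites scored 0).
#' @export
tidy.conservation_profile <- function(x, ...) {
  tibble(site = seq_len(x$n_sites), score = unname(x$per_site),
         flagged = seq_len(x$n_sites) %in% x$flagged_sites)
}

#' One-row summary of a conservation profile
#'
#' @param x A `conservation_profile`.
#' @param ... Unused.
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble(locus = x$locus, data_type = x$data_type, metric = x$metric,
         total = x$total, per_length = x$per_length,
         codon_corrected_per_length = x$codon_corrected_per_length,
         gap_fraction = x$gap_fraction, n_sites = x$n_sites)
}

#' Iteration records of an iterative analysis
#'
#' @param x An `iterative_analysis`.
#' @param ... Unused.
#' @export
tidy.iterative_analysis <- function(x, ...) x$records

#' One-row summary of an iterative analysis
#'
#' @param x An `iterative_analysis`.
#' @param ... Unused.
#' @return Reps, N range, and the `#1`/`#4` frequencies at the smallest
#'   and largest N.
#' @export
glance.iterative_analysis <- function(x, ...) {
  freq_at <- function(lab, n) {
    row <- filter(x$topology, .data$label == lab, .data$N == n)
    if (nrow(row)) row$frequency else NA_real_
  }
  n_lo <- min(x$n_range); n_hi <- max(x$n_range)
  tibble(reps = x$reps, n_min = n_lo, n_max = n_hi,
         data_type = x$data_type,
         top1_freq_n_min = freq_at("#1", n_lo),
         top1_freq_n_max = freq_at("#1", n_hi),
         polytomy_freq_n_min = freq_at("#4", n_lo),
         polytomy_freq_n_max = freq_at("#4", n_hi),
         mean_variants_n_min = filter(x$variants,
                                      .data$N == n_lo)$mean,
         mean_variants_n_max = filter(x$variants,
                                      .data$N == n_hi)$mean)
}
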