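#' Count ingroup-informative variant columns
#'
#' The number of alignment columns at which the three ingroup sequences
#' carry at least two distinct non-gap, non-ambiguous residues. Columns
#' varying only in the outgroup are excluded -- they carry no information
#' about ingroup relationships.
#'
#' @param aln A 4-row `seq_alignment`.
#' @param outgroup Row (taxon) label of the outgroup.
#' @return Integer count.
#' @export
count_ingroup_variants <- function(aln, outgroup) {
  stopifnot(inherits(aln, "seq_alignment"), nrow(aln$matrix) == 4L)
  rows <- aln$labels$label
  if (!outgroup %in% rows) abort("outgroup label absent from alignment")
  sub <- aln$matrix[rows != outgroup, , drop = FALSE]
  ambiguous <- if (aln$alphabet == "protein") "X" else c("X", "N")
  sub[sub %in% c(GAP_CHAR, ambiguous)] <- NA
  n_distinct_col <- apply(sub, 2L, function(col)
    length(unique(col[!is.na(col)])))
  sum(n_distinct_col >= 2L)
}

#' Box-plot summary statistics
#'
#' Location and whisker statistics as drawn in the iterative-analysis
#' figures: type-7 (linear interpolation) quartiles, whiskers at
#' `q25 - 1.5 * IQR` and `q75 + 1.5 * IQR`, plus mean, min and max.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble.
#' @export
boxplot_stats <- function(values) {
  if (length(values) == 0L) abort("empty input")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  tibble(n = length(values), mean = mean(values), min = min(values),
         q25 = q[1], median = q[2], q75 = q[3], max = max(values),
         whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr)
}

#' Reference topology implied by a panel's species tree
#'
#' Label `#1` is the simulated sister pair `(taxa[1], taxa[2])`.
#'
#' @param panel A `protein_panel`.
#' @export
panel_reference <- function(panel) {
  reference_topology(panel$spec$taxa, panel$spec$outgroup,
                     pair1 = panel$spec$taxa[1:2])
}

#' @noRd
#' Draw one individual per taxon from the availability table.
draw_individuals <- function(by_taxon, taxa) {
  vapply(taxa, function(tx) {
    ids <- by_taxon[[tx]]
    if (length(ids) == 1L) ids else sample(ids, 1L)
  }, character(1))
}

#' One iteration of the protein-subsampling concatenation analysis
#'
#' Samples `N` loci without replacement, draws one individual per taxon
#' (independently per locus by default, mirroring per-protein sampling of
#' representatives; or once per iteration with
#' `individual_draw = "per-rep"`), concatenates the quartet alignments,
#' fits the maximum-likelihood quartet, optionally bootstraps, collapses
#' short/unsupported internal branches, classifies against the reference
#' tree and counts ingroup variants.
#'
#' @param panel A `protein_panel`.
#' @param N Number of loci to concatenate (<= panel size).
#' @param seed Integer seed for this iteration.
#' @param ref A [reference_topology()]; defaults to [panel_reference()].
#' @param data_type `"protein"` or `"dna"`.
#' @param B Bootstrap replicates for support (0 disables support and makes
#'   collapsing purely length/tie-based).
#' @param min_length,min_support Collapse thresholds
#'   (see [collapse_branches()]).
#' @param individual_draw `"per-locus"` or `"per-rep"`.
#' @param cache Optional environment memoising per-(locus, individuals)
#'   site-pattern and variant counts across iterations; site patterns are
#'   additive over partitions, so the concatenated fit never rebuilds the
#'   supermatrix.
#' @return A one-row tibble: `N`, `label`, `topology`, `n_variants`,
#'   `support`, `logLik`, `loci_used`, `individuals_used`.
#' @export
run_iteration <- function(panel, N, seed, ref = panel_reference(panel),
                          data_type = c("protein", "dna"), B = 0,
                          min_length = 1e-6, min_support = 50,
                          individual_draw = c("per-locus", "per-rep"),
                          cache = NULL) {
  data_type <- match.arg(data_type)
  individual_draw <- match.arg(individual_draw)
  check_seed(seed)
  loci <- panel_loci(panel)
  if (N > length(loci)) abort("`N` exceeds the number of loci in the panel")
  taxa <- panel$spec$taxa
  inds <- panel_individuals(panel)
  if (!all(taxa %in% inds$taxon))
    abort("a taxon has no individuals in the panel")
  by_taxon <- split(inds$individual, inds$taxon)
  alphabet <- if (data_type == "protein") "protein" else "dna"
  outgroup_row <- match(ref$outgroup, taxa)
  if (is.na(outgroup_row)) abort("reference outgroup not a panel taxon")

  locus_part <- function(locus, pick) {
    key <- paste(locus, data_type, paste(pick, collapse = "/"), sep = "@")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    aln <- panel_quartet(panel, locus, individuals = pick,
                         data_type = data_type)
    pdat <- quartet_pattern_data(aln$matrix, aln$alphabet)
    val <- list(counts = setNames(pdat$counts, pdat$keys),
                n_sites = pdat$n_sites,
                n_variants = count_ingroup_variants(aln, ref$outgroup))
    if (!is.null(cache)) cache[[key]] <- val
    val
  }

  with_seed(seed, {
    chosen <- if (N == length(loci)) loci else sample(loci, N)
    chosen <- sort(chosen)
    rep_pick <- if (individual_draw == "per-rep")
      draw_individuals(by_taxon, taxa) else NULL
    picks <- lapply(chosen, function(locus)
      rep_pick %||% draw_individuals(by_taxon, taxa))
    parts <- purrr::map2(chosen, picks, locus_part)
    pdat <- pdat_from_keys(
      merge_pattern_counts(lapply(parts, `[[`, "counts")),
      alphabet_size(alphabet),
      sum(vapply(parts, `[[`, numeric(1), "n_sites")))
    fit <- quartet_fit_from_pdat(pdat, taxa, alphabet)
    if (B > 0) fit <- bootstrap_support(fit, B = B,
                                        seed = derive_seeds(seed, 1L))
    fit <- collapse_branches(fit, min_length = min_length,
                             min_support = min_support)
    used <- vapply(seq_along(chosen), function(i)
      paste0(chosen[i], ":", paste(picks[[i]], collapse = ",")),
      character(1))
    tibble(N = N, label = classify_quartet(fit, ref),
           topology = fit$topology,
           n_variants = sum(vapply(parts, `[[`, numeric(1), "n_variants")),
           support = fit$support, logLik = fit$logLik,
           loci_used = paste(chosen, collapse = ";"),
           individuals_used = paste(used, collapse = ";"))
  })
}

#' Iterative protein-subsampling concatenation analysis
#'
#' The core experiment: for each panel size `N` in `n_range`, repeat
#' [run_iteration()] `reps` times and summarise the topology-label
#' frequencies, the ingroup-variant distributions and the bootstrap
#' support, tracking how phylogenetic resolution grows as proteins
#' accumulate.
#'
#' @inheritParams run_iteration
#' @param n_range Integer vector of panel sizes (e.g. `1:12`).
#' @param reps Repetitions per `N` (default 1000).
#' @param seed Master integer seed; each (N, rep) gets a derived substream.
#' @return An `iterative_analysis` object: `$records` (reps x |n_range|
#'   rows), `$topology` (per-N label frequencies), `$variants` (per-N
#'   [boxplot_stats()] of ingroup variants), `$support` (per-(N, label)
#'   bootstrap summaries, polytomies excluded).
#' @export
run_analysis <- function(panel, n_range = seq_along(panel_loci(panel)),
                         reps = 1000, seed,
                         ref = panel_reference(panel),
                         data_type = c("protein", "dna"), B = 0,
                         min_length = 1e-6, min_support = 50,
                         individual_draw = c("per-locus", "per-rep")) {
  data_type <- match.arg(data_type)
  individual_draw <- match.arg(individual_draw)
  if (reps < 1) abort("`reps` must be >= 1")
  check_seed(seed)
  grid <- tidyr::expand_grid(N = sort(unique(as.integer(n_range))),
                             rep = seq_len(reps))
  seeds <- derive_seeds(seed, nrow(grid))
  cache <- new.env(parent = emptyenv())
  records <- list_rbind(lapply(seq_len(nrow(grid)), function(i) {
    rec <- run_iteration(panel, grid$N[i], seeds[i], ref = ref,
                         data_type = data_type, B = B,
                         min_length = min_length,
                         min_support = min_support,
                         individual_draw = individual_draw,
                         cache = cache)
    rec$rep <- grid$rep[i]
    rec
  }))
  structure(list(records = records,
                 topology = topology_frequencies(records),
                 variants = variant_summary(records),
                 support = support_summary(records),
                 reps = reps, n_range = sort(unique(as.integer(n_range))),
                 data_type = data_type, seed = as.integer(seed)),
            class = "iterative_analysis")
}

#' Per-N topology-label frequencies
#'
#' @param records Iteration records (see [run_analysis()]).
#' @return A tibble `N`, `label`, `count`, `frequency` (counts per N sum
#'   to the repetitions).
#' @export
topology_frequencies <- function(records) {
  records |>
    mutate(label = factor(.data$label, levels = paste0("#", 1:4))) |>
    count(.data$N, .data$label, .drop = FALSE, name = "count") |>
    group_by(.data$N) |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup() |>
    mutate(label = as.character(.data$label))
}

#' @noRd
variant_summary <- function(records) {
  records |>
    group_by(.data$N) |>
    dplyr::group_modify(~ boxplot_stats(.x$n_variants)) |>
    ungroup()
}

#' Bootstrap support grouped by panel size and topology label
#'
#' @param records Iteration records with a `support` column; polytomies
#'   (absent support) are excluded. Empty groups are simply absent.
#' @return A tibble of [boxplot_stats()] per (N, label).
#' @export
support_summary <- function(records) {
  resolved <- filter(records, !is.na(.data$support))
  if (nrow(resolved) == 0L)
    return(tibble(N = integer(), label = character()))
  resolved |>
    group_by(.data$N, .data$label) |>
    dplyr::group_modify(~ boxplot_stats(.x$support)) |>
    ungroup()
}

#' @export
print.iterative_analysis <- function(x, ...) {
  cat(sprintf("<iterative_analysis> %s, N in {%s}, %d reps each\n",
              x$data_type, paste(range(x$n_range), collapse = "..."),
              x$reps))
  top1 <- filter(x$topology, .data$label == "#1")
  cat(sprintf("  #1 frequency: %.1f%% at N=%d -> %.1f%% at N=%d\n",
              100 * top1$frequency[1], min(x$n_range),
              100 * top1$frequency[nrow(top1)], max(x$n_range)))
  invisible(x)
}
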