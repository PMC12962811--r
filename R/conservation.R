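#' Shannon entropy of one alignment column
#'
#' Computes `-sum(p_i log2 p_i)` (bits) over the observed residue
#' frequencies of a column. By default gaps are excluded from the
#' frequencies (their fraction is reported separately by
#' [profile_entropy()]); `gap_policy = "as_state"` counts the gap as a
#' 21st/5th state. Ambiguous residues (`X`/`N`) are always excluded. An
#' all-gap column under `exclude` has no defined score and is reported as 0
#' (flagged by [profile_entropy()]).
#'
#' @param column Character vector of residues.
#' @param gap_policy `"exclude"` (default) or `"as_state"`.
#' @param ambiguous Residues treated as missing (`X` always; `N` only for
#'   nucleotide columns -- it is a real amino acid).
#' @return Entropy in bits; 0 for invariant columns.
#' @examples
#' column_entropy(c("A", "C", "D", "E"))  # 2 bits
#' column_entropy(c("A", "A", "A", "B"))  # 0.8113 bits
#' @export
column_entropy <- function(column, gap_policy = c("exclude", "as_state"),
                           ambiguous = c("X", "N")) {
  gap_policy <- match.arg(gap_policy)
  if (length(column) == 0L) abort("empty column")
  x <- column[!column %in% ambiguous]
  if (gap_policy == "exclude") x <- x[x != GAP_CHAR]
  if (length(x) == 0L) return(0)
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

#' Per-site entropy profile of an alignment
#'
#' Scores every column with [column_entropy()] and aggregates: `total` is
#' the sum over sites, `per_length` the total divided by the alignment
#' length, and `codon_corrected_per_length` applies the divide-by-3 codon
#' correction (see [codon_correct()]) so nucleotide and amino-acid
#' alignments of the same locus are comparable per coding unit.
#'
#' @param aln A `seq_alignment`.
#' @param data_type `"protein"`, `"exon"`, or `"intron_exon"` (the two
#'   nucleotide types differ only in how they are labelled and corrected).
#' @param locus Locus name recorded in the profile.
#' @param gap_policy Passed to [column_entropy()].
#' @param correction_side Passed to [codon_correct()].
#' @return A `conservation_profile` object.
#' @export
profile_entropy <- function(aln, data_type = c("protein", "exon",
                                               "intron_exon"),
                            locus = "locus",
                            gap_policy = c("exclude", "as_state"),
                            correction_side = c("nucleotide", "protein")) {
  data_type <- match.arg(data_type)
  gap_policy <- match.arg(gap_policy)
  correction_side <- match.arg(correction_side)
  stopifnot(inherits(aln, "seq_alignment"))
  if (ncol(aln$matrix) == 0L) abort("zero-width alignment")
  ambiguous <- if (aln$alphabet == "protein") "X" else c("X", "N")
  per_site <- apply(aln$matrix, 2L, column_entropy,
                    gap_policy = gap_policy, ambiguous = ambiguous)
  all_gap <- apply(aln$matrix, 2L, function(col)
    all(col %in% c(GAP_CHAR, ambiguous)))
  gap_fraction <- mean(aln$matrix == GAP_CHAR)
  new_conservation_profile(locus, data_type, "entropy", per_site,
                           all_gap, gap_fraction, correction_side)
}

#' @noRd
new_conservation_profile <- function(locus, data_type, metric, per_site,
                                     flagged = rep(FALSE, length(per_site)),
                                     gap_fraction = 0,
                                     correction_side = "nucleotide") {
  total <- sum(per_site)
  per_length <- total / length(per_site)
  structure(
    list(locus = locus, data_type = data_type, metric = metric,
         per_site = per_site, flagged_sites = which(flagged),
         gap_fraction = gap_fraction,
         total = total, per_length = per_length,
         codon_corrected_per_length = codon_correct(per_length, data_type,
                                                    correction_side),
         n_sites = length(per_site)),
    class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %s [%s, %s]: total %.4g, per-site %.4g (codon-corrected %.4g), %d sites\n",
              x$locus, x$data_type, x$metric, x$total, x$per_length,
              x$codon_corrected_per_length, x$n_sites))
  invisible(x)
}

#' Codon length-correction for cross-data-type comparison
#'
#' Three nucleotides code one amino acid, so per-site scores of nucleotide
#' and protein alignments of the same locus live on different length
#' scales. The correction divides the nucleotide per-site score by 3 while
#' keeping the protein measurement intact (`correction_side =
#' "nucleotide"`, the default). The converse convention -- dividing the
#' protein score by 3 and leaving nucleotide types unaltered -- is exposed
#' as `correction_side = "protein"`; the two conventions order loci and
#' data types identically and differ only by the constant factor.
#'
#' @param per_length_score Non-negative per-site score.
#' @param data_type `"protein"`, `"exon"` or `"intron_exon"`.
#' @param correction_side Which side the factor 3 is applied to.
#' @return The corrected score.
#' @export
codon_correct <- function(per_length_score,
                          data_type = c("protein", "exon", "intron_exon"),
                          correction_side = c("nucleotide", "protein")) {
  data_type <- match.arg(data_type)
  correction_side <- match.arg(correction_side)
  if (any(per_length_score < 0)) abort("score must be >= 0")
  nucleotide <- data_type %in% c("exon", "intron_exon")
  if (correction_side == "nucleotide") {
    if (nucleotide) per_length_score / 3 else per_length_score
  } else {
    if (nucleotide) per_length_score else per_length_score / 3
  }
}

#' Per-site evolutionary rates under a fixed quartet tree
#'
#' A simplified site-rate estimator in the spirit of evolutionary-rate
#' conservation scoring: with the gene tree held fixed, each site's
#' relative rate is the maximum-likelihood scaling factor of all branch
#' lengths under a Poisson amino-acid (or JC69 nucleotide) model, found by
#' bounded one-dimensional search, then normalised to mean 1 across sites.
#' Invariant sites take rate 0 before normalisation. This is a documented
#' approximation to empirical-Bayes rate estimation, validated at the
#' ranking level only.
#'
#' @param aln A 4-row `seq_alignment`.
#' @param tree The fixed gene tree: a `quartet_fit`, or a newick string /
#'   `phylo` whose tip labels match the alignment rows (branch lengths in
#'   substitutions/site).
#' @param locus,data_type Recorded in the profile.
#' @param max_rate Upper bound of the rate search.
#' @return A `conservation_profile` with `metric = "rate"`; if every site
#'   is invariant the profile is flat (all rates equal).
#' @export
site_rates <- function(aln, tree, locus = "locus",
                       data_type = c("protein", "exon", "intron_exon"),
                       max_rate = 50) {
  data_type <- match.arg(data_type)
  stopifnot(inherits(aln, "seq_alignment"))
  labels <- aln$labels$label
  if (inherits(tree, "quartet_fit")) {
    if (!setequal(tree$labels, labels))
      abort("tree/alignment label mismatch")
    cherry <- tree$cherry %||% sort(labels)[1:2]
    bl <- tree$branch_lengths
  } else {
    if (is.character(tree)) tree <- ape::read.tree(text = tree)
    if (!inherits(tree, "phylo")) abort("`tree` must be quartet_fit/newick/phylo")
    if (!setequal(tree$tip.label, labels))
      abort("tree/alignment label mismatch")
    q <- phylo_to_quartet_lengths(tree)
    cherry <- q$cherry
    bl <- q$branch_lengths
  }
  pair1 <- match(cherry, labels)
  perm <- c(pair1, setdiff(seq_len(4L), pair1))
  base <- unname(c(bl[labels[perm]], bl[["internal"]]))
  if (all(base == 0)) base <- rep(1e-3, 5L)

  pdat <- quartet_pattern_data(aln$matrix, aln$alphabet)
  pat_rate <- vapply(seq_along(pdat$counts), function(p) {
    sub <- list(S = pdat$S[, p, drop = FALSE], counts = 1,
                m = pdat$m[p], k = pdat$k, n_sites = 1L)
    f <- make_quartet_loglik(sub, perm)
    if (sub$m <= 1L) return(0)  # invariant or uninformative column
    optimize(function(r) f(r * base), c(0, max_rate), maximum = TRUE,
             tol = 1e-6)$maximum
  }, numeric(1))
  # map pattern rates back onto sites via per-column canonical keys
  cd <- quartet_column_keys(aln$matrix, aln$alphabet)
  per_site <- pat_rate[match(cd, pdat$keys)]
  if (mean(per_site) > 0) per_site <- per_site / mean(per_site)
  else per_site <- rep(1, length(per_site))
  new_conservation_profile(locus, data_type, "rate", per_site)
}

#' @noRd
quartet_column_keys <- function(mat, alphabet) {
  states <- alphabet_states(alphabet)
  s <- matrix(match(mat, states), nrow = 4L)
  na <- is.na(s)
  eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
  s1 <- s[1, ]; s2 <- s[2, ]; s3 <- s[3, ]; s4 <- s[4, ]
  c1 <- ifelse(na[1, ], 0L, 1L); m1 <- c1
  c2 <- ifelse(na[2, ], 0L, ifelse(eq(s2, s1), c1, m1 + 1L))
  m2 <- pmax(m1, c2)
  c3 <- ifelse(na[3, ], 0L,
               ifelse(eq(s3, s1), c1, ifelse(eq(s3, s2), c2, m2 + 1L)))
  m3 <- pmax(m2, c3)
  c4 <- ifelse(na[4, ], 0L,
               ifelse(eq(s4, s1), c1,
                      ifelse(eq(s4, s2), c2, ifelse(eq(s4, s3), c3, m3 + 1L))))
  paste(c1, c2, c3, c4, sep = ".")
}

#' @noRd
#' Map an arbitrary 4-leaf phylo onto cherry + 5 named branch lengths.
phylo_to_quartet_lengths <- function(tree) {
  tree <- ape::unroot(tree)
  labels <- tree$tip.label
  n <- length(labels)
  stopifnot(n == 4L)
  bl <- setNames(numeric(5L), c(labels, "internal"))
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2L]
    if (child <= n) bl[labels[child]] <- tree$edge.length[e]
    else bl["internal"] <- tree$edge.length[e]
  }
  internal_nodes <- unique(edge[, 1L])
  # cherry: two tips sharing a non-root internal parent
  cherry <- NULL
  for (v in internal_nodes) {
    kids <- edge[edge[, 1L] == v, 2L]
    tipkids <- kids[kids <= n]
    if (length(tipkids) == 2L) cherry <- sort(labels[tipkids])
  }
  if (is.null(cherry)) cherry <- sort(labels)[1:2]
  list(cherry = cherry, branch_lengths = bl)
}

#' Mean conservation scores under individual resampling
#'
#' Repeatedly samples one individual per taxon from a panel, scores the
#' resulting four-sequence alignment, and reports the mean per-locus
#' summaries across repetitions together with their Monte-Carlo standard
#' errors -- the resampling protocol that accounts for within-taxon
#' polymorphism.
#'
#' @param panel A `protein_panel`.
#' @param metric `"entropy"` or `"rate"` (rates are estimated on each
#'   resampled quartet's own fitted gene tree).
#' @param data_type Which alignment to score.
#' @param reps Number of resampling repetitions (default 1000).
#' @param seed Integer seed.
#' @param gap_policy Passed to [profile_entropy()].
#' @return A tibble with one row per locus: mean `total`, `per_length`,
#'   `codon_corrected_per_length` across repetitions and the Monte-Carlo
#'   standard error of the total.
#' @export
resampled_scores <- function(panel, metric = c("entropy", "rate"),
                             data_type = c("protein", "dna"),
                             reps = 1000, seed,
                             gap_policy = c("exclude", "as_state")) {
  metric <- match.arg(metric)
  data_type <- match.arg(data_type)
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(panel, "protein_panel"))
  if (reps < 1) abort("`reps` must be >= 1")
  check_seed(seed)
  inds <- panel_individuals(panel)
  if (any(!panel$spec$taxa %in% inds$taxon)) abort("a taxon has no individuals")
  by_taxon <- split(inds$individual, inds$taxon)
  prof_type <- if (data_type == "protein") "protein" else "exon"

  with_seed(seed, {
    rows <- vector("list", length(panel_loci(panel)))
    for (li in seq_along(panel_loci(panel))) {
      locus <- panel_loci(panel)[li]
      totals <- per_lengths <- corrected <- numeric(reps)
      for (r in seq_len(reps)) {
        pick <- vapply(panel$spec$taxa, function(tx) {
          ids <- by_taxon[[tx]]
          if (length(ids) == 1L) ids else sample(ids, 1L)
        }, character(1))
        aln <- panel_quartet(panel, locus, individuals = pick,
                             data_type = data_type)
        prof <- if (metric == "entropy")
          profile_entropy(aln, prof_type, locus, gap_policy = gap_policy)
        else site_rates(aln, fit_quartet(aln), locus, prof_type)
        totals[r] <- prof$total
        per_lengths[r] <- prof$per_length
        corrected[r] <- prof$codon_corrected_per_length
      }
      rows[[li]] <- tibble(
        locus = locus, data_type = prof_type, metric = metric, reps = reps,
        total = mean(totals), total_se = sd(totals) / sqrt(reps),
        per_length = mean(per_lengths),
        codon_corrected_per_length = mean(corrected))
    }
    list_rbind(rows)
  })
}

#' Rank loci by conservation score
#'
#' Orders loci from highest to lowest score, either by the aggregated
#' total (`normalize = FALSE`) or by the length-normalised per-site score
#' (`normalize = TRUE`); long conserved loci and short variable loci can
#' swap ranks between the two modes. Ties are broken lexicographically by
#' locus name and flagged.
#'
#' @param profiles A list of `conservation_profile` objects or a tibble
#'   with columns `locus`, `data_type`, `total`, `per_length`.
#' @param normalize Rank by per-site score instead of total.
#' @return A tibble ordered by decreasing score with columns `rank`,
#'   `locus`, `score`, `tied`.
#' @export
rank_loci <- function(profiles, normalize = FALSE) {
  tab <- if (is.data.frame(profiles)) as_tibble(profiles)
  else list_rbind(lapply(profiles, function(p)
    tibble(locus = p$locus, data_type = p$data_type, metric = p$metric,
           total = p$total, per_length = p$per_length)))
  if (nrow(tab) == 0L) abort("no profiles to rank")
  if (length(unique(tab$data_type)) != 1L)
    abort("cannot rank mixed data types together",
          class = "pq_error_mixed_types")
  tab$score <- if (normalize) tab$per_length else tab$total
  tab <- arrange(tab, desc(.data$score), .data$locus)
  tab$rank <- seq_len(nrow(tab))
  tab$tied <- duplicated(tab$score) | duplicated(tab$score, fromLast = TRUE)
  select(tab, "rank", "locus", "data_type", "score", "tied")
}
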