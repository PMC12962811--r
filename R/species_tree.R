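#' Specify a four-taxon species (population) tree
#'
#' The simulator works on a rooted four-taxon population tree
#' `(((A,B),C),O)` with all times in coalescent units (one unit = 2N
#' generations of the reference population). The two ingroup splits occur at
#' `t_ab` (A--B divergence) and `t_abc = t_ab + internal_t` (C joining the
#' A--B ancestor); the outgroup O splits at `t_out`. `internal_t` is the
#' duration of the internal branch on which A and B lineages may fail to
#' coalesce, producing incomplete lineage sorting: under this
#' parameterisation a locus genealogy is discordant with the population tree
#' with probability (2/3)·exp(-internal_t / N_AB).
#'
#' @param taxa Character vector of four taxon names, ordered `(A, B, C, O)`:
#'   `A` and `B` are the expected sister pair, `C` the third ingroup taxon,
#'   `O` the outgroup.
#' @param outgroup Name of the outgroup taxon; must be `taxa[4]`.
#' @param t_ab Divergence time of A and B (coalescent units, > 0).
#' @param internal_t Duration of the internal branch between the two ingroup
#'   splits (>= 0).
#' @param t_out Divergence time of the outgroup; must exceed
#'   `t_ab + internal_t`.
#' @param pop_sizes Named numeric vector of per-branch coalescent scaling
#'   factors for populations `A`, `B`, `C`, `O`, `AB`, `ABC`, `ABCO`
#'   (an entry of 1 means coalescence at rate 1 per lineage pair per unit).
#'   Missing entries default to 1.
#' @param admixture_events Optional tibble/data frame with columns `source`,
#'   `target` (taxon names), `time` (coalescent units, before the target
#'   joins any ancestor) and `proportion` (migration probability m in
#'   \[0, 1\]): at `time`, each sampled lineage of `target` is reassigned to
#'   the `source` population with probability m.
#' @return An object of class `species_tree_spec`.
#' @examples
#' spec <- species_tree(c("A", "B", "C", "O"), t_ab = 1, internal_t = 1,
#'                      t_out = 5)
#' @export
species_tree <- function(taxa, outgroup = taxa[4], t_ab, internal_t, t_out,
                         pop_sizes = NULL, admixture_events = NULL) {
  if (length(taxa) != 4L || anyDuplicated(taxa))
    abort("`taxa` must be four distinct names")
  if (!identical(outgroup, taxa[4]))
    abort("`outgroup` must be the fourth element of `taxa`")
  if (!is.numeric(t_ab) || t_ab <= 0) abort("`t_ab` must be > 0")
  if (!is.numeric(internal_t) || internal_t < 0)
    abort("`internal_t` must be >= 0")
  t_abc <- t_ab + internal_t
  if (!is.numeric(t_out) || t_out <= t_abc)
    abort("`t_out` must exceed t_ab + internal_t: the outgroup split predates both ingroup splits")
  pops <- c("A", "B", "C", "O", "AB", "ABC", "ABCO")
  sizes <- setNames(rep(1, 7L), pops)
  if (!is.null(pop_sizes)) {
    if (is.null(names(pop_sizes)) || !all(names(pop_sizes) %in% pops))
      abort("`pop_sizes` must be named with population labels A,B,C,O,AB,ABC,ABCO")
    if (any(pop_sizes <= 0)) abort("population sizes must be positive")
    sizes[names(pop_sizes)] <- pop_sizes
  }
  adm <- NULL
  if (!is.null(admixture_events)) {
    adm <- as_tibble(admixture_events)
    need <- c("source", "target", "time", "proportion")
    if (!all(need %in% names(adm)))
      abort("`admixture_events` needs columns source, target, time, proportion")
    if (!all(adm$source %in% taxa) || !all(adm$target %in% taxa))
      abort("admixture source/target must be taxon names")
    if (any(adm$proportion < 0 | adm$proportion > 1))
      abort("admixture proportion must lie in [0, 1]")
    if (any(adm$time < 0)) abort("admixture times must be >= 0")
    adm <- arrange(adm, .data$time)
  }
  structure(
    list(taxa = taxa, outgroup = outgroup,
         split_times = c(t_ab = t_ab, t_abc = t_abc, t_out = t_out),
         internal_t = internal_t, pop_sizes = sizes,
         admixture_events = adm),
    class = "species_tree_spec")
}

#' @export
print.species_tree_spec <- function(x, ...) {
  cat("<species_tree_spec>\n")
  cat(sprintf("  tree: (((%s,%s),%s),%s)\n", x$taxa[1], x$taxa[2],
              x$taxa[3], x$taxa[4]))
  cat(sprintf("  splits (coal. units): t_ab=%.3g  t_abc=%.3g  t_out=%.3g  (internal T=%.3g)\n",
              x$split_times[1], x$split_times[2], x$split_times[3],
              x$internal_t))
  if (!is.null(x$admixture_events))
    cat(sprintf("  admixture pulses: %d\n", nrow(x$admixture_events)))
  invisible(x)
}

#' Hominid-like species-tree preset
#'
#' A great-ape-like configuration: deep splits, an internal branch long
#' enough that incomplete lineage sorting affects a modest fraction of loci
#' (discordance (2/3)e^-1.4 ~ 16%), and a distant outgroup. These times are
#' package presets on the coalescent-unit scale, chosen to reproduce
#' genome-scale observations for human/chimp/gorilla/orangutan comparisons;
#' they are adjustable, not literature estimates.
#'
#' @param taxa Four taxon names `(A, B, C, O)` with `O` the outgroup.
#' @param internal_t Internal branch duration (coalescent units).
#' @param ... Passed to [species_tree()].
#' @return A `species_tree_spec`.
#' @export
hominid_tree <- function(taxa = c("Homo", "Pan", "Gorilla", "Pongo"),
                         internal_t = 1.4, ...) {
  species_tree(taxa, t_ab = 5, internal_t = internal_t, t_out = 12,
               pop_sizes = c(A = 0.1, B = 0.1, C = 0.1, O = 0.1), ...)
}

#' Hominin-like species-tree preset
#'
#' A configuration emulating three very closely related populations (modern
#' humans, Neanderthals, Denisovans) with a distant outgroup: shallow ingroup
#' splits, a very short internal branch (default 0.05 coalescent units, so
#' roughly (2/3)e^-0.05 ~ 63% of true gene trees are discordant), and small
#' within-taxon diversity. The expected sister pair `(A, B)` corresponds to
#' the two archaic lineages.
#'
#' @inheritParams hominid_tree
#' @param admixture_events Optional archaic-introgression pulses, e.g. from
#'   taxon A into C (see [species_tree()]).
#' @export
hominin_tree <- function(taxa = c("Neanderthal", "Denisovan", "Sapiens", "Pan"),
                         internal_t = 0.05, admixture_events = NULL, ...) {
  species_tree(taxa, t_ab = 0.6, internal_t = internal_t, t_out = 12,
               pop_sizes = c(A = 0.05, B = 0.05, C = 0.05, O = 0.1,
                             AB = 1, ABC = 0.3, ABCO = 1),
               admixture_events = admixture_events, ...)
}
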