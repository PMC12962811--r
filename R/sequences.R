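#' @noRd
#' Mutate one codon through `n` accepted/rejected single-nucleotide
#' proposals. `m` is max(1, omega); acceptance is 1/m for synonymous and
#' omega/m for nonsynonymous proposals, stops always rejected.
evolve_codon <- function(codon, n, omega, m) {
  nb <- codon_neighbours()
  for (k in seq_len(n)) {
    cand <- nb[[codon]]
    j <- sample.int(9L, 1L)
    cls <- cand$cls[j]
    if (cls == "stop") next
    acc <- if (cls == "syn") 1 / m else omega / m
    if (runif(1L) < acc) codon <- cand$neigh[j]
  }
  codon
}

#' @noRd
#' Evolve a codon vector along one branch of length `t` (coalescent units).
evolve_branch_codons <- function(codons, t, locus) {
  m <- max(1, locus$omega)
  lambda <- locus$mu * locus$rate_profile * m * t
  nprop <- rpois(length(codons), lambda)
  hit <- which(nprop > 0L)
  for (i in hit) codons[i] <- evolve_codon(codons[i], nprop[i],
                                           locus$omega, m)
  codons
}

#' @noRd
#' Neutral Jukes-Cantor evolution of intron nucleotides along one branch;
#' the per-site substitution rate mu/3 matches a synonymous codon position.
evolve_branch_intron <- function(nt, t, mu) {
  nmut <- rpois(length(nt), mu / 3 * t)
  hit <- which(nmut > 0L)
  for (i in hit) {
    for (k in seq_len(nmut[i])) nt[i] <- sample(setdiff(DNA_STATES, nt[i]), 1L)
  }
  nt
}

#' Evolve DNA and protein sequences along a gene tree
#'
#' Simulates the codon process of a [locus_model()] down a rooted gene tree
#' (branch lengths in coalescent units): a stop-free root sequence is drawn
#' uniformly over sense codons, single-nucleotide changes are proposed at
#' rate `mu * rate_profile` per codon per unit, synonymous changes accepted
#' at relative rate 1 and nonsynonymous at relative rate `omega`, stop
#' codons rejected. Protein tips are exact standard-code translations of
#' the DNA tips. If the locus declares intron sites, a neutral
#' Jukes--Cantor intron evolves on the same tree.
#'
#' @param tree A rooted gene tree: an `ape::phylo`, a newick string, or a
#'   one-row tibble from [simulate_gene_trees()].
#' @param locus A [locus_model()].
#' @param seed Integer seed.
#' @return A list of sequence-set tibbles: `dna` (exons only), `protein`,
#'   and `intron_exon` (intron plus exon) when the locus has intron sites.
#' @export
evolve_sequences <- function(tree, locus, seed) {
  check_seed(seed)
  if (!inherits(locus, "locus_model")) abort("`locus` must be a locus_model")
  if (locus$n_codons < 1L) abort("zero-length locus")
  if (is.data.frame(tree)) tree <- tree$newick[1]
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo/newick gene tree")
  if (is.null(tree$edge.length)) abort("gene tree must have branch lengths")

  ct <- codon_table()
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    root_codons <- sample(ct$sense, locus$n_codons, replace = TRUE)
    root_intron <- if (locus$n_intron_sites > 0L)
      sample(DNA_STATES, locus$n_intron_sites, replace = TRUE) else NULL

    codon_seqs <- vector("list", n_tip + tree$Nnode)
    intron_seqs <- vector("list", n_tip + tree$Nnode)
    codon_seqs[[root]] <- root_codons
    intron_seqs[[root]] <- root_intron

    po <- rev(ape::postorder(tree))  # parents before children
    for (e in po) {
      parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      t_br <- tree$edge.length[e]
      codon_seqs[[child]] <- evolve_branch_codons(codon_seqs[[parent]],
                                                  t_br, locus)
      if (!is.null(root_intron))
        intron_seqs[[child]] <- evolve_branch_intron(intron_seqs[[parent]],
                                                     t_br, locus$mu)
    }

    labels <- tree$tip.label
    dna <- vapply(seq_len(n_tip),
                  function(i) paste(codon_seqs[[i]], collapse = ""),
                  character(1))
    protein <- vapply(dna, translate_dna, character(1), USE.NAMES = FALSE)
    out <- list(
      dna = tibble(label = labels, sequence = dna),
      protein = tibble(label = labels, sequence = protein))
    if (!is.null(root_intron)) {
      intron <- vapply(seq_len(n_tip),
                       function(i) paste(intron_seqs[[i]], collapse = ""),
                       character(1))
      out$intron_exon <- tibble(label = labels,
                                sequence = paste0(intron, dna))
    }
    out
  })
}
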