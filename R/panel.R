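#' Generate a multi-individual protein panel with known ground truth
#'
#' Simulates, for each locus, one gene tree shared by all sampled
#' individuals (the within-taxon genealogy is part of the same structured
#' coalescent, so individuals of one taxon carry realistic shared
#' polymorphism), then evolves DNA and protein sequences down that tree.
#' The result emulates a palaeoproteomic reference panel: P loci times four
#' taxa times several individuals, heterogeneous per-locus conservation,
#' and -- when the species tree carries admixture pulses -- archaic
#' introgressed haplotypes in a subset of individuals.
#'
#' @param spec A [species_tree()] specification.
#' @param loci List of [locus_model()] objects with distinct names.
#' @param individuals_per_taxon Integer (scalar or length 4, ordered as
#'   `spec$taxa`).
#' @param seed Master integer seed; per-locus substreams are derived from
#'   it deterministically.
#' @return A `protein_panel`: per-locus `seq_alignment`s (`$alignments`,
#'   each with `dna`, `protein` and optionally `intron_exon`), a
#'   ground-truth tibble `$truth` (locus, topology_class, ils_flag,
#'   introgressed_flag, newick, based on the first individual of each
#'   taxon), and per-sequence introgression flags `$carriers`.
#' @export
build_panel <- function(spec, loci, individuals_per_taxon = 1L, seed) {
  if (!inherits(spec, "species_tree_spec"))
    abort("`spec` must be a species_tree_spec")
  if (inherits(loci, "locus_model")) loci <- list(loci)
  names(loci) <- vapply(loci, function(l) l$name, character(1))
  if (anyDuplicated(names(loci)))
    abort("duplicate locus names", class = "pq_error_duplicate_locus")
  check_seed(seed)
  stopifnot(all(individuals_per_taxon >= 1L))

  locus_seeds <- derive_seeds(seed, 2L * length(loci))
  truth <- vector("list", length(loci))
  carriers <- vector("list", length(loci))
  alignments <- vector("list", length(loci))

  for (i in seq_along(loci)) {
    locus <- loci[[i]]
    g <- with_seed(locus_seeds[i], sim_genealogy(spec, individuals_per_taxon))
    seqs <- evolve_sequences(genealogy_phylo(g), locus,
                             locus_seeds[length(loci) + i])
    ann <- function(ss) {
      ss <- parse_seq_labels(ss, fields = c("taxon", "individual"))
      as_seq_alignment(ss)
    }
    alignments[[i]] <- lapply(seqs, ann)
    truth[[i]] <- tibble(
      locus = locus$name,
      topology_class = cherry_to_class[[g$cherry]],
      ils_flag = is.na(g$t_ab_coal) || g$t_ab_coal > g$t_abc,
      introgressed_flag = any(g$introgressed_tip),
      newick = genealogy_newick(g))
    carriers[[i]] <- tibble(locus = locus$name, taxon = g$tip_taxon,
                            individual = paste0("ind", g$tip_ind),
                            introgressed = g$introgressed_tip)
  }
  names(alignments) <- names(loci)
  structure(list(spec = spec, loci = loci,
                 individuals_per_taxon = individuals_per_taxon,
                 alignments = alignments,
                 truth = list_rbind(truth),
                 carriers = list_rbind(carriers),
                 seed = as.integer(seed)),
            class = "protein_panel")
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("<protein_panel> %d loci x 4 taxa (%s)\n",
              length(x$loci), paste(x$spec$taxa, collapse = ", ")))
  cat(sprintf("  individuals/taxon: %s; discordant gene trees: %d; introgressed loci: %d\n",
              paste(x$individuals_per_taxon, collapse = "/"),
              sum(x$truth$topology_class != "concordant"),
              sum(x$truth$introgressed_flag)))
  invisible(x)
}

#' Locus names of a panel
#' @param panel A `protein_panel`.
#' @export
panel_loci <- function(panel) names(panel$alignments)

#' Individuals available per taxon
#' @param panel A `protein_panel`.
#' @return A tibble `taxon`, `individual`.
#' @export
panel_individuals <- function(panel) {
  distinct(panel$carriers, .data$taxon, .data$individual)
}

#' Extract a one-individual-per-taxon quartet alignment for one locus
#'
#' @param panel A `protein_panel`.
#' @param locus Locus name.
#' @param individuals Named character vector `taxon -> individual`; defaults
#'   to the first individual of each taxon.
#' @param data_type `"protein"`, `"dna"` or `"intron_exon"`.
#' @return A 4-row `seq_alignment` whose rows are labelled by taxon.
#' @export
panel_quartet <- function(panel, locus,
                          individuals = NULL,
                          data_type = c("protein", "dna", "intron_exon")) {
  data_type <- match.arg(data_type)
  aln <- panel$alignments[[locus]][[data_type]]
  if (is.null(aln)) abort(paste0("locus/data type not in panel: ", locus,
                                 "/", data_type))
  taxa <- panel$spec$taxa
  if (is.null(individuals))
    individuals <- setNames(rep("ind1", 4L), taxa)
  want <- paste0(taxa, "|", individuals[taxa])
  idx <- match(want, aln$labels$label)
  if (anyNA(idx)) abort(paste0("individual not in panel: ",
                               want[which(is.na(idx))[1]]))
  seqs <- tibble(label = taxa, taxon = taxa,
                 individual = unname(individuals[taxa]),
                 sequence = apply(aln$matrix[idx, , drop = FALSE], 1L,
                                  paste, collapse = ""))
  as_seq_alignment(seqs, alphabet = aln$alphabet)
}

#' Restrict a panel to whitelisted individuals
#'
#' Mirrors analyses that restrict the modern-human representative to
#' largely unadmixed population panels: taxa named in the whitelist keep
#' only the listed individuals, all other taxa are untouched.
#'
#' @param panel A `protein_panel`.
#' @param individual_whitelist Named list `taxon -> character vector of
#'   individual ids` (e.g. `list(Sapiens = c("ind1", "ind3"))`).
#' @return A filtered `protein_panel`.
#' @export
filter_panel <- function(panel, individual_whitelist) {
  stopifnot(inherits(panel, "protein_panel"))
  if (length(individual_whitelist) == 0L ||
      is.null(names(individual_whitelist)))
    abort("`individual_whitelist` must be a named list taxon -> individuals")
  have <- panel_individuals(panel)
  for (tx in names(individual_whitelist)) {
    keep <- individual_whitelist[[tx]]
    avail <- filter(have, .data$taxon == tx)$individual
    if (length(intersect(keep, avail)) == 0L)
      abort(paste0("whitelist removes taxon entirely: ", tx),
            class = "pq_error_empty_taxon")
  }
  drop_row <- function(lbl_taxon, lbl_ind) {
    tx_listed <- lbl_taxon %in% names(individual_whitelist)
    tx_listed & !mapply(function(tx, id)
      id %in% individual_whitelist[[tx]], lbl_taxon, lbl_ind)
  }
  panel$alignments <- lapply(panel$alignments, function(types)
    lapply(types, function(aln) {
      drop <- drop_row(aln$labels$taxon, aln$labels$individual)
      aln$labels <- aln$labels[!drop, , drop = FALSE]
      aln$matrix <- aln$matrix[!drop, , drop = FALSE]
      aln
    }))
  panel$carriers <- filter(panel$carriers,
                           !drop_row(.data$taxon, .data$individual))
  panel
}

#' Write a panel to disk (one FASTA per locus plus ground truth)
#'
#' Writes `protein/<locus>.fasta` and `dna/<locus>.fasta` with headers
#' `taxon|individual|locus`, the ground-truth sidecar `truth.tsv`, the
#' per-sequence introgression flags `carriers.tsv`, and a `config.yaml`
#' recording the species tree, loci and seed.
#'
#' @param panel A `protein_panel`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "protein_panel"))
  for (sub in c("protein", "dna"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (locus in panel_loci(panel)) {
    for (sub in c("protein", "dna")) {
      aln <- panel$alignments[[locus]][[sub]]
      seqs <- as_seq_set(aln)
      seqs$label <- paste0(seqs$label, "|", locus)
      write_fasta(seqs, file.path(dir, sub, paste0(locus, ".fasta")))
    }
  }
  write.table(panel$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(panel$carriers, file.path(dir, "carriers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- list(
    taxa = as.list(panel$spec$taxa), outgroup = panel$spec$outgroup,
    split_times = as.list(panel$spec$split_times),
    internal_t = panel$spec$internal_t,
    pop_sizes = as.list(panel$spec$pop_sizes),
    individuals_per_taxon = panel$individuals_per_taxon,
    seed = panel$seed,
    loci = lapply(panel$loci, function(l)
      list(name = l$name, n_codons = l$n_codons, mu = l$mu,
           omega = l$omega, n_intron_sites = l$n_intron_sites)))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a panel written by [write_panel()]
#'
#' @param dir Panel directory.
#' @return A `protein_panel` (alignments, truth and carriers; the species
#'   tree is rebuilt from `config.yaml`).
#' @export
read_panel <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  spec <- species_tree(unlist(cfg$taxa), cfg$outgroup,
                       t_ab = cfg$split_times$t_ab,
                       internal_t = cfg$internal_t,
                       t_out = cfg$split_times$t_out,
                       pop_sizes = unlist(cfg$pop_sizes))
  loci <- lapply(cfg$loci, function(l)
    locus_model(l$name, l$n_codons, l$mu, l$omega,
                n_intron_sites = l$n_intron_sites))
  names(loci) <- vapply(loci, function(l) l$name, character(1))
  read_aln <- function(path) {
    seqs <- parse_seq_labels(read_fasta(path),
                             fields = c("taxon", "individual", "locus"))
    seqs$label <- paste(seqs$taxon, seqs$individual, sep = "|")
    as_seq_alignment(seqs)
  }
  alignments <- lapply(names(loci), function(nm) {
    out <- list(
      protein = read_aln(file.path(dir, "protein", paste0(nm, ".fasta"))),
      dna = read_aln(file.path(dir, "dna", paste0(nm, ".fasta"))))
    out
  })
  names(alignments) <- names(loci)
  truth <- as_tibble(read.table(file.path(dir, "truth.tsv"), sep = "\t",
                                header = TRUE))
  carriers <- as_tibble(read.table(file.path(dir, "carriers.tsv"),
                                   sep = "\t", header = TRUE))
  structure(list(spec = spec, loci = loci,
                 individuals_per_taxon = cfg$individuals_per_taxon,
                 alignments = alignments, truth = truth,
                 carriers = carriers, seed = cfg$seed),
            class = "protein_panel")
}
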