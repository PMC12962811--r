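#' Describe the substitution process of one protein-coding locus
#'
#' A locus is a stretch of `n_codons` codons evolving under a simplified
#' codon process: single-nucleotide changes are proposed at rate
#' `mu * rate_profile[i]` per codon per coalescent unit; proposals producing
#' stop codons are rejected, synonymous proposals are accepted at relative
#' rate 1 and nonsynonymous proposals at relative rate `omega`. Low `omega`
#' therefore yields conserved proteins whose DNA still accumulates
#' synonymous variation -- the conservation heterogeneity that drives
#' protein-versus-DNA information comparisons. An optional neutral intron
#' of `n_intron_sites` nucleotides evolves alongside under Jukes--Cantor at
#' the synonymous-equivalent per-site rate `mu / 3`.
#'
#' @param name Locus name (unique within a panel).
#' @param n_codons Number of codons (> 0).
#' @param mu Proposal rate per codon per coalescent unit.
#' @param omega Nonsynonymous/synonymous acceptance ratio in `[0, Inf)`.
#' @param rate_profile Optional per-codon relative rates (non-negative,
#'   rescaled to mean 1); default flat.
#' @param n_intron_sites Neutral intron length in nucleotides (default 0).
#' @return A `locus_model` object.
#' @export
locus_model <- function(name, n_codons, mu, omega = 1,
                        rate_profile = NULL, n_intron_sites = 0L) {
  if (!is.numeric(n_codons) || n_codons < 1) abort("`n_codons` must be > 0")
  if (!is.numeric(mu) || mu < 0) abort("`mu` must be >= 0")
  if (!is.numeric(omega) || omega < 0) abort("`omega` must be >= 0")
  n_codons <- as.integer(n_codons)
  if (is.null(rate_profile)) rate_profile <- rep(1, n_codons)
  if (length(rate_profile) != n_codons)
    abort("`rate_profile` must have one entry per codon")
  if (any(rate_profile < 0)) abort("rates must be non-negative")
  if (mean(rate_profile) > 0)
    rate_profile <- rate_profile / mean(rate_profile)
  structure(list(name = as.character(name), n_codons = n_codons, mu = mu,
                 omega = omega, rate_profile = rate_profile,
                 n_intron_sites = as.integer(n_intron_sites)),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %s: %d codons, mu=%.4g, omega=%.3g, intron=%dnt\n",
              x$name, x$n_codons, x$mu, x$omega, x$n_intron_sites))
  invisible(x)
}

#' Default locus set emulating a deep-time protein panel
#'
#' Twelve loci with lengths matching the enamel/collagen proteins routinely
#' recovered from million-year-old fossil material (AMELX, ENAM, AMBN, AMTN,
#' ODAM, MMP20, COL17A1, AHSG, ALB, AMELY and the two collagen type I
#' chains) and heterogeneous purifying selection: collagens and AMELX
#' strongly conserved (low omega), ODAM and AMELY fast.
#'
#' @param mu Shared proposal rate per codon per coalescent unit.
#' @return A list of [locus_model()] objects.
#' @export
deep_time_loci <- function(mu = 0.004) {
  spec <- tibble(
    name = c("AMELX", "AMELY", "AMBN", "AMTN", "ENAM", "ODAM",
             "MMP20", "COL17A1", "AHSG", "ALB", "COL1A1", "COL1A2"),
    n_codons = c(205L, 206L, 447L, 209L, 1142L, 279L,
                 483L, 1497L, 367L, 609L, 1464L, 1366L),
    omega = c(0.08, 0.8, 0.35, 0.4, 0.35, 0.7,
              0.25, 0.2, 0.3, 0.3, 0.05, 0.05))
  purrr::pmap(spec, function(name, n_codons, omega)
    locus_model(name, n_codons, mu, omega))
}

#' Strongly conserved locus set
#'
#' Twelve collagen-like loci under strong purifying selection (low omega):
#' their DNA accumulates synonymous variation and usually resolves the
#' quartet, while the protein is nearly invariant -- the configuration in
#' which translation visibly destroys phylogenetic information.
#'
#' @param n Number of loci.
#' @param n_codons,mu,omega Shared locus parameters.
#' @return A list of [locus_model()] objects.
#' @export
conserved_loci <- function(n = 12, n_codons = 400, mu = 0.012,
                           omega = 0.02) {
  lapply(seq_len(n), function(i)
    locus_model(sprintf("CONS%02d", i), n_codons, mu, omega))
}

# --- genetic code tables ---------------------------------------------------

codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      codons <- names(gc)
      tab <<- list(codons = codons, aa = unname(gc),
                   sense = codons[gc != "*"])
    }
    tab
  }
})

#' @noRd
#' For each sense codon, the 9 single-nucleotide neighbours with their
#' acceptance class: "syn", "nonsyn" or "stop".
codon_neighbours <- local({
  nb <- NULL
  function() {
    if (!is.null(nb)) return(nb)
    ct <- codon_table()
    aa_of <- setNames(ct$aa, ct$codons)
    out <- lapply(ct$codons, function(cd) {
      if (aa_of[[cd]] == "*") return(NULL)
      nts <- strsplit(cd, "")[[1]]
      neigh <- character(0); cls <- character(0)
      for (pos in 1:3) for (alt in setdiff(DNA_STATES, nts[pos])) {
        x <- nts; x[pos] <- alt
        cd2 <- paste(x, collapse = "")
        neigh <- c(neigh, cd2)
        cls <- c(cls, if (aa_of[[cd2]] == "*") "stop"
                 else if (aa_of[[cd2]] == aa_of[[cd]]) "syn" else "nonsyn")
      }
      list(neigh = neigh, cls = cls)
    })
    names(out) <- ct$codons
    nb <<- out
    nb
  }
})
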