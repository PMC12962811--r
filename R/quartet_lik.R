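QUARTET_PERMS <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))

#' @noRd
#' Compress a 4-row alignment into canonical site patterns.
#'
#' Each column is recoded by first occurrence (gaps/ambiguity -> 0), so
#' likelihood under an exchangeable model (JC69 / Poisson) depends only on
#' the pattern and the number of distinct observed states m. At most 15
#' distinct patterns exist regardless of alignment length.
quartet_pattern_data <- function(mat, alphabet) {
  stopifnot(nrow(mat) == 4L)
  states <- alphabet_states(alphabet)
  s <- matrix(match(mat, states), nrow = 4L)
  na <- is.na(s)
  eq <- function(a, b) !is.na(a) & !is.na(b) & a == b
  s1 <- s[1L, ]; s2 <- s[2L, ]; s3 <- s[3L, ]; s4 <- s[4L, ]
  c1 <- ifelse(na[1L, ], 0L, 1L)
  m1 <- c1
  c2 <- ifelse(na[2L, ], 0L, ifelse(eq(s2, s1), c1, m1 + 1L))
  m2 <- pmax(m1, c2)
  c3 <- ifelse(na[3L, ], 0L,
               ifelse(eq(s3, s1), c1, ifelse(eq(s3, s2), c2, m2 + 1L)))
  m3 <- pmax(m2, c3)
  c4 <- ifelse(na[4L, ], 0L,
               ifelse(eq(s4, s1), c1,
                      ifelse(eq(s4, s2), c2, ifelse(eq(s4, s3), c3, m3 + 1L))))
  key <- paste(c1, c2, c3, c4, sep = ".")
  counts <- table(key)
  pdat_from_keys(setNames(as.numeric(counts), names(counts)),
                 alphabet_size(alphabet), ncol(mat))
}

#' @noRd
#' Rebuild pattern data from a named count vector ("c1.c2.c3.c4" keys).
#' Pattern counts are additive across concatenated partitions, so merged
#' loci can be fitted without rebuilding the supermatrix.
pdat_from_keys <- function(named_counts, k, n_sites) {
  S <- vapply(strsplit(names(named_counts), ".", fixed = TRUE),
              as.integer, integer(4L))
  if (is.null(dim(S))) S <- matrix(S, nrow = 4L)
  list(S = S, counts = unname(named_counts), keys = names(named_counts),
       m = apply(S, 2L, max), k = k, n_sites = n_sites)
}

#' @noRd
merge_pattern_counts <- function(count_list) {
  all_keys <- unique(unlist(lapply(count_list, names)))
  out <- setNames(numeric(length(all_keys)), all_keys)
  for (ct in count_list) out[names(ct)] <- out[names(ct)] + ct
  out
}

#' @noRd
#' Log-likelihood closure for one tip arrangement ((p1,p2),(p3,p4)).
#' The state space is lumped to {observed states, other}: exact under
#' equal-rates equal-frequency models. Branch length order: pendant
#' branches of the four arranged tips, then the internal branch.
make_quartet_loglik <- function(pdat, perm, counts = NULL) {
  S <- pdat$S[perm, , drop = FALSE]
  k <- pdat$k
  m <- pdat$m
  counts <- counts %||% pdat$counts
  P <- ncol(S)
  # 0/1 indicator (P x 5) of tip state == class; 5th ("other") column 0.
  # Rows with missing tips get the all-ones conditional.
  Imats <- lapply(1:4, function(j) {
    I <- matrix(0, P, 5L)
    I[cbind(which(S[j, ] > 0L), S[j, S[j, ] > 0L])] <- 1
    I
  })
  miss <- lapply(1:4, function(j) which(S[j, ] == 0L))
  V <- outer(m, 1:4, ">=") * 1  # mask of classes actually observed
  ovec <- k - m                  # multiplicity of the lumped "other" class
  kfac <- k / (k - 1)

  # Summing the internal-branch transition over lumped classes collapses
  # to inner_x = pd5*wB + (ps5-pd5)*B_x for every class x, hence
  # L = (pd5*wA*wB + (ps5-pd5)*C) / k with wA, wB the size-weighted
  # conditional sums and C their size-weighted elementwise product.
  function(t5) {
    e <- exp(-kfac * t5)
    ps <- 1 / k + (k - 1) / k * e
    pd <- (1 - e) / k
    cond <- function(j) {
      cc <- pd[j] + (ps[j] - pd[j]) * Imats[[j]]
      if (length(miss[[j]])) cc[miss[[j]], ] <- 1
      cc
    }
    A <- cond(1L) * cond(2L)
    B <- cond(3L) * cond(4L)
    Ao <- A[, 1:4, drop = FALSE] * V
    Bo <- B[, 1:4, drop = FALSE] * V
    wA <- rowSums(Ao) + ovec * A[, 5L]
    wB <- rowSums(Bo) + ovec * B[, 5L]
    C <- rowSums(Ao * Bo) + ovec * A[, 5L] * B[, 5L]
    L <- (pd[5L] * wA * wB + (ps[5L] - pd[5L]) * C) / k
    sum(counts * log(L))
  }
}

#' @noRd
split_string <- function(labels, perm) {
  sides <- c(paste(sort(labels[perm[1:2]]), collapse = ","),
             paste(sort(labels[perm[3:4]]), collapse = ","))
  paste(sort(sides), collapse = "|")
}

#' Quartet log-likelihood under an exchangeable substitution model
#'
#' Felsenstein pruning over an unrooted four-taxon tree under JC69 (DNA) or
#' a Poisson amino-acid model (equal exchangeabilities and frequencies).
#' Branch lengths are expected substitutions per site. Gaps and ambiguous
#' residues are treated as missing data. The value is invariant to
#' re-rooting.
#'
#' @param aln A 4-row `seq_alignment`.
#' @param topology One side of the split: a character vector of two row
#'   labels forming a cherry (e.g. `c("Homo", "Pan")`).
#' @param branch_lengths Numeric vector of 5 non-negative lengths, named by
#'   the four row labels plus `"internal"`.
#' @param model `"auto"` (from the alphabet), `"JC69"` or `"PoissonAA"`.
#' @return The log-likelihood (sum over sites).
#' @export
quartet_log_likelihood <- function(aln, topology, branch_lengths,
                                   model = c("auto", "JC69", "PoissonAA")) {
  model <- match.arg(model)
  check_quartet_model(aln, model)
  labels <- aln$labels$label
  if (!all(topology %in% labels) || length(topology) != 2L)
    abort("`topology` must name two row labels forming a cherry")
  if (length(branch_lengths) != 5L || any(!is.finite(branch_lengths)) ||
      any(branch_lengths < 0))
    abort("`branch_lengths` must be 5 finite non-negative values")
  if (is.null(names(branch_lengths)))
    abort("`branch_lengths` must be named by the row labels plus 'internal'")
  pair1 <- match(topology, labels)
  perm <- c(pair1, setdiff(1:4, pair1))
  pdat <- quartet_pattern_data(aln$matrix, aln$alphabet)
  f <- make_quartet_loglik(pdat, perm)
  t5 <- c(branch_lengths[labels[perm]], branch_lengths[["internal"]])
  f(unname(t5))
}

#' @noRd
check_quartet_model <- function(aln, model) {
  if (!inherits(aln, "seq_alignment")) abort("`aln` must be a seq_alignment")
  if (nrow(aln$matrix) != 4L) abort("quartet inference needs exactly 4 rows")
  if (ncol(aln$matrix) < 1L) abort("alignment has no columns")
  if (model == "JC69" && aln$alphabet != "dna")
    abort("JC69 requires a DNA alignment")
  if (model == "PoissonAA" && aln$alphabet != "protein")
    abort("PoissonAA requires a protein alignment")
  invisible(TRUE)
}

#' @noRd
#' Cyclic bounded one-dimensional optimisation of the 5 branch lengths.
optimise_quartet_lengths <- function(f, init = rep(0.05, 5L),
                                     max_len = 10, rel_tol = 1e-8,
                                     max_cycles = 25L, brent_tol = 1e-7) {
  t5 <- init
  best <- f(t5)
  for (cycle in seq_len(max_cycles)) {
    prev <- best
    for (b in 1:5) {
      opt <- optimize(function(x) f(replace(t5, b, x)),
                      c(0, max_len), maximum = TRUE, tol = brent_tol)
      if (opt$objective > best) {
        t5[b] <- opt$maximum
        best <- opt$objective
      }
    }
    if (best - prev <= rel_tol * (abs(prev) + 1e-12)) break
  }
  # snap near-zero optimiser residue on the internal branch
  t5[t5 < 1e-9] <- 0
  list(lengths = t5, logLik = f(t5))
}

#' @noRd
fit_quartet_core <- function(pdat, labels, counts = NULL,
                             tie_tol = 1e-6, max_cycles = 25L,
                             brent_tol = 1e-7) {
  fits <- vector("list", 3L)
  tip_len <- rep(0.05, 4L)  # pendant warm start shared across topologies
  internal0 <- 0.05
  for (ti in 1:3) {
    perm <- QUARTET_PERMS[[ti]]
    f <- make_quartet_loglik(pdat, perm, counts = counts)
    fits[[ti]] <- optimise_quartet_lengths(
      f, init = c(tip_len[perm], internal0),
      max_cycles = max_cycles, brent_tol = brent_tol)
    if (ti == 1L) {
      tip_len[perm] <- fits[[1L]]$lengths[1:4]
      internal0 <- max(fits[[1L]]$lengths[5L], 1e-3)
    }
  }
  lnl <- vapply(fits, `[[`, numeric(1), "logLik")
  names(lnl) <- vapply(QUARTET_PERMS, function(p) split_string(labels, p),
                       character(1))
  ord <- order(lnl, decreasing = TRUE)
  tie <- lnl[ord[1]] - lnl[ord[2]] <= tie_tol
  best <- ord[1]
  perm <- QUARTET_PERMS[[best]]
  bl <- setNames(fits[[best]]$lengths,
                 c(labels[perm], "internal"))[c(labels, "internal")]
  list(split = names(lnl)[best], cherry = sort(labels[perm[1:2]]),
       is_polytomy = tie, branch_lengths = bl,
       logLik = lnl[[best]], lnl_all = lnl)
}

#' Fit a quartet gene tree by exhaustive maximum likelihood
#'
#' Optimises the five branch lengths of each of the three resolved
#' unrooted topologies (bounded one-dimensional search per branch, cycled
#' to convergence, lengths capped at 10 substitutions/site) and selects the
#' topology with the highest likelihood. Exact likelihood ties -- e.g. an
#' alignment with no topology-informative site -- yield a polytomy, never a
#' random tie-break.
#'
#' @param aln A 4-row `seq_alignment` (rows typically labelled by taxon).
#' @param model `"auto"`, `"JC69"` or `"PoissonAA"`.
#' @param tie_tol Log-likelihood difference below which the two best
#'   topologies are declared tied (polytomy).
#' @return A `quartet_fit` object: `topology` (canonical split string or
#'   `"POLYTOMY"`), `cherry`, `branch_lengths` (named, the four pendant
#'   branches plus `internal`), `logLik`, per-topology `lnl_all`,
#'   `support` (bootstrap %, `NA` until [bootstrap_support()] is run).
#' @export
fit_quartet <- function(aln, model = c("auto", "JC69", "PoissonAA"),
                        tie_tol = 1e-6) {
  model <- match.arg(model)
  check_quartet_model(aln, model)
  pdat <- quartet_pattern_data(aln$matrix, aln$alphabet)
  quartet_fit_from_pdat(pdat, aln$labels$label, aln$alphabet, tie_tol)
}

#' @noRd
quartet_fit_from_pdat <- function(pdat, labels, alphabet, tie_tol = 1e-6) {
  core <- fit_quartet_core(pdat, labels, tie_tol = tie_tol)
  structure(
    list(topology = if (core$is_polytomy) "POLYTOMY" else core$split,
         cherry = if (core$is_polytomy) NULL else core$cherry,
         is_polytomy = core$is_polytomy,
         branch_lengths = core$branch_lengths,
         logLik = core$logLik, lnl_all = core$lnl_all,
         support = NA_real_, labels = labels,
         model = if (alphabet == "dna") "JC69" else "PoissonAA",
         n_sites = pdat$n_sites, pdat = pdat, tie_tol = tie_tol),
    class = "quartet_fit")
}

#' @export
print.quartet_fit <- function(x, ...) {
  cat("<quartet_fit>", x$topology, "\n")
  cat(sprintf("  model %s, %d sites, lnL %.4f%s\n", x$model, x$n_sites,
              x$logLik,
              if (!is.na(x$support)) sprintf(", support %.0f%%", x$support)
              else ""))
  invisible(x)
}

#' Bootstrap support for the inferred ingroup pair
#'
#' Resamples alignment columns with replacement `B` times (implemented as a
#' multinomial redraw of site-pattern counts, which is distributionally
#' identical), refits the quartet on each replicate, and reports the
#' percentage of replicates whose maximum-likelihood topology recovers the
#' original cherry. Tied replicates count as non-recovering. Returns `NA`
#' if the original fit is a polytomy.
#'
#' @param fit A `quartet_fit`.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return The fit with `support` set (a percentage in \[0, 100\]).
#' @export
bootstrap_support <- function(fit, B = 100, seed) {
  stopifnot(inherits(fit, "quartet_fit"))
  if (B < 1) abort("`B` must be >= 1")
  check_seed(seed)
  if (fit$is_polytomy) {
    fit$support <- NA_real_
    return(fit)
  }
  pdat <- fit$pdat
  n <- sum(pdat$counts)
  hits <- with_seed(seed, {
    draws <- rmultinom(B, n, pdat$counts / n)
    vapply(seq_len(B), function(b) {
      core <- fit_quartet_core(pdat, fit$labels, counts = draws[, b],
                               tie_tol = fit$tie_tol, max_cycles = 8L,
                               brent_tol = 1e-5)
      !core$is_polytomy && identical(core$cherry, fit$cherry)
    }, logical(1))
  })
  fit$support <- 100 * mean(hits)
  fit
}

#' Collapse short or unsupported internal branches into a polytomy
#'
#' Applies the conservative trimming used before topology classification:
#' an internal branch shorter than `min_length` (substitutions/site), or
#' with bootstrap support below `min_support` when support has been
#' computed, turns the quartet into a polytomy. Pendant branches are never
#' collapsed.
#'
#' @param fit A `quartet_fit`.
#' @param min_length Minimum internal branch length (default 1e-6).
#' @param min_support Minimum bootstrap percentage (default 50).
#' @return The (possibly collapsed) `quartet_fit`.
#' @export
collapse_branches <- function(fit, min_length = 1e-6, min_support = 50) {
  stopifnot(inherits(fit, "quartet_fit"))
  if (min_length < 0 || min_support < 0)
    abort("thresholds must be non-negative")
  if (fit$is_polytomy) return(fit)
  short <- fit$branch_lengths[["internal"]] < min_length
  weak <- !is.na(fit$support) && fit$support < min_support
  if (short || weak) {
    fit$topology <- "POLYTOMY"
    fit$is_polytomy <- TRUE
    fit$cherry <- NULL
    fit$support <- NA_real_
  }
  fit
}

#' Export a fitted quartet as newick
#'
#' @param fit A resolved `quartet_fit` (polytomies export as a star tree).
#' @param digits Branch-length digits.
#' @return A newick string; bootstrap support (if any) labels the internal
#'   node.
#' @export
quartet_newick <- function(fit, digits = 6) {
  stopifnot(inherits(fit, "quartet_fit"))
  bl <- fit$branch_lengths
  fmt <- function(lbl) sprintf("%s:%.*g", lbl, digits, bl[[lbl]])
  if (fit$is_polytomy) {
    return(paste0("(", paste(vapply(fit$labels, fmt, character(1)),
                             collapse = ","), ");"))
  }
  pair1 <- fit$cherry
  pair2 <- setdiff(fit$labels, pair1)
  sup <- if (!is.na(fit$support)) sprintf("%.0f", fit$support) else ""
  sprintf("((%s,%s)%s:%.*g,%s,%s);", fmt(pair1[1]), fmt(pair1[2]), sup,
          digits, bl[["internal"]], fmt(pair2[1]), fmt(pair2[2]))
}
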