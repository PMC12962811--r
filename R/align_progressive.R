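#' @noRd
#' Column-vs-column substitution scores for two profiles (character
#' matrices). Gap residues contribute 0; otherwise the mean pairwise
#' match/mismatch score between the two columns.
profile_scores <- function(pa, pb, match, mismatch) {
  states <- setdiff(unique(c(as.vector(pa), as.vector(pb))), GAP_CHAR)
  fa <- vapply(states, function(s) colSums(pa == s), numeric(ncol(pa)))
  fb <- vapply(states, function(s) colSums(pb == s), numeric(ncol(pb)))
  if (ncol(pa) == 1L) fa <- matrix(fa, nrow = 1L)
  if (ncol(pb) == 1L) fb <- matrix(fb, nrow = 1L)
  n_pairs <- nrow(pa) * nrow(pb)
  same <- fa %*% t(fb)
  tot <- outer(rowSums(fa), rowSums(fb))
  (match * same + mismatch * (tot - same)) / n_pairs
}

#' @noRd
#' Global affine-gap alignment of two profiles; returns the merged profile
#' and the optimal score.
nw_profile_align <- function(pa, pb, gap_open, gap_extend, match, mismatch) {
  la <- ncol(pa); lb <- ncol(pb)
  S <- profile_scores(pa, pb, match, mismatch)
  neg <- -Inf
  M <- matrix(neg, la + 1L, lb + 1L)
  X <- matrix(neg, la + 1L, lb + 1L)  # gap in B (consume A)
  Y <- matrix(neg, la + 1L, lb + 1L)  # gap in A (consume B)
  M[1L, 1L] <- 0
  if (la > 0) X[2:(la + 1L), 1L] <- -gap_open - (seq_len(la) - 1L) * gap_extend
  if (lb > 0) Y[1L, 2:(lb + 1L)] <- -gap_open - (seq_len(lb) - 1L) * gap_extend
  for (i in seq_len(la) + 1L) {
    for (j in seq_len(lb) + 1L) {
      M[i, j] <- S[i - 1L, j - 1L] +
        max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - gap_open, X[i - 1L, j] - gap_extend,
                     Y[i - 1L, j] - gap_open)
      Y[i, j] <- max(M[i, j - 1L] - gap_open, Y[i, j - 1L] - gap_extend,
                     X[i, j - 1L] - gap_open)
    }
  }
  # deterministic traceback, preferring diagonal, then A-consuming, then B
  i <- la + 1L; j <- lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  score <- c(M[i, j], X[i, j], Y[i, j])[state]
  steps <- character(0)
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      steps <- c("both", steps)
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L) {
      steps <- c("A", steps)
      prev <- c(M[i - 1L, j] - gap_open, X[i - 1L, j] - gap_extend,
                Y[i - 1L, j] - gap_open)
      i <- i - 1L
      state <- which.max(prev)
    } else {
      steps <- c("B", steps)
      prev <- c(M[i, j - 1L] - gap_open, X[i, j - 1L] - gap_open,
                Y[i, j - 1L] - gap_extend)
      j <- j - 1L
      state <- which.max(prev)
    }
  }
  na <- nrow(pa); nb <- nrow(pb)
  cols <- lapply(seq_along(steps), function(k) {
    st <- steps[k]
    ii <- sum(steps[seq_len(k)] %in% c("both", "A"))
    jj <- sum(steps[seq_len(k)] %in% c("both", "B"))
    switch(st,
           both = c(pa[, ii], pb[, jj]),
           A = c(pa[, ii], rep(GAP_CHAR, nb)),
           B = c(rep(GAP_CHAR, na), pb[, jj]))
  })
  list(profile = do.call(cbind, cols), score = score)
}

#' Progressive multiple alignment with affine gap costs
#'
#' A deterministic pairwise-to-profile progressive aligner
#' (Needleman--Wunsch with affine gaps) intended for small sets of
#' near-identical orthologs. Sequences are merged in order of decreasing
#' similarity (shared 3-mer counts; ties broken by input order). Synthetic
#' panels are generated already aligned, so this path is only needed for
#' unaligned external input.
#'
#' @param seqs Sequence-set tibble (`label`, `sequence`) or named character
#'   vector; 2--16 sequences over one alphabet.
#' @param gap_open,gap_extend Positive gap opening/extension costs.
#' @param match,mismatch Residue match/mismatch scores.
#' @return A `seq_alignment`; for two sequences the optimal pairwise score
#'   is attached as attribute `"score"`.
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_extend = 1,
                              match = 2, mismatch = -1) {
  if (is.character(seqs)) seqs <- tibble(label = names(seqs) %||%
                                           paste0("seq", seq_along(seqs)),
                                         sequence = unname(seqs))
  n <- nrow(seqs)
  if (n < 2L || n > 16L) abort("progressive_align handles 2-16 sequences")
  if (any(nchar(seqs$sequence) == 0L))
    abort("empty sequence", class = "pq_error_empty_record")
  if (gap_open < 0 || gap_extend < 0) abort("gap costs must be >= 0")
  alphabet <- guess_alphabet(unlist(strsplit(seqs$sequence, "")))
  chars <- strsplit(toupper(seqs$sequence), "")

  kmer_sim <- function(a, b) {
    k <- min(3L, length(a), length(b))
    ka <- table(vapply(seq_len(length(a) - k + 1L), function(i)
      paste(a[i:(i + k - 1L)], collapse = ""), character(1)))
    kb <- table(vapply(seq_len(length(b) - k + 1L), function(i)
      paste(b[i:(i + k - 1L)], collapse = ""), character(1)))
    shared <- intersect(names(ka), names(kb))
    sum(pmin(ka[shared], kb[shared]))
  }
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sim[i, j] <- sim[j, i] <- kmer_sim(chars[[i]], chars[[j]])
  }
  # guide order: most similar pair first, then greedy best-attaching sequence
  start <- which(sim == max(sim), arr.ind = TRUE)[1L, ]
  order_idx <- sort(unname(start))
  remaining <- setdiff(seq_len(n), order_idx)
  while (length(remaining)) {
    best <- remaining[which.max(vapply(remaining, function(r)
      max(sim[r, order_idx]), numeric(1)))]
    order_idx <- c(order_idx, best)
    remaining <- setdiff(remaining, best)
  }

  profile <- matrix(chars[[order_idx[1]]], nrow = 1L)
  members <- order_idx[1]
  score <- NA_real_
  for (idx in order_idx[-1L]) {
    res <- nw_profile_align(profile, matrix(chars[[idx]], nrow = 1L),
                            gap_open, gap_extend, match, mismatch)
    profile <- res$profile
    score <- res$score
    members <- c(members, idx)
  }
  out_seqs <- tibble(
    label = seqs$label[members],
    sequence = apply(profile, 1L, paste, collapse = ""))
  out_seqs <- out_seqs[match(seqs$label, out_seqs$label), ]
  aln <- as_seq_alignment(out_seqs, alphabet = alphabet)
  if (n == 2L) attr(aln, "score") <- score
  aln
}
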