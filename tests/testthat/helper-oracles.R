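# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths.

# Jukes-Cantor transition probability matrix (k states).
oracle_pmat <- function(t, k = 4) {
  e <- exp(-k / (k - 1) * t)
  m <- matrix((1 - e) / k, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

# Quartet likelihood by explicit summation over all internal-state
# assignments (k^2 per site, evaluated as the full matrix sum
# A[u,] * P5[u,v] * B[v,] per column). mat: 4 x L character; topology
# ((1,2),(3,4)); bl: pendant lengths for rows 1-4 then internal.
oracle_quartet_loglik <- function(mat, bl, states) {
  k <- length(states)
  st <- matrix(match(mat, states), nrow = 4)
  P <- lapply(bl, oracle_pmat, k = k)
  L <- ncol(mat)
  cond <- function(tip) {
    cc <- matrix(1, k, L)
    ok <- !is.na(st[tip, ])
    cc[, ok] <- P[[tip]][, st[tip, ok]]
    cc
  }
  A <- cond(1) * cond(2)
  B <- cond(3) * cond(4)
  sum(log(colSums(A * (P[[5]] %*% B)) / k))
}

# Grid-search quartet ML oracle: coarse 5D grid then cyclic fine-grid
# refinement per topology, extending a branch's grid whenever the optimum
# lands on its upper boundary. Returns best topology index and its lnL.
oracle_quartet_grid <- function(aln_mat, states) {
  perms <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  coarse <- c(0.005, 0.03, 0.1, 0.25, 0.6, 1.5)
  best <- lapply(perms, function(perm) {
    m <- aln_mat[perm, , drop = FALSE]
    ll <- function(bl) oracle_quartet_loglik(m, bl, states)
    grid <- as.matrix(expand.grid(coarse, coarse, coarse, coarse, coarse))
    vals <- apply(grid, 1, ll)
    bl <- grid[which.max(vals), ]
    for (pass in 1:3) {
      for (b in 1:5) {
        hi <- 1
        repeat {
          fine <- seq(0, hi, by = 0.01)
          vals <- vapply(fine, function(x) ll(replace(bl, b, x)),
                         numeric(1))
          bl[b] <- fine[which.max(vals)]
          if (bl[b] < hi - 1e-9 || hi >= 8) break
          hi <- hi * 2
        }
      }
    }
    list(lnL = ll(bl), bl = bl)
  })
  lnls <- vapply(best, `[[`, numeric(1), "lnL")
  list(best_topology = which.max(lnls), lnL = max(lnls), all = lnls)
}

# Brute-force pairwise global alignment score with affine gaps, by
# memoised recursion over (i, j, last-move).
oracle_pair_score <- function(a, b, gap_open, gap_extend, match, mismatch) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i == 0 && j == 0) {
      return(if (last == "s") 0 else -Inf)
    }
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- -Inf
    if (last == "d") {
      if (i > 0 && j > 0) {
        s <- if (a[i] == b[j]) match else mismatch
        val <- s + max(rec(i - 1, j - 1, "d"), rec(i - 1, j - 1, "a"),
                       rec(i - 1, j - 1, "b"), rec(i - 1, j - 1, "s"))
      }
    } else if (last == "a") {  # gap in b, consumed a[i]
      if (i > 0) {
        val <- max(rec(i - 1, j, "d") - gap_open,
                   rec(i - 1, j, "a") - gap_extend,
                   rec(i - 1, j, "b") - gap_open,
                   rec(i - 1, j, "s") - gap_open)
      }
    } else if (last == "b") {
      if (j > 0) {
        val <- max(rec(i, j - 1, "d") - gap_open,
                   rec(i, j - 1, "b") - gap_extend,
                   rec(i, j - 1, "a") - gap_open,
                   rec(i, j - 1, "s") - gap_open)
      }
    }
    memo[[key]] <- val
    val
  }
  max(rec(length(a), length(b), "d"), rec(length(a), length(b), "a"),
      rec(length(a), length(b), "b"))
}

# Build a tiny seq_alignment from bare strings.
make_aln <- function(..., labels = NULL, alphabet = NULL) {
  seqs <- c(...)
  labels <- labels %||% paste0("t", seq_along(seqs))
  as_seq_alignment(tibble::tibble(label = labels, sequence = seqs),
                   alphabet = alphabet)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Simulate a DNA alignment of given length directly from a fixed quartet
# tree under JC (independent of the package's codon machinery).
oracle_sim_dna <- function(n_sites, bl, labels = c("a", "b", "c", "d")) {
  states <- c("A", "C", "G", "T")
  P <- lapply(bl, oracle_pmat, k = 4)
  draw <- function(from, pm) {
    vapply(from, function(s) sample.int(4, 1, prob = pm[s, ]), integer(1))
  }
  u <- sample.int(4, n_sites, replace = TRUE)
  v <- draw(u, P[[5]])
  tips <- rbind(draw(u, P[[1]]), draw(u, P[[2]]),
                draw(v, P[[3]]), draw(v, P[[4]]))
  mat <- matrix(states[tips], nrow = 4)
  make_aln(apply(mat, 1, paste, collapse = ""), labels = labels)
}
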