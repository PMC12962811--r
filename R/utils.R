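#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join distinct n desc across all_of count rename pull
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap list_rbind
#' @importFrom stats optimize rexp runif rpois rbinom rmultinom quantile
#'   setNames median cor binom.test sd
#' @importFrom utils head tail write.table read.table
NULL

DNA_STATES <- c("A", "C", "G", "T")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "W", "Y", "V", "T")

#' Number of states in a residue alphabet
#' @param alphabet `"dna"` or `"protein"`.
#' @return 4 or 20.
#' @keywords internal
alphabet_size <- function(alphabet) {
  switch(alphabet, dna = 4L, protein = 20L,
         abort(paste0("unknown alphabet: ", alphabet)))
}

alphabet_states <- function(alphabet) {
  switch(alphabet, dna = DNA_STATES, protein = AA_STATES,
         abort(paste0("unknown alphabet: ", alphabet)))
}

#' Derive deterministic child seeds from a master seed
#'
#' One master seed drives every stochastic stage; substreams for loci,
#' replicates and individuals are derived from it so stages can be re-run
#' independently and reproducibly.
#'
#' @param seed Master integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort("`seed` must be a single finite number")
  invisible(as.integer(seed))
}
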