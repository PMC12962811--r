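#' Define the reference population-tree labelling scheme
#'
#' Classification of a rooted quartet compares its ingroup cherry against
#' the population tree: label `#1` is the cherry expected under the
#' reference tree, `#2` and `#3` the two alternative resolved rooted
#' arrangements, `#4` the uninformative polytomy. The three resolved labels
#' partition the three possible ingroup pairs.
#'
#' @param taxa Four taxon names.
#' @param outgroup The outgroup taxon (used for rooting).
#' @param pair1 Character vector of the two ingroup taxa expected to be
#'   sisters under the population tree (label `#1`).
#' @param pair2,pair3 Optional explicit pairs for labels `#2`/`#3`; by
#'   default the remaining two pairs in order of their first taxon's
#'   position in `taxa`.
#' @return A `reference_topology` object.
#' @examples
#' ref <- reference_topology(c("Homo", "Pan", "Gorilla", "Pongo"),
#'                           outgroup = "Pongo", pair1 = c("Homo", "Pan"))
#' @export
reference_topology <- function(taxa, outgroup, pair1,
                               pair2 = NULL, pair3 = NULL) {
  if (length(taxa) != 4L || anyDuplicated(taxa)) abort("need 4 distinct taxa")
  if (!outgroup %in% taxa) abort("outgroup must be one of `taxa`")
  ingroup <- setdiff(taxa, outgroup)
  if (!all(pair1 %in% ingroup) || length(pair1) != 2L)
    abort("`pair1` must be two ingroup taxa")
  all_pairs <- utils::combn(ingroup, 2L, simplify = FALSE)
  key <- function(p) paste(sort(p), collapse = ",")
  rest <- all_pairs[!vapply(all_pairs, key, character(1)) %in% key(pair1)]
  if (is.null(pair2)) pair2 <- rest[[1]]
  if (is.null(pair3)) pair3 <- rest[[2]]
  pairs <- list(`#1` = sort(pair1), `#2` = sort(pair2), `#3` = sort(pair3))
  if (anyDuplicated(vapply(pairs, key, character(1))) ||
      !setequal(vapply(pairs, key, character(1)),
                vapply(all_pairs, key, character(1))))
    abort("labels #1-#3 must partition the three ingroup pairs")
  structure(list(taxa = taxa, outgroup = outgroup, ingroup = ingroup,
                 pairs = pairs),
            class = "reference_topology")
}

#' @export
print.reference_topology <- function(x, ...) {
  cat("<reference_topology> outgroup:", x$outgroup, "\n")
  for (lab in names(x$pairs))
    cat(sprintf("  %s: (%s)\n", lab, paste(x$pairs[[lab]], collapse = ",")))
  invisible(x)
}

#' Classify a fitted quartet against the reference population tree
#'
#' Roots the quartet on the outgroup pendant edge and maps the resulting
#' ingroup cherry through the reference labelling: `#1` concordant with the
#' population tree, `#2`/`#3` the alternative resolved arrangements, `#4`
#' the polytomy. An outgroup falling inside the inferred cherry is not an
#' error -- rooting on it still leaves a unique ingroup pair on the far
#' side of the internal branch.
#'
#' @param fit A `quartet_fit` (typically after [collapse_branches()]).
#' @param ref A [reference_topology()] sharing the fit's taxon labels.
#' @return One of `"#1"`, `"#2"`, `"#3"`, `"#4"`.
#' @export
classify_quartet <- function(fit, ref) {
  stopifnot(inherits(fit, "quartet_fit"),
            inherits(ref, "reference_topology"))
  if (!setequal(fit$labels, ref$taxa))
    abort("fit and reference must share taxon labels")
  if (fit$is_polytomy) return("#4")
  # the ingroup cherry: the split side without the outgroup
  cherry <- fit$cherry
  if (ref$outgroup %in% cherry)
    cherry <- sort(setdiff(fit$labels, cherry))
  key <- paste(cherry, collapse = ",")
  for (lab in names(ref$pairs))
    if (identical(paste(ref$pairs[[lab]], collapse = ","), key)) return(lab)
  abort("cherry does not match any reference pair")  # unreachable
}
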