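GAP_CHAR <- "-"

#' Read a FASTA file into a sequence set
#'
#' Returns sequences as a tibble (`label`, `sequence`), the tidy currency
#' used throughout the package. Headers using `|`-separated fields (the
#' panel convention `taxon|individual|locus`) can be expanded with
#' [parse_seq_labels()].
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `label` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path),
                                class = "pq_error_missing_file")
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warn("empty FASTA file; returning an empty sequence set")
    return(tibble(label = character(), sequence = character()))
  }
  labels <- names(set)
  seqs <- toupper(as.character(set))
  if (anyDuplicated(labels))
    abort("duplicate FASTA headers", class = "pq_error_duplicate_headers")
  if (any(nchar(seqs) == 0L))
    abort("empty FASTA records", class = "pq_error_empty_record")
  tibble(label = labels, sequence = unname(seqs))
}

#' Write a sequence set to FASTA
#'
#' @param seqs A tibble with `label` and `sequence` columns, or a named
#'   character vector.
#' @param path Output path.
#' @return `path`, invisibly. Round trips losslessly through [read_fasta()].
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- tibble(label = names(seqs),
                                         sequence = unname(seqs))
  stopifnot(all(c("label", "sequence") %in% names(seqs)))
  if (anyDuplicated(seqs$label))
    abort("duplicate sequence labels", class = "pq_error_duplicate_headers")
  set <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$label))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Split `taxon|individual|locus` labels into columns
#'
#' @param seqs Sequence-set tibble with a `label` column.
#' @param fields Names for the `|`-separated header fields, in order.
#' @param sep Field separator (default `|`).
#' @return `seqs` with one extra column per field.
#' @export
parse_seq_labels <- function(seqs, fields = c("taxon", "individual", "locus"),
                             sep = "|") {
  parts <- strsplit(seqs$label, sep, fixed = TRUE)
  bad <- lengths(parts) < length(fields)
  if (any(bad))
    abort(paste0("labels with fewer than ", length(fields), " `", sep,
                 "`-separated fields: ", seqs$label[which(bad)[1]]),
          class = "pq_error_bad_header")
  for (i in seq_along(fields))
    seqs[[fields[i]]] <- vapply(parts, `[[`, character(1), i)
  seqs
}

#' @noRd
guess_alphabet <- function(chars) {
  u <- setdiff(unique(chars), c(GAP_CHAR, "N", "X"))
  if (all(u %in% DNA_STATES)) "dna" else "protein"
}

#' Build an alignment object from equal-length sequences
#'
#' The alignment container holds an equal-length residue matrix (rows =
#' sequences) over a declared alphabet, per-row taxon/individual
#' annotations, and an optional partition map (0-based, half-open column
#' intervals per locus) when the alignment is a concatenation.
#'
#' @param seqs A sequence-set tibble (see [read_fasta()]); optional `taxon`
#'   and `individual` columns annotate rows.
#' @param alphabet `"dna"`, `"protein"`, or `NULL` to guess.
#' @param partitions Optional tibble `locus`, `start`, `end` (0-based,
#'   half-open, disjoint, contiguous, covering all columns).
#' @return A `seq_alignment` object.
#' @export
as_seq_alignment <- function(seqs, alphabet = NULL, partitions = NULL) {
  stopifnot(all(c("label", "sequence") %in% names(seqs)))
  if (nrow(seqs) == 0L) abort("empty sequence set",
                              class = "pq_error_empty_record")
  lens <- nchar(seqs$sequence)
  if (length(unique(lens)) != 1L)
    abort("sequences have unequal lengths; align them first",
          class = "pq_error_unequal_lengths")
  if (lens[1] == 0L) abort("zero-width alignment",
                           class = "pq_error_empty_record")
  mat <- matrix(unlist(strsplit(toupper(seqs$sequence), "")),
                nrow = nrow(seqs), byrow = TRUE)
  rownames(mat) <- seqs$label
  if (is.null(alphabet)) alphabet <- guess_alphabet(as.vector(mat))
  ok <- c(alphabet_states(alphabet), GAP_CHAR, "N", "X")
  stray <- setdiff(unique(as.vector(mat)), ok)
  if (length(stray))
    abort(paste0("residues outside the ", alphabet, " alphabet: ",
                 paste(stray, collapse = " ")),
          class = "pq_error_mixed_alphabet")
  labels <- tibble(
    label = seqs$label,
    taxon = if ("taxon" %in% names(seqs)) seqs$taxon else seqs$label,
    individual = if ("individual" %in% names(seqs)) seqs$individual
                 else rep(NA_character_, nrow(seqs)))
  if (!is.null(partitions)) partitions <- check_partitions(partitions,
                                                           ncol(mat))
  structure(list(labels = labels, matrix = mat, alphabet = alphabet,
                 partitions = partitions),
            class = "seq_alignment")
}

#' @noRd
check_partitions <- function(partitions, width) {
  p <- arrange(as_tibble(partitions), .data$start)
  stopifnot(all(c("locus", "start", "end") %in% names(p)))
  if (any(p$start >= p$end)) abort("empty partition interval")
  if (p$start[1] != 0L || p$end[nrow(p)] != width ||
      (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)])))
    abort("partitions must be disjoint, contiguous and cover all columns")
  p
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d x %d (%s)%s\n", nrow(x$matrix),
              ncol(x$matrix), x$alphabet,
              if (!is.null(x$partitions))
                sprintf(", %d partitions", nrow(x$partitions)) else ""))
  invisible(x)
}

#' @export
dim.seq_alignment <- function(x) dim(x$matrix)

#' Convert an alignment back to a sequence-set tibble
#' @param aln A `seq_alignment`.
#' @return A tibble with `label`, `taxon`, `individual`, `sequence`.
#' @export
as_seq_set <- function(aln) {
  stopifnot(inherits(aln, "seq_alignment"))
  mutate(aln$labels,
         sequence = apply(aln$matrix, 1L, paste, collapse = ""))
}

#' Translate a DNA sequence with the standard genetic code
#'
#' @param dna_sequence A single DNA string (may contain `-`/`N`).
#' @param frame Offset in nucleotides (0, 1 or 2) before the first codon.
#' @param internal_stop `"error"` (default) or `"X"`.
#' @return The amino-acid string; codons containing ambiguity or gaps
#'   translate to `X`, a trailing stop codon is trimmed.
#' @examples
#' translate_dna("ATGGCT")  # "MA"
#' @export
translate_dna <- function(dna_sequence, frame = 0,
                          internal_stop = c("error", "X")) {
  internal_stop <- match.arg(internal_stop)
  stopifnot(length(dna_sequence) == 1L)
  s <- toupper(dna_sequence)
  if (frame > 0) s <- substring(s, frame + 1L)
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L)
    abort("sequence length (after frame offset) must be a positive multiple of 3",
          class = "pq_error_bad_frame")
  ct <- codon_table()
  aa_of <- setNames(ct$aa, ct$codons)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- ifelse(codons %in% ct$codons, unname(aa_of[codons]), "X")
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    if (internal_stop == "error")
      abort("internal stop codon", class = "pq_error_internal_stop")
    aa[aa == "*"] <- "X"
  }
  paste(aa, collapse = "")
}

#' Concatenate locus alignments into a supermatrix
#'
#' Rows are matched by taxon label; every input must contain exactly one
#' row per taxon of the first input (no missing-data padding: a taxon
#' absent from any locus aborts the concatenation). The partition map
#' records each locus's column interval (0-based, half-open).
#'
#' @param alignments Named list of `seq_alignment` objects (names become
#'   partition locus names; unnamed inputs are numbered).
#' @return A `seq_alignment` with `partitions` set.
#' @export
concatenate_alignments <- function(alignments) {
  if (inherits(alignments, "seq_alignment")) alignments <- list(alignments)
  stopifnot(length(alignments) >= 1L)
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    names(alignments) <- paste0("locus", seq_along(alignments))
  taxa <- alignments[[1]]$labels$taxon
  alphabet <- alignments[[1]]$alphabet
  mats <- lapply(seq_along(alignments), function(i) {
    a <- alignments[[i]]
    if (!identical(a$alphabet, alphabet))
      abort("all inputs must share one alphabet",
            class = "pq_error_mixed_alphabet")
    idx <- match(taxa, a$labels$taxon)
    if (anyNA(idx) || nrow(a$matrix) != length(taxa))
      abort(paste0("taxon sets differ at locus ", names(alignments)[i]),
            class = "pq_error_taxon_mismatch")
    a$matrix[idx, , drop = FALSE]
  })
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  partitions <- tibble(locus = names(alignments),
                       start = c(0L, head(ends, -1L)), end = ends)
  mat <- do.call(cbind, mats)
  rownames(mat) <- taxa
  structure(list(labels = tibble(label = taxa, taxon = taxa,
                                 individual = NA_character_),
                 matrix = mat, alphabet = alphabet,
                 partitions = partitions),
            class = "seq_alignment")
}

#' Export a partition map in RAxML style
#'
#' Writes one `locus = start-end` line per partition (1-based inclusive, as
#' RAxML expects, converted from the internal 0-based half-open intervals).
#'
#' @param aln A concatenated `seq_alignment` with partitions.
#' @param path Output file.
#' @export
write_partition_map <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"), !is.null(aln$partitions))
  lines <- sprintf("%s = %d-%d", aln$partitions$locus,
                   aln$partitions$start + 1L, aln$partitions$end)
  writeLines(lines, path)
  invisible(path)
}
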