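#' Validate (and optionally convert) an introgressed-segment table
#'
#' Segments are BED-like records of archaic-introgressed haplotypes: one
#' row per contiguous introgressed tract on one chromosome copy of one
#' individual. Required columns: `individual`, `haplotype` (0/1),
#' `chromosome`, `start`, `end`, `ancestry` (`archaic`, `Neanderthal`,
#' `Denisovan` or `ambiguous`), `panel` (population label), `region`
#' (continental label). Coordinates are 0-based half-open internally;
#' 1-based inclusive input is converted with `one_based = TRUE`.
#'
#' @param segments A data frame of segments.
#' @param one_based Input uses 1-based inclusive coordinates.
#' @return A validated tibble.
#' @export
as_segment_table <- function(segments, one_based = FALSE) {
  seg <- as_tibble(segments)
  need <- c("individual", "haplotype", "chromosome", "start", "end",
            "ancestry", "panel", "region")
  missing_cols <- setdiff(need, names(seg))
  if (length(missing_cols))
    abort(paste0("segment table lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "pq_error_bad_segments")
  if (one_based) seg$start <- seg$start - 1L
  if (any(seg$start >= seg$end))
    abort("malformed intervals: need start < end",
          class = "pq_error_bad_segments")
  if (!all(seg$haplotype %in% c(0L, 1L)))
    abort("haplotype must be 0 or 1", class = "pq_error_bad_segments")
  seg
}

#' Read a segment table from a BED-like TSV
#'
#' @param path TSV with a header row and the columns of
#'   [as_segment_table()].
#' @param one_based Convert from 1-based inclusive coordinates.
#' @export
read_segment_table <- function(path, one_based = FALSE) {
  as_segment_table(read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE),
                   one_based = one_based)
}

#' @noRd
as_gene_interval <- function(gene) {
  g <- as.list(gene)
  stopifnot(all(c("chromosome", "start", "end") %in% names(g)))
  if (g$start >= g$end) abort("malformed gene interval")
  g
}

#' Segments overlapping a gene interval
#'
#' Half-open interval intersection: a segment `[s, e)` overlaps the gene
#' `[gs, ge)` iff `s < ge` and `e > gs` on the same chromosome.
#'
#' @param segments A segment table (see [as_segment_table()]).
#' @param gene A list/one-row data frame with `chromosome`, `start`, `end`
#'   (0-based half-open) and optionally `gene` (name).
#' @return The overlapping subset, same columns.
#' @export
overlapping_segments <- function(segments, gene) {
  seg <- as_segment_table(segments)
  g <- as_gene_interval(gene)
  filter(seg, .data$chromosome == g$chromosome,
         .data$start < g$end, .data$end > g$start)
}

#' Archaic-variant carrier frequency per population panel
#'
#' A chromosome (an `(individual, haplotype)` pair) carries the archaic
#' version of a gene if at least one of its introgressed segments overlaps
#' the gene interval. Frequencies are carriers divided by the panel's
#' chromosome count; the global frequency pools carriers and chromosomes
#' over all panels (the chromosome-weighted mean of panel frequencies).
#' `level = "individual"` counts individuals instead, with
#' `panel_sizes$n` interpreted as individual counts.
#'
#' @param segments A segment table.
#' @param gene Gene interval (see [overlapping_segments()]).
#' @param panel_sizes Tibble `panel`, `n` (chromosomes -- or individuals --
#'   genotyped per panel; all > 0).
#' @param level `"chromosome"` (default) or `"individual"`.
#' @return A tibble `panel`, `carriers`, `n`, `frequency`, with a final
#'   `global` row.
#' @export
archaic_frequency <- function(segments, gene, panel_sizes,
                              level = c("chromosome", "individual")) {
  level <- match.arg(level)
  sizes <- as_tibble(panel_sizes)
  stopifnot(all(c("panel", "n") %in% names(sizes)))
  if (any(sizes$n <= 0)) abort("panel sizes must be positive")
  ov <- overlapping_segments(segments, gene)
  carriers <- if (level == "chromosome")
    distinct(ov, .data$panel, .data$individual, .data$haplotype)
  else distinct(ov, .data$panel, .data$individual)
  per_panel <- carriers |>
    count(.data$panel, name = "carriers") |>
    dplyr::right_join(sizes, by = "panel") |>
    mutate(carriers = tidyr::replace_na(.data$carriers, 0L),
           frequency = .data$carriers / .data$n)
  if (any(per_panel$carriers > per_panel$n))
    abort("more carriers than chromosomes in a panel; check `panel_sizes`")
  global <- tibble(panel = "global",
                   carriers = sum(per_panel$carriers),
                   n = sum(per_panel$n)) |>
    mutate(frequency = .data$carriers / .data$n)
  bind_rows(select(per_panel, "panel", "carriers", "n", "frequency"),
            global)
}

#' Segment report for track-style rendering
#'
#' Rows covering the gene plus a flank, grouped by continental region and
#' sorted by decreasing segment length within region -- the layout used to
#' display introgressed haplotypes stacked over a gene.
#'
#' @param segments A segment table.
#' @param gene Gene interval.
#' @param flank Non-negative flank (bp) added to both sides.
#' @return A tibble with `length` added, sorted by (region, -length).
#' @export
segment_report <- function(segments, gene, flank = 0) {
  if (flank < 0) abort("`flank` must be >= 0")
  g <- as_gene_interval(gene)
  g$start <- max(0, g$start - flank)
  g$end <- g$end + flank
  overlapping_segments(segments, g) |>
    mutate(length = .data$end - .data$start) |>
    arrange(.data$region, desc(.data$length))
}

#' Plant a synthetic introgressed-segment table with known frequencies
#'
#' Generates a segment table in which each panel carries the archaic
#' version of each gene at an exact planted chromosome frequency
#' (`round(frequency * n)` carriers), for testing frequency recovery.
#' Carrier segments span the gene with random jitter; non-carrier
#' chromosomes receive no overlapping segment.
#'
#' @param genes Tibble `gene`, `chromosome`, `start`, `end`.
#' @param panels Tibble `panel`, `region`, `n_individuals` (2 chromosomes
#'   each).
#' @param freq Tibble `gene`, `panel`, `frequency` (planted carrier
#'   frequency per chromosome).
#' @param seed Integer seed.
#' @param ancestry Ancestry label written on planted segments.
#' @return A segment table.
#' @export
simulate_segment_table <- function(genes, panels, freq, seed,
                                   ancestry = "archaic") {
  check_seed(seed)
  genes <- as_tibble(genes); panels <- as_tibble(panels)
  freq <- as_tibble(freq)
  with_seed(seed, {
    rows <- list()
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      for (pi in seq_len(nrow(panels))) {
        p <- panels[pi, ]
        fr <- filter(freq, .data$gene == g$gene, .data$panel == p$panel)
        f <- if (nrow(fr)) fr$frequency[1] else 0
        n_chrom <- 2L * p$n_individuals
        n_carriers <- round(f * n_chrom)
        if (n_carriers == 0L) next
        chroms <- tibble(
          individual = paste0(p$panel, "_ind",
                              rep(seq_len(p$n_individuals), each = 2L)),
          haplotype = rep(0:1, p$n_individuals))
        pick <- chroms[sample.int(n_chrom, n_carriers), ]
        rows[[length(rows) + 1L]] <- tibble(
          individual = pick$individual, haplotype = pick$haplotype,
          chromosome = g$chromosome,
          start = g$start - sample(0:20000, n_carriers, replace = TRUE),
          end = g$end + sample(0:20000, n_carriers, replace = TRUE),
          ancestry = ancestry, panel = p$panel, region = p$region,
          gene = g$gene)
      }
    }
    if (!length(rows))
      return(tibble(individual = character(), haplotype = integer(),
                    chromosome = character(), start = integer(),
                    end = integer(), ancestry = character(),
                    panel = character(), region = character(),
                    gene = character()))
    mutate(list_rbind(rows), start = pmax(.data$start, 0L))
  })
}
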