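#' Default pipeline configuration
#'
#' A nested list mirroring the pipeline stages; any part can be overridden
#' and the whole structure can be stored as YAML. `preset` selects the
#' species-tree preset (`"hominid"` or `"hominin"`).
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, out_dir = "paleoquartet_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(preset = "hominid", individuals_per_taxon = 2L,
                    mu = 0.004),
    score = list(enabled = TRUE, metric = "entropy", reps = 100L),
    iterate = list(enabled = TRUE, n_min = 1L, n_max = NULL, reps = 100L,
                   bootstrap = 0L, min_length = 1e-6, min_support = 50,
                   data_type = "protein"),
    introgression = list(enabled = FALSE, segments = NULL, genes = NULL,
                         panel_sizes = NULL)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the structure of [default_config()]; missing
#'   entries fall back to defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config: ", path))
  user <- yaml::read_yaml(path)
  base <- unclass(default_config())
  merged <- utils::modifyList(base, user)
  structure(merged, class = "run_config")
}

#' Run the simulate / score / iterate / introgression pipeline
#'
#' Validates the configuration, simulates a ground-truth panel, scores
#' conservation, runs the iterative concatenation analysis, optionally
#' overlaps an introgressed-segment table with gene intervals, and writes
#' every stage's tables as TSV plus a JSON manifest recording parameters,
#' seed, package version and file checksums. Existing stage outputs are
#' never silently overwritten.
#'
#' @param config A `run_config` (see [default_config()] /
#'   [read_config()]).
#' @param overwrite Allow writing into a non-empty output directory.
#' @return The manifest (a list), invisibly; outputs under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_config(), overwrite = FALSE) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  seed <- check_seed(config$seed)
  out <- config$out_dir
  # validation before any compute
  intro <- config$introgression
  if (isTRUE(intro$enabled)) {
    for (p in list(intro$segments, intro$genes, intro$panel_sizes))
      if (is.character(p) && !file.exists(p))
        abort(paste0("missing input path: ", p),
              class = "pq_error_missing_file")
  }
  if (dir.exists(out) && length(dir(out)) > 0 && !overwrite)
    abort(paste0("output dir not empty (use overwrite = TRUE): ", out),
          class = "pq_error_would_overwrite")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_line <- function(...) {
    msg <- sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                   paste0(...))
    cat(msg, "\n", sep = "", file = file.path(out, "run.log"), append = TRUE)
  }
  seeds <- derive_seeds(seed, 4L)
  written <- character(0)
  save_tsv <- function(tab, name) {
    path <- file.path(out, name)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  # -- simulate ------------------------------------------------------------
  log_line("simulate: building panel")
  sim <- config$simulate
  spec <- switch(sim$preset,
                 hominid = hominid_tree(),
                 hominin = hominin_tree(),
                 abort(paste0("unknown preset: ", sim$preset)))
  loci <- deep_time_loci(mu = sim$mu)
  panel <- build_panel(spec, loci, sim$individuals_per_taxon, seeds[1])
  panel_dir <- file.path(out, "panel")
  write_panel(panel, panel_dir)
  written <- c(written, file.path(panel_dir, "truth.tsv"))

  results <- list()
  # -- conservation scores -------------------------------------------------
  if (isTRUE(config$score$enabled)) {
    log_line("score: resampled conservation")
    scores <- resampled_scores(panel, metric = config$score$metric,
                               reps = config$score$reps, seed = seeds[2])
    save_tsv(scores, "conservation.tsv")
    ranking <- rank_loci(mutate(scores, data_type = "protein"),
                         normalize = TRUE)
    save_tsv(ranking, "ranking.tsv")
    results$scores <- scores
  }
  # -- iterative analysis --------------------------------------------------
  if (isTRUE(config$iterate$enabled)) {
    it <- config$iterate
    n_max <- it$n_max %||% length(panel_loci(panel))
    log_line("iterate: N=", it$n_min, "..", n_max, " x ", it$reps, " reps")
    ana <- run_analysis(panel, n_range = it$n_min:n_max, reps = it$reps,
                        seed = seeds[3], data_type = it$data_type,
                        B = it$bootstrap, min_length = it$min_length,
                        min_support = it$min_support)
    save_tsv(ana$records, "iteration_records.tsv")
    save_tsv(ana$topology, "topology_frequencies.tsv")
    save_tsv(ana$variants, "variant_stats.tsv")
    if (nrow(ana$support)) save_tsv(ana$support, "support_stats.tsv")
    results$analysis <- ana
  }
  # -- introgression -------------------------------------------------------
  if (isTRUE(intro$enabled)) {
    log_line("introgression: overlap and frequencies")
    segments <- if (is.character(intro$segments))
      read_segment_table(intro$segments) else as_segment_table(intro$segments)
    genes <- if (is.character(intro$genes))
      as_tibble(read.table(intro$genes, sep = "\t", header = TRUE))
    else as_tibble(intro$genes)
    sizes <- if (is.character(intro$panel_sizes))
      as_tibble(read.table(intro$panel_sizes, sep = "\t", header = TRUE))
    else as_tibble(intro$panel_sizes)
    freqs <- list_rbind(lapply(seq_len(nrow(genes)), function(i) {
      mutate(archaic_frequency(segments, genes[i, ], sizes),
             gene = genes$gene[i])
    }))
    save_tsv(freqs, "archaic_frequencies.tsv")
    results$frequencies <- freqs
  }

  manifest <- list(
    package = "paleoquartet",
    version = as.character(utils::packageVersion("paleoquartet")),
    seed = seed,
    config = unclass(config),
    outputs = lapply(setNames(nm = basename(written)), function(b) {
      p <- written[basename(written) == b][1]
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("done")
  invisible(c(results, list(manifest = manifest, panel = panel)))
}
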