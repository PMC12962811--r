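iter_spec <- species_tree(c("A", "B", "C", "O"), t_ab = 2, internal_t = 1.2,
                          t_out = 8)
iter_loci <- function(n = 5, n_codons = 150)
  lapply(seq_len(n), function(i)
    locus_model(paste0("L", i), n_codons, mu = 0.015, omega = 0.5))

test_that("ingroup variant counting excludes outgroup-only variation", {
  aln <- make_aln("AAA", "AAA", "AAR", "CCC",
                  labels = c("h", "p", "g", "o"), alphabet = "protein")
  expect_equal(count_ingroup_variants(aln, "o"), 1L)
  same <- make_aln(rep("ACGT", 4), labels = c("h", "p", "g", "o"))
  expect_equal(count_ingroup_variants(same, "o"), 0L)
  outg_only <- make_aln("A", "A", "A", "G", labels = c("h", "p", "g", "o"))
  expect_equal(count_ingroup_variants(outg_only, "o"), 0L)
  # gaps and ambiguity don't count as states
  gappy <- make_aln("A-", "AX", "RA", "CA",
                    labels = c("h", "p", "g", "o"), alphabet = "protein")
  expect_equal(count_ingroup_variants(gappy, "o"), 1L)
  expect_error(count_ingroup_variants(aln, "nope"), "outgroup")
})

test_that("variant counts are additive over partitions", {
  pan <- build_panel(iter_spec, iter_loci(4), 1, seed = 2)
  alns <- lapply(setNames(nm = panel_loci(pan)),
                 function(l) panel_quartet(pan, l))
  per_locus <- vapply(alns, count_ingroup_variants, numeric(1),
                      outgroup = "O")
  cc <- concatenate_alignments(alns)
  expect_equal(count_ingroup_variants(cc, "O"), sum(per_locus))
})

test_that("boxplot statistics follow the quartile/whisker formulas", {
  expect_equal(boxplot_stats(rep(0, 4))[, c("mean", "median", "q25", "q75")],
               tibble::tibble(mean = 0, median = 0, q25 = 0, q75 = 0))
  # whiskers straight from the caption formula
  x <- c(2, 2, 2, 4, 4, 4)  # q25 = 2, q75 = 4
  st <- boxplot_stats(x)
  expect_equal(st$q25, 2); expect_equal(st$q75, 4)
  expect_equal(st$whisker_lo, 2 - 1.5 * 2)
  expect_equal(st$whisker_hi, 4 + 1.5 * 2)
  # type-7 quantile oracle: sorted linear interpolation at p(n-1)+1
  v <- c(9, 1, 5, 3, 7, 2, 8, 4, 6)
  st2 <- boxplot_stats(v)
  s <- sort(v)
  interp <- function(p) {
    h <- p * (length(s) - 1) + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(st2$q25, interp(0.25))
  expect_equal(st2$median, interp(0.5))
  expect_equal(st2$q75, interp(0.75))
  expect_error(boxplot_stats(numeric(0)), "empty")
})

test_that("an iteration at N = panel size uses every locus", {
  pan <- build_panel(iter_spec, iter_loci(4), 2, seed = 3)
  rec <- run_iteration(pan, 4, seed = 1)
  expect_identical(strsplit(rec$loci_used, ";")[[1]],
                   sort(panel_loci(pan)))
  expect_identical(run_iteration(pan, 2, seed = 5),
                   run_iteration(pan, 2, seed = 5))
  expect_error(run_iteration(pan, 9, seed = 1), "exceeds")
})

test_that("N = 1 labels equal the exhaustive per-locus classification", {
  pan <- build_panel(iter_spec, iter_loci(6), 1, seed = 4)
  ref <- panel_reference(pan)
  oracle <- vapply(setNames(nm = panel_loci(pan)), function(l) {
    fit <- collapse_branches(fit_quartet(panel_quartet(pan, l)))
    classify_quartet(fit, ref)
  }, character(1))
  ana <- run_analysis(pan, n_range = 1, reps = 40, seed = 6)
  expect_identical(ana$records$label,
                   unname(oracle[ana$records$loci_used]))
})

test_that("label counts conserve reps and runs are seed-reproducible", {
  pan <- build_panel(iter_spec, iter_loci(4), 2, seed = 7)
  ana <- run_analysis(pan, n_range = c(1, 3), reps = 15, seed = 8)
  sums <- ana$topology |>
    dplyr::group_by(N) |>
    dplyr::summarise(total = sum(count))
  expect_true(all(sums$total == 15))
  expect_equal(nrow(ana$records), 30)
  ana2 <- run_analysis(pan, n_range = c(1, 3), reps = 15, seed = 8)
  expect_identical(ana$records, ana2$records)
  expect_identical(ana$topology, ana2$topology)
  expect_error(run_analysis(pan, 1, reps = 0, seed = 1), "reps")
})

test_that("per-rep individual drawing reuses one pick across loci", {
  pan <- build_panel(iter_spec, iter_loci(3), 3, seed = 9)
  rec <- run_iteration(pan, 3, seed = 10, individual_draw = "per-rep")
  picks <- vapply(strsplit(rec$individuals_used, ";")[[1]],
                  function(s) sub(".*:", "", s), character(1))
  expect_length(unique(picks), 1L)
})

test_that("support summaries group boot percentages by (N, label)", {
  records <- tibble::tibble(
    N = c(1, 1, 1, 2, 2),
    label = c("#1", "#1", "#4", "#1", "#2"),
    support = c(90, 70, NA, 100, 55))
  tab <- support_summary(records)
  expect_equal(nrow(tab), 3L)  # polytomy excluded
  row11 <- dplyr::filter(tab, N == 1, label == "#1")
  expect_equal(row11$mean, 80)
  expect_equal(row11$n, 2)
  single <- dplyr::filter(tab, N == 2, label == "#2")
  expect_equal(single$median, 55)
  expect_equal(single$min, single$max)
  empty <- support_summary(tibble::tibble(N = 1, label = "#4",
                                          support = NA_real_))
  expect_equal(nrow(empty), 0L)
})

test_that("bootstrap-backed iterations populate support", {
  pan <- build_panel(iter_spec, iter_loci(3, n_codons = 300), 1, seed = 11)
  ana <- run_analysis(pan, n_range = 3, reps = 4, seed = 12, B = 20)
  resolved <- dplyr::filter(ana$records, label != "#4")
  expect_true(all(!is.na(resolved$support)))
  expect_true(all(resolved$support >= 0 & resolved$support <= 100))
  expect_true(all(is.na(dplyr::filter(ana$records, label == "#4")$support)))
})

test_that("filtering out introgressed individuals raises concordance", {
  # reference expects the (A,B) cherry; a pulse from A into C drags
  # carrier C haplotypes toward A, so removing carrier individuals from C
  # should recover the population tree more often at N = max
  adm <- tibble::tibble(source = "A", target = "C", time = 0.02,
                        proportion = 0.35)
  spec <- species_tree(c("A", "B", "C", "O"), t_ab = 1.5, internal_t = 2,
                       t_out = 8,
                       pop_sizes = c(A = 0.05, B = 0.05, C = 0.05, O = 0.1),
                       admixture_events = adm)
  loci <- lapply(1:6, function(i)
    locus_model(paste0("L", i), 300, mu = 0.02, omega = 0.6))
  pan <- build_panel(spec, loci, 6, seed = 4)
  carrier_ids <- unique(dplyr::filter(pan$carriers, introgressed)$individual)
  clean_ids <- setdiff(paste0("ind", 1:6), carrier_ids)
  expect_gt(length(carrier_ids), 0)
  expect_gt(length(clean_ids), 0)
  clean <- filter_panel(pan, list(C = clean_ids))
  ana_all <- run_analysis(pan, n_range = 6, reps = 40, seed = 14)
  ana_clean <- run_analysis(clean, n_range = 6, reps = 40, seed = 14)
  f1 <- function(a) dplyr::filter(a$topology, label == "#1")$frequency
  expect_gt(f1(ana_clean), f1(ana_all))
})
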