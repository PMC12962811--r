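test_that("column entropy matches closed forms", {
  expect_equal(column_entropy(c("A", "A", "A", "A")), 0)
  expect_equal(column_entropy(c("A", "C", "D", "E")), 2)
  expect_equal(column_entropy(c("A", "A", "A", "B")),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(round(column_entropy(c("A", "A", "A", "B")), 4), 0.8113)
  # gap policies
  expect_equal(column_entropy(c("A", "A", "-", "-")), 0)
  expect_equal(column_entropy(c("A", "A", "-", "-"), gap_policy = "as_state"),
               1)
  expect_equal(column_entropy(c("-", "-", "-", "-")), 0)  # undefined -> 0
  expect_equal(column_entropy(c("A", "A", "A", "X")), 0)  # ambiguity excluded
  expect_error(column_entropy(character(0)), "empty")
})

test_that("profile totals equal the independent column-wise oracle", {
  set.seed(8)
  mat <- matrix(sample(c("A", "R", "N", "D", "C"), 4 * 50, TRUE), nrow = 4)
  aln <- make_aln(apply(mat, 1, paste, collapse = ""), alphabet = "protein")
  prof <- profile_entropy(aln, "protein", locus = "toy")
  oracle <- vapply(seq_len(ncol(mat)), function(j) {
    p <- table(mat[, j]) / 4
    -sum(p * log2(p))
  }, numeric(1))
  expect_equal(unname(prof$per_site), oracle)
  expect_equal(prof$total, sum(oracle))
  expect_equal(prof$per_length, sum(oracle) / 50)
  # two-column additivity example
  two <- profile_entropy(make_aln("AA", "CA", "DA", "EA",
                                  alphabet = "protein"), "protein")
  expect_equal(two$total, 2)
  expect_equal(two$per_length, 1)
  # all-identical alignment scores zero
  expect_equal(profile_entropy(make_aln("AAA", "AAA"), "exon")$total, 0)
})

test_that("entropy agrees with bio3d on gap-free alignments", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  mat <- matrix(sample(c("A", "G", "L", "V", "W"), 4 * 25, TRUE), nrow = 4)
  aln <- make_aln(apply(mat, 1, paste, collapse = ""), alphabet = "protein")
  ours <- profile_entropy(aln, "protein")$per_site
  theirs <- bio3d::entropy(mat)$H
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("entropy respects bounds and symmetries", {
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(3:8, 1); L <- sample(5:20, 1)
    mat <- matrix(sample(c("A", "C", "G", "T"), n * L, TRUE), nrow = n)
    aln <- make_aln(apply(mat, 1, paste, collapse = ""))
    prof <- profile_entropy(aln, "exon")
    k_obs <- apply(mat, 2, function(col) length(unique(col)))
    expect_true(all(prof$per_site >= 0))
    expect_true(all(prof$per_site <= log2(pmax(k_obs, 2)) + 1e-12))
    expect_identical(prof$per_site == 0, k_obs == 1)
    # permuting rows changes nothing
    aln_r <- make_aln(apply(mat[sample(n), ], 1, paste, collapse = ""))
    expect_equal(profile_entropy(aln_r, "exon")$per_site, prof$per_site)
    # permuting columns permutes per-site scores, preserving the total
    perm <- sample(L)
    aln_c <- make_aln(apply(mat[, perm, drop = FALSE], 1, paste,
                            collapse = ""))
    prof_c <- profile_entropy(aln_c, "exon")
    expect_equal(unname(prof_c$per_site), unname(prof$per_site[perm]))
    expect_equal(prof_c$total, prof$total)
  }
})

test_that("the codon correction scales the declared side by three", {
  expect_equal(codon_correct(0.30, "exon"), 0.10)
  expect_equal(codon_correct(0.30, "intron_exon"), 0.10)
  expect_equal(codon_correct(0.30, "protein"), 0.30)
  expect_equal(codon_correct(0.30, "protein", "protein"), 0.10)
  expect_equal(codon_correct(0.30, "exon", "protein"), 0.30)
  expect_equal(codon_correct(0, "exon"), 0)
  expect_error(codon_correct(0.3, "rna"))
  expect_error(codon_correct(-1, "exon"))
})

test_that("site rates are flat when invariant and peak on variable sites", {
  tree <- "((a:0.1,b:0.1):0.05,c:0.1,d:0.1);"
  flat <- site_rates(make_aln(rep("AAAA", 4), labels = letters[1:4]),
                     tree, data_type = "exon")
  expect_true(all(flat$per_site == flat$per_site[1]))
  one <- make_aln("AACA", "AACA", "AAAA", "AAAA", labels = letters[1:4])
  prof <- site_rates(one, tree, data_type = "exon")
  expect_equal(which.max(prof$per_site), 3L)
  expect_equal(mean(prof$per_site), 1)
  expect_error(site_rates(one, "((a:1,b:1):1,(c:1,x:1):1);"), "mismatch")
})

test_that("per-site ML rates match a brute-force likelihood grid", {
  bl <- c(0.12, 0.08, 0.15, 0.3, 0.05)
  tree <- sprintf("((a:%g,b:%g):%g,c:%g,d:%g);", bl[1], bl[2], bl[5],
                  bl[3], bl[4])
  # two variable columns with different sharing patterns: their relative
  # rates survive the mean-1 normalisation
  aln <- make_aln("AT", "AT", "GT", "GC", labels = letters[1:4])
  grid <- seq(0, 30, by = 1e-3)
  r_star <- vapply(1:2, function(j) {
    lik <- vapply(grid, function(r)
      oracle_quartet_loglik(aln$matrix[, j, drop = FALSE], r * bl,
                            c("A", "C", "G", "T")), numeric(1))
    grid[which.max(lik)]
  }, numeric(1))
  prof <- site_rates(aln, tree, data_type = "exon")
  expect_equal(mean(prof$per_site), 1)
  expect_equal(prof$per_site[1] / prof$per_site[2],
               r_star[1] / r_star[2], tolerance = 1e-3)
})

test_that("resampling individuals reproduces the exhaustive average", {
  spec <- species_tree(c("A", "B", "C", "O"), t_ab = 2, internal_t = 1,
                       t_out = 8)
  loci <- lapply(1:2, function(i)
    locus_model(paste0("L", i), 80, mu = 0.02, omega = 0.5))
  pan1 <- build_panel(spec, loci, 1, seed = 4)
  # degenerate resampling: one individual per taxon
  rs <- resampled_scores(pan1, reps = 5, seed = 1)
  direct <- profile_entropy(panel_quartet(pan1, "L1"), "protein")
  expect_equal(rs$total[rs$locus == "L1"], direct$total)
  expect_equal(rs$total_se[rs$locus == "L1"], 0)
  # same seed, same answer
  pan2 <- build_panel(spec, loci, 2, seed = 4)
  expect_identical(resampled_scores(pan2, reps = 20, seed = 2),
                   resampled_scores(pan2, reps = 20, seed = 2))
  # 2 individuals/taxon: mean over reps within 3 SE of the 16-combination
  # exhaustive average
  combos <- expand.grid(A = paste0("ind", 1:2), B = paste0("ind", 1:2),
                        C = paste0("ind", 1:2), O = paste0("ind", 1:2),
                        stringsAsFactors = FALSE)
  exact <- mean(vapply(seq_len(nrow(combos)), function(i) {
    pick <- unlist(combos[i, ])
    profile_entropy(panel_quartet(pan2, "L1", individuals = pick),
                    "protein")$total
  }, numeric(1)))
  rs2 <- resampled_scores(pan2, reps = 400, seed = 3)
  row <- rs2[rs2$locus == "L1", ]
  expect_lt(abs(row$total - exact), 3 * row$total_se + 1e-9)
})

test_that("rank order flips between total and per-length scoring", {
  profiles <- tibble::tibble(
    locus = c("LONGCONS", "SHORTVAR", "MID"),
    data_type = "protein",
    total = c(5, 3, 1), per_length = c(5 / 1000, 3 / 100, 1 / 300))
  by_total <- rank_loci(profiles)
  expect_identical(by_total$locus, c("LONGCONS", "SHORTVAR", "MID"))
  by_site <- rank_loci(profiles, normalize = TRUE)
  expect_identical(by_site$locus[1], "SHORTVAR")
  # ties flagged and broken lexicographically
  tied <- rank_loci(tibble::tibble(locus = c("b", "a"),
                                   data_type = "protein",
                                   total = c(1, 1), per_length = c(1, 1)))
  expect_identical(tied$locus, c("a", "b"))
  expect_true(all(tied$tied))
  expect_error(rank_loci(tibble::tibble(locus = c("a", "b"),
                                        data_type = c("protein", "exon"),
                                        total = 1:2, per_length = 1:2)),
               class = "pq_error_mixed_types")
})

test_that("entropy per site correlates with selective constraint", {
  spec <- species_tree(c("A", "B", "C", "O"), t_ab = 3, internal_t = 1.5,
                       t_out = 10)
  omegas <- seq(0.02, 1, length.out = 12)
  loci <- lapply(seq_along(omegas), function(i)
    locus_model(paste0("L", i), 200, mu = 0.015, omega = omegas[i]))
  pan <- build_panel(spec, loci, 1, seed = 21)
  per_len <- vapply(panel_loci(pan), function(l)
    profile_entropy(panel_quartet(pan, l), "protein", l)$per_length,
    numeric(1))
  expect_gt(cor(omegas, per_len, method = "spearman"), 0)
})

test_that("information drops from intron+exon to exon to protein", {
  spec <- species_tree(c("A", "B", "C", "O"), t_ab = 3, internal_t = 1.5,
                       t_out = 10)
  loci <- lapply(1:6, function(i)
    locus_model(paste0("L", i), 150, mu = 0.02, omega = 0.3,
                n_intron_sites = 300))
  pan <- build_panel(spec, loci, 1, seed = 31)
  totals <- vapply(panel_loci(pan), function(l) {
    c(ie = profile_entropy(panel_quartet(pan, l, data_type = "intron_exon"),
                           "intron_exon", l)$total,
      ex = profile_entropy(panel_quartet(pan, l, data_type = "dna"),
                           "exon", l)$total,
      pr = profile_entropy(panel_quartet(pan, l), "protein", l)$total)
  }, numeric(3))
  means <- rowMeans(totals)
  expect_gte(means[["ie"]], means[["ex"]])
  expect_gte(means[["ex"]], means[["pr"]])
  # per-locus the intron+exon superset can never fall below its exon part
  expect_true(all(totals["ie", ] >= totals["ex", ] - 1e-9))
})
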