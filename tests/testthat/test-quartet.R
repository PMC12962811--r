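dna_bl <- c(w = 0.12, x = 0.07, y = 0.2, z = 0.33, internal = 0.09)

test_that("quartet likelihood matches closed forms and enumeration", {
  # invariant column, all branch lengths zero: only the root term survives
  inv <- make_aln("A", "A", "A", "A", labels = c("w", "x", "y", "z"))
  z5 <- setNames(rep(0, 5), c("w", "x", "y", "z", "internal"))
  expect_equal(quartet_log_likelihood(inv, c("w", "x"), z5), log(1 / 4))
  aa <- make_aln("M", "M", "M", "M", labels = c("w", "x", "y", "z"),
                 alphabet = "protein")
  expect_equal(quartet_log_likelihood(aa, c("w", "x"), z5,
                                      model = "PoissonAA"), log(1 / 20))
  # star tree: all three topologies identical
  star <- setNames(c(0.1, 0.1, 0.1, 0.1, 0), names(z5))
  col <- make_aln("A", "C", "A", "C", labels = c("w", "x", "y", "z"))
  lls <- vapply(list(c("w", "x"), c("w", "y"), c("w", "z")), function(tp)
    quartet_log_likelihood(col, tp, star), numeric(1))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-12)
  # toy alignments equal brute-force sums over internal states
  set.seed(4)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T"), 24, TRUE), nrow = 4,
                  dimnames = list(c("w", "x", "y", "z"), NULL))
    aln <- make_aln(apply(mat, 1, paste, collapse = ""),
                    labels = rownames(mat))
    expect_equal(quartet_log_likelihood(aln, c("w", "x"), dna_bl),
                 oracle_quartet_loglik(mat, unname(dna_bl),
                                       c("A", "C", "G", "T")),
                 tolerance = 1e-10)
  }
  # amino-acid enumeration (400 internal-state pairs per site)
  aas <- strsplit("ARNDCQEGHILKMFPSWYVT", "")[[1]]
  mat <- matrix(sample(aas, 12, TRUE), nrow = 4,
                dimnames = list(c("w", "x", "y", "z"), NULL))
  aln <- make_aln(apply(mat, 1, paste, collapse = ""),
                  labels = rownames(mat), alphabet = "protein")
  expect_equal(quartet_log_likelihood(aln, c("w", "x"), dna_bl,
                                      model = "PoissonAA"),
               oracle_quartet_loglik(mat, unname(dna_bl), aas),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting and row order", {
  set.seed(5)
  sim <- oracle_sim_dna(60, c(0.1, 0.12, 0.15, 0.2, 0.35),
                        labels = c("w", "x", "y", "z"))
  mat <- sim$matrix
  mat[1, 1:4] <- "-"  # missing data handled too
  aln <- make_aln(apply(mat, 1, paste, collapse = ""),
                  labels = rownames(mat))
  base <- quartet_log_likelihood(aln, c("w", "x"), dna_bl)
  # the same split named from the other side
  expect_equal(quartet_log_likelihood(aln, c("y", "z"), dna_bl), base)
  # rows permuted
  perm <- c(3, 1, 4, 2)
  aln_p <- make_aln(apply(mat[perm, ], 1, paste, collapse = ""),
                    labels = rownames(mat)[perm])
  expect_equal(quartet_log_likelihood(aln_p, c("w", "x"), dna_bl), base)
  fit <- fit_quartet(aln)
  fit_p <- fit_quartet(aln_p)
  expect_equal(fit$logLik, fit_p$logLik, tolerance = 1e-6)
  expect_identical(fit$topology, fit_p$topology)
  expect_error(quartet_log_likelihood(aln, c("w", "x"),
                                      replace(dna_bl, 1, Inf)), "finite")
})

test_that("JC likelihood agrees with phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(6)
  mat <- matrix(sample(c("A", "C", "G", "T"), 160, TRUE), nrow = 4,
                dimnames = list(c("w", "x", "y", "z"), NULL))
  aln <- make_aln(apply(mat, 1, paste, collapse = ""),
                  labels = rownames(mat))
  tree <- ape::read.tree(
    text = "((w:0.12,x:0.07):0.09,y:0.2,z:0.33);")
  pm <- phangorn::pml(tree, phangorn::phyDat(mat, type = "DNA"),
                      model = "JC")
  expect_equal(quartet_log_likelihood(aln, c("w", "x"), dna_bl),
               pm$logLik, tolerance = 1e-8)
})

test_that("fit recovers obvious topologies and declares honest polytomies", {
  # ingroup pair identical at every site, far from the rest
  aln <- make_aln("AAAAAACCCCGG", "AAAAAACCCCGG",
                  "TTTTTTCCCCAA", "TTTTTTGGGGAA",
                  labels = c("h", "p", "g", "o"))
  fit <- fit_quartet(aln)
  expect_false(fit$is_polytomy)
  expect_identical(fit$cherry, c("h", "p"))
  # all-identical rows cannot prefer a topology
  same <- make_aln(rep("ACGTACGT", 4), labels = c("h", "p", "g", "o"))
  expect_true(fit_quartet(same)$is_polytomy)
  expect_error(fit_quartet(make_aln("AC", "AC", "AC")), "4 rows")
})

test_that("fitted topology and likelihood match the grid-search oracle", {
  set.seed(7)
  bl_true <- c(0.1, 0.12, 0.09, 0.15, 0.4)
  agree <- 0
  for (rep in 1:8) {
    aln <- oracle_sim_dna(20, bl_true)
    fit <- fit_quartet(aln)
    oracle <- oracle_quartet_grid(aln$matrix, c("A", "C", "G", "T"))
    splits <- list(c("a", "b"), c("a", "c"), c("a", "d"))
    if (!fit$is_polytomy) {
      expect_gte(fit$logLik, oracle$lnL - 0.05)
      expect_lte(abs(fit$logLik - oracle$lnL), 0.05)
      if (setequal(fit$cherry, splits[[oracle$best_topology]]) ||
          setequal(setdiff(c("a", "b", "c", "d"), fit$cherry),
                   splits[[oracle$best_topology]]))
        agree <- agree + 1
    }
  }
  expect_gte(agree, 7)
})

test_that("bootstrap support behaves at its limits and is reproducible", {
  # every column a copy of one decisive pattern: support is 100
  decisive <- make_aln(strrep("A", 12), strrep("A", 12),
                       strrep("G", 12), strrep("G", 12),
                       labels = c("h", "p", "g", "o"))
  fit <- bootstrap_support(fit_quartet(decisive), B = 40, seed = 1)
  expect_equal(fit$support, 100)
  # zero variable columns: polytomy, support absent
  flat <- fit_quartet(make_aln(rep("AAAA", 4),
                               labels = c("h", "p", "g", "o")))
  expect_true(flat$is_polytomy)
  expect_true(is.na(bootstrap_support(flat, B = 10, seed = 1)$support))
  # reproducibility
  set.seed(8)
  aln <- oracle_sim_dna(60, c(0.1, 0.1, 0.1, 0.1, 0.15))
  f1 <- bootstrap_support(fit_quartet(aln), B = 30, seed = 9)
  f2 <- bootstrap_support(fit_quartet(aln), B = 30, seed = 9)
  expect_identical(f1$support, f2$support)
  expect_error(bootstrap_support(f1, B = 0, seed = 1), "B")
})

test_that("collapsing turns short or weak internal branches into polytomies", {
  aln <- make_aln("AAAAAACCCC", "AAAAAACCCC", "TTTTTTCCCC", "TTTTTTCCCA",
                  labels = c("h", "p", "g", "o"))
  fit <- fit_quartet(aln)
  expect_false(fit$is_polytomy)
  # healthy branch and support survive
  fit$support <- 99
  kept <- collapse_branches(fit, min_length = 1e-6, min_support = 50)
  expect_false(kept$is_polytomy)
  # tiny internal branch collapses
  short <- fit; short$branch_lengths[["internal"]] <- 1e-9
  expect_true(collapse_branches(short, min_length = 1e-6)$is_polytomy)
  # weak support collapses, and support is dropped with the topology
  weak <- fit; weak$support <- 10
  collapsed <- collapse_branches(weak, min_support = 50)
  expect_true(collapsed$is_polytomy)
  expect_true(is.na(collapsed$support))
  expect_error(collapse_branches(fit, min_length = -1), "non-negative")
})

test_that("classification maps rooted cherries through the reference tree", {
  hominid <- reference_topology(c("Homo", "Pan", "Gorilla", "Pongo"),
                                outgroup = "Pongo",
                                pair1 = c("Homo", "Pan"))
  mk_fit <- function(cherry, labels) {
    structure(list(topology = paste(sort(cherry), collapse = ","),
                   cherry = sort(cherry), is_polytomy = FALSE,
                   labels = labels, support = NA_real_),
              class = "quartet_fit")
  }
  taxa <- c("Homo", "Pan", "Gorilla", "Pongo")
  expect_identical(classify_quartet(mk_fit(c("Homo", "Pan"), taxa),
                                    hominid), "#1")
  expect_identical(classify_quartet(mk_fit(c("Gorilla", "Homo"), taxa),
                                    hominid), "#2")
  expect_identical(classify_quartet(mk_fit(c("Gorilla", "Pan"), taxa),
                                    hominid), "#3")
  # outgroup inside the inferred cherry: rooted on it, the far pair labels
  expect_identical(classify_quartet(mk_fit(c("Homo", "Pongo"), taxa),
                                    hominid), "#3")
  poly <- structure(list(topology = "POLYTOMY", cherry = NULL,
                         is_polytomy = TRUE, labels = taxa,
                         support = NA_real_), class = "quartet_fit")
  expect_identical(classify_quartet(poly, hominid), "#4")
  hominin <- reference_topology(
    c("Neanderthal", "Denisovan", "Sapiens", "Pan"), outgroup = "Pan",
    pair1 = c("Neanderthal", "Denisovan"))
  taxa2 <- c("Neanderthal", "Denisovan", "Sapiens", "Pan")
  expect_identical(classify_quartet(mk_fit(c("Neanderthal", "Denisovan"),
                                           taxa2), hominin), "#1")
  # labels partition the pairs
  expect_error(reference_topology(taxa, "Pongo", c("Homo", "Pan"),
                                  pair2 = c("Homo", "Pan")), "partition")
})

test_that("long sequences recover the true gene-tree topology", {
  spec <- species_tree(c("A", "B", "C", "O"), t_ab = 2, internal_t = 1,
                       t_out = 8)
  loci <- lapply(1:12, function(i)
    locus_model(paste0("L", i), 2000, mu = 0.01, omega = 0.8))
  pan <- build_panel(spec, loci, 1, seed = 13)
  hits_dna <- hits_aa <- 0
  for (l in panel_loci(pan)) {
    cls <- pan$truth$topology_class[pan$truth$locus == l]
    true_pair <- switch(cls, concordant = c("A", "B"),
                        `discordant-A` = c("A", "C"),
                        `discordant-B` = c("B", "C"))
    for (dt in c("dna", "protein")) {
      fit <- fit_quartet(panel_quartet(pan, l, data_type = dt))
      cherry <- fit$cherry
      if (!is.null(cherry) && "O" %in% cherry)
        cherry <- setdiff(c("A", "B", "C", "O"), cherry)
      ok <- !fit$is_polytomy && setequal(cherry, true_pair)
      if (dt == "dna") hits_dna <- hits_dna + ok else hits_aa <- hits_aa + ok
    }
  }
  expect_gte(hits_dna, 11)
  expect_gte(hits_aa, 11)
})

test_that("newick export carries lengths and support", {
  aln <- make_aln("AAAAAACCCC", "AAAAAACCCC", "TTTTTTCCCC", "TTTTTTCCCA",
                  labels = c("h", "p", "g", "o"))
  fit <- bootstrap_support(fit_quartet(aln), B = 10, seed = 2)
  nk <- quartet_newick(fit)
  tr <- ape::read.tree(text = nk)
  expect_setequal(tr$tip.label, c("h", "p", "g", "o"))
  expect_equal(ape::Ntip(tr), 4)
})
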