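#' @noRd
#' Structured Kingman coalescent on the four-population tree.
#'
#' Simulates the genealogy of `n_per_taxon` sampled lineages per taxon under
#' `spec`. Epoch boundaries are the population merges (t_ab, t_abc, t_out)
#' and any admixture pulse times; within an epoch each population coalesces
#' pairs at rate choose(n,2)/N. An admixture pulse (source, target, time, m)
#' reassigns every lineage still in the target population to the source
#' population independently with probability m.
#'
#' Returns a list with the node table (for newick export), per-tip
#' introgression flags, the ingroup cherry (roles), and the A-B reference
#' coalescence time.
sim_genealogy <- function(spec, n_per_taxon) {
  roles <- c("A", "B", "C", "O")
  taxa <- spec$taxa
  role_of <- setNames(roles, taxa)
  n_each <- if (length(n_per_taxon) == 1L) rep(n_per_taxon, 4L) else n_per_taxon
  stopifnot(length(n_each) == 4L, all(n_each >= 1L))
  n_tips <- sum(n_each)

  tip_taxon <- rep(taxa, n_each)
  tip_ind <- unlist(lapply(n_each, seq_len))
  labels <- paste0(tip_taxon, "|ind", tip_ind)

  # node bookkeeping: children + times; tips are 1..n_tips
  max_nodes <- 2L * n_tips
  node_time <- numeric(max_nodes)
  node_left <- integer(max_nodes)
  node_right <- integer(max_nodes)
  next_node <- n_tips + 1L

  active <- seq_len(n_tips)
  pop <- role_of[tip_taxon]
  # tip sets for introgression flags; ref-taxon sets for topology class
  tipsets <- lapply(seq_len(n_tips), identity)
  ref_tip <- setNames(c(1L, 1L + n_each[1], 1L + n_each[1] + n_each[2],
                        1L + n_each[1] + n_each[2] + n_each[3]), roles)
  introgressed_tip <- logical(n_tips)

  t_ab <- spec$split_times[["t_ab"]]
  t_abc <- spec$split_times[["t_abc"]]
  t_out <- spec$split_times[["t_out"]]

  boundaries <- tibble(time = c(t_ab, t_abc, t_out),
                       kind = c("merge_ab", "merge_abc", "merge_out"))
  if (!is.null(spec$admixture_events)) {
    adm <- spec$admixture_events
    boundaries <- bind_rows(
      boundaries,
      tibble(time = adm$time, kind = paste0("admix", seq_len(nrow(adm)))))
  }
  boundaries <- arrange(boundaries, .data$time)
  boundaries <- bind_rows(boundaries, tibble(time = Inf, kind = "end"))

  cherry <- NA_character_
  t_ab_coal <- NA_real_
  tcur <- 0

  merge_pair <- function(i, j, tm) {
    id <- next_node
    node_time[id] <<- tm
    node_left[id] <<- active[i]
    node_right[id] <<- active[j]
    next_node <<- next_node + 1L
    new_set <- c(tipsets[[i]], tipsets[[j]])
    # first merge uniting reference tips of two ingroup taxa fixes the cherry
    if (is.na(cherry)) {
      refs_in <- roles[1:3][vapply(roles[1:3],
        function(r) ref_tip[[r]] %in% new_set, logical(1))]
      refs_l <- roles[1:3][vapply(roles[1:3],
        function(r) ref_tip[[r]] %in% tipsets[[i]], logical(1))]
      refs_r <- roles[1:3][vapply(roles[1:3],
        function(r) ref_tip[[r]] %in% tipsets[[j]], logical(1))]
      if (length(refs_l) >= 1 && length(refs_r) >= 1 && length(refs_in) == 2)
        cherry <<- paste(sort(refs_in), collapse = "")
    }
    if (is.na(t_ab_coal) &&
        ref_tip[["A"]] %in% new_set && ref_tip[["B"]] %in% new_set &&
        (ref_tip[["A"]] %in% tipsets[[i]]) != (ref_tip[["A"]] %in% tipsets[[j]]))
      t_ab_coal <<- tm
    keep <- setdiff(seq_along(active), c(i, j))
    tipsets[keep] -> ts2
    tipsets <<- c(ts2, list(new_set))
    pop <<- c(pop[keep], pop[i])
    active <<- c(active[keep], id)
  }

  for (b in seq_len(nrow(boundaries))) {
    tb <- boundaries$time[b]
    kind <- boundaries$kind[b]
    # coalescence within [tcur, tb)
    repeat {
      if (length(active) == 1L) break
      tab <- table(pop)
      pops_here <- names(tab)[tab >= 2]
      if (length(pops_here) == 0L) { tcur <- tb; break }
      rates <- vapply(pops_here, function(p) {
        np <- tab[[p]]
        np * (np - 1) / 2 / spec$pop_sizes[[p]]
      }, numeric(1))
      total <- sum(rates)
      w <- rexp(1L, total)
      if (tcur + w >= tb) { tcur <- tb; break }
      tcur <- tcur + w
      p <- sample(pops_here, 1L, prob = rates)
      idx <- which(pop == p)
      pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
      merge_pair(pair[1L], pair[2L], tcur)
    }
    if (length(active) == 1L && tb == Inf) break
    # boundary action
    if (kind == "merge_ab") {
      pop[pop %in% c("A", "B")] <- "AB"
    } else if (kind == "merge_abc") {
      pop[pop %in% c("AB", "C")] <- "ABC"
    } else if (kind == "merge_out") {
      pop[pop %in% c("ABC", "O")] <- "ABCO"
    } else if (startsWith(kind, "admix")) {
      ev <- spec$admixture_events[as.integer(sub("admix", "", kind)), ]
      tgt_pop <- role_of[[ev$target]]
      src_pop <- role_of[[ev$source]]
      hit <- which(pop == tgt_pop & runif(length(pop)) < ev$proportion)
      if (length(hit)) {
        pop[hit] <- src_pop
        for (i in hit) introgressed_tip[tipsets[[i]]] <- TRUE
      }
    }
  }

  list(root = active[1L], node_time = node_time, node_left = node_left,
       node_right = node_right, n_tips = n_tips, labels = labels,
       tip_taxon = tip_taxon, tip_ind = tip_ind,
       introgressed_tip = introgressed_tip,
       cherry = cherry, t_ab_coal = t_ab_coal, t_abc = t_abc)
}

#' @noRd
genealogy_newick <- function(g) {
  rec <- function(id) {
    if (id <= g$n_tips) return(g$labels[id])
    l <- g$node_left[id]; r <- g$node_right[id]
    bl <- g$node_time[id] - if (l <= g$n_tips) 0 else g$node_time[l]
    br <- g$node_time[id] - if (r <= g$n_tips) 0 else g$node_time[r]
    sprintf("(%s:%.8g,%s:%.8g)", rec(l), bl, rec(r), br)
  }
  paste0(rec(g$root), ";")
}

#' @noRd
genealogy_phylo <- function(g) {
  ape::read.tree(text = genealogy_newick(g))
}

cherry_to_class <- c(AB = "concordant", AC = "discordant-A",
                     BC = "discordant-B")

#' Simulate gene trees under the multispecies coalescent
#'
#' Draws locus genealogies (one sampled lineage per taxon) under a
#' four-taxon species tree, records the realised rooted ingroup topology
#' relative to the population tree, whether incomplete lineage sorting
#' occurred (the A and B lineages failed to coalesce before the end of their
#' first shared ancestral branch), and whether any lineage was reassigned by
#' an admixture pulse.
#'
#' @param spec A [species_tree()] specification.
#' @param n Number of independent gene trees to draw.
#' @param seed Integer seed.
#' @return A tibble with one row per locus: `newick` (rooted, branch lengths
#'   in coalescent units), `topology_class` (`concordant`, `discordant-A`
#'   with the A--C cherry, or `discordant-B` with the B--C cherry),
#'   `ils_flag`, `introgressed_flag`.
#' @examples
#' spec <- species_tree(c("A","B","C","O"), t_ab = 1, internal_t = 1, t_out = 5)
#' trees <- simulate_gene_trees(spec, n = 100, seed = 1)
#' mean(trees$topology_class != "concordant")  # ~ (2/3) exp(-1)
#' @export
simulate_gene_trees <- function(spec, n, seed) {
  if (!inherits(spec, "species_tree_spec"))
    abort("`spec` must be a species_tree_spec")
  check_seed(seed)
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1")
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- sim_genealogy(spec, 1L)
      rows[[i]] <- tibble(
        locus = paste0("locus", i),
        newick = genealogy_newick(g),
        topology_class = cherry_to_class[[g$cherry]],
        ils_flag = is.na(g$t_ab_coal) || g$t_ab_coal > g$t_abc,
        introgressed_flag = any(g$introgressed_tip))
    }
    list_rbind(rows)
  })
}

#' @rdname simulate_gene_trees
#' @export
simulate_gene_tree <- function(spec, seed) {
  simulate_gene_trees(spec, 1L, seed)
}
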