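# Seeded synthetic data: Yule trees and matching taxon-record tables.
#
# The generator emulates the substrate of the real analysis — a large rooted
# 16S reference tree of type strains (~8,000 leaves) of which roughly 13%
# already carry a genome project — so every pipeline stage can be exercised
# at full scale without any download. Yule (pure-birth) trees are used
# because the analysis consumes only topology and branch lengths and the
# Yule process has an analytically known expected total length,
# E[total] = (n - 1) / birth_rate, which anchors the simulator's own tests.

#' Simulation specification
#'
#' Defaults describe the study conditions of the KMG-I selection: a tree of
#' 8,029 type strains; about 13% of strains with a registered genome project
#' (7% with sequence data available, the rest ongoing); a small fraction
#' failing the growth screen; 33 phyla. `birth_rate` is in events per unit
#' branch length (the time scale is arbitrary; coverage fractions are
#' invariant under rescaling).
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth_rate Yule splitting rate per lineage (> 0).
#' @param seed Integer seed; every random draw is a pure function of it.
#' @param frac_sequenced Probability a leaf has a completed genome project.
#' @param frac_ongoing Probability of an ongoing project
#'   (`frac_sequenced + frac_ongoing <= 1`).
#' @param frac_nongrowable Probability a leaf fails the growth screen.
#' @param n_phyla Number of monophyletic phylum groups to cut the tree into.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_leaves = 8029, birth_rate = 1, seed = 1,
                            frac_sequenced = 0.07, frac_ongoing = 0.06,
                            frac_nongrowable = 0.05, n_phyla = 33) {
  n_leaves <- as.integer(n_leaves)
  n_phyla <- as.integer(n_phyla)
  if (is.na(n_leaves) || n_leaves < 2L) {
    pd_stop("pdselect_validation_error", "n_leaves must be >= 2")
  }
  if (!is.finite(birth_rate) || birth_rate <= 0) {
    pd_stop("pdselect_validation_error", "birth_rate must be > 0")
  }
  probs <- c(frac_sequenced, frac_ongoing, frac_nongrowable)
  if (any(probs < 0 | probs > 1) || frac_sequenced + frac_ongoing > 1) {
    pd_stop("pdselect_validation_error",
            "fractions must lie in [0,1] with frac_sequenced + frac_ongoing <= 1")
  }
  if (is.na(n_phyla) || n_phyla < 1L) {
    pd_stop("pdselect_validation_error", "n_phyla must be >= 1")
  }
  structure(list(n_leaves = n_leaves, birth_rate = birth_rate,
                 seed = as.integer(seed), frac_sequenced = frac_sequenced,
                 frac_ongoing = frac_ongoing,
                 frac_nongrowable = frac_nongrowable, n_phyla = n_phyla),
            class = "simulation_spec")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Grows a rooted binary tree from two lineages: while `m` lineages are
#' extant the next split arrives after an Exp(`m * birth_rate`) wait and
#' hits a uniformly chosen lineage. Growth stops when `n_leaves` lineages
#' exist, plus one final Exp(`n * birth_rate`) interval so pendant edges of
#' the last split are not systematically zero. Branch lengths are the
#' inter-event exposure times; leaf labels are `T000001`, ... in lineage
#' creation order. Fully determined by `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A `phylo` object with `n_leaves` tips.
#' @export
simulate_yule_tree <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_leaves
  lambda <- spec$birth_rate
  with_seed(spec$seed, {
    n_nodes <- 2L * n - 1L
    parent <- integer(n_nodes)
    birth <- numeric(n_nodes)
    is_leaf <- rep(TRUE, n_nodes)
    # node 1 = root, born at time 0 with two children
    next_id <- 1L
    root <- next_id; next_id <- next_id + 1L
    is_leaf[root] <- FALSE
    lineages <- integer(n)
    c1 <- next_id; next_id <- next_id + 1L
    c2 <- next_id; next_id <- next_id + 1L
    parent[c(c1, c2)] <- root
    lineages[1:2] <- c(c1, c2)
    m <- 2L
    t <- 0
    while (m < n) {
      t <- t + stats::rexp(1, m * lambda)
      j <- sample.int(m, 1L)
      v <- lineages[j]
      is_leaf[v] <- FALSE
      a <- next_id; next_id <- next_id + 1L
      b <- next_id; next_id <- next_id + 1L
      parent[c(a, b)] <- v
      birth[c(a, b)] <- t
      lineages[j] <- a
      m <- m + 1L
      lineages[m] <- b
    }
    t_end <- t + stats::rexp(1, m * lambda)
    elen <- numeric(n_nodes)
    for (v in seq(2L, n_nodes)) {
      elen[v] <- if (is_leaf[v]) t_end - birth[v] else NA
    }
    # internal nodes: edge ends when the node itself splits (= birth of its
    # children); recover from any child's birth time
    child_birth <- numeric(n_nodes)
    child_birth[parent[-1L]] <- birth[-1L]
    internal <- which(!is_leaf)
    elen[internal] <- child_birth[internal] - birth[internal]

    # renumber to ape convention: tips 1..n, internals n+1..2n-1, root n+1
    leaf_ids <- which(is_leaf)
    int_ids <- c(root, setdiff(internal, root))
    new_id <- integer(n_nodes)
    new_id[leaf_ids] <- seq_len(n)
    new_id[int_ids] <- n + seq_along(int_ids)
    nonroot <- seq(2L, n_nodes)
    edge <- cbind(new_id[parent[nonroot]], new_id[nonroot])
    phy <- structure(list(edge = edge,
                          edge.length = elen[nonroot],
                          tip.label = sprintf("T%06d", seq_len(n)),
                          Nnode = n - 1L),
                     class = "phylo")
    ape::reorder.phylo(phy, "cladewise")
  })
}

#' Assign phyla and genome/growability statuses to a simulated tree
#'
#' Phyla are monophyletic: the tree is cut into `n_phyla` clades by
#' repeatedly splitting the group with the most leaves (largest-first), so
#' per-phylum PD summaries remain interpretable. Genome status is drawn
#' independently per leaf (`complete` with `frac_sequenced`, `ongoing` with
#' `frac_ongoing`, otherwise `none`); growability with
#' `1 - frac_nongrowable`. All leaves are type strains with themselves as
#' the typified species. Deterministic given `spec$seed` (a sub-seed
#' decorrelated from the tree draws is used).
#'
#' @param tree A `phylo` object (typically from [simulate_yule_tree()]).
#' @param spec A [simulation_spec()].
#' @return A validated record data frame, one row per leaf in tip order.
#' @export
assign_records <- function(tree, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  idx <- tree_index(tree)
  n <- idx$n_tips
  if (spec$n_phyla > n) {
    pd_stop("pdselect_validation_error",
            "n_phyla (%d) exceeds the number of leaves (%d)", spec$n_phyla, n)
  }
  nl <- leaves_below(idx)
  kids <- vector("list", idx$n_nodes)
  for (i in seq_len(nrow(idx$tree$edge))) {
    p <- idx$tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], idx$tree$edge[i, 2])
  }
  groups <- idx$root
  while (length(groups) < spec$n_phyla) {
    splittable <- groups[groups > n]
    g <- splittable[which.max(nl[splittable])]
    groups <- c(setdiff(groups, g), kids[[g]])
  }
  phylum <- character(n)
  groups <- groups[order(-nl[groups], groups)]  # stable naming: largest first
  for (i in seq_along(groups)) {
    phylum[clade_tips(idx, groups[i])] <- sprintf("P%02d", i)
  }
  labels <- idx$labels
  with_seed(child_seed(spec$seed, 2L), {
    u <- stats::runif(n)
    status <- ifelse(u < spec$frac_sequenced, "complete",
                     ifelse(u < spec$frac_sequenced + spec$frac_ongoing,
                            "ongoing", "none"))
    growable <- stats::runif(n) >= spec$frac_nongrowable
    validate_records(data.frame(
      taxon_name = labels,
      phylum = phylum,
      species_or_subspecies_id = labels,
      is_type_strain = TRUE,
      genome_status = status,
      genome_is_type = status != "none",
      growable = growable,
      proposed = FALSE,
      stringsAsFactors = FALSE
    ))
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper returning a tree and matching record table from one
#' specification.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `tree` and `records`.
#' @export
simulate_dataset <- function(spec) {
  tree <- simulate_yule_tree(spec)
  list(tree = tree, records = assign_records(tree, spec))
}
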