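# Phylogenetic diversity of taxon subsets.
#
# Two conventions are supported:
#   rooted   - sum of branch lengths on all root-to-member paths (Faith's PD
#              with the root always retained); pd of a single taxon is its
#              root distance.
#   unrooted - sum of branch lengths of the minimal connected subgraph
#              spanning the members; pd of a single taxon is 0.
# Both are computed by growing a spanning subtree one taxon at a time; the
# rooted convention is the unrooted one with the root preseeded into the
# subtree, so a single engine serves both (and greedy selection reuses it).

pd_mode_arg <- function(mode) match.arg(mode, c("rooted", "unrooted"))

# Incremental spanning-subtree engine. `gain(x)` is the branch length that
# adding tip x would contribute; `add(x)` commits it. `topnode` is the
# shallowest node of the current subtree; paths from tips outside its clade
# go up past it, hence the ldepth correction on the topnode's root path.
new_pd_engine <- function(idx, mode) {
  insub <- logical(idx$n_nodes)
  ontop <- logical(idx$n_nodes)   # topnode and its ancestors
  topnode <- 0L
  if (mode == "rooted") {
    topnode <- idx$root
    insub[topnode] <- TRUE
    ontop[topnode] <- TRUE
  }
  gain <- function(x) {
    if (topnode == 0L) return(0)
    s <- 0
    v <- x
    repeat {
      if (insub[v]) return(s)
      if (ontop[v]) return(s + idx$ldepth[topnode] - idx$ldepth[v])
      s <- s + idx$elen[v]
      v <- idx$parent[v]
    }
  }
  add <- function(x) {
    if (topnode == 0L) {
      insub[x] <<- TRUE
      topnode <<- x
      v <- x
      repeat {
        ontop[v] <<- TRUE
        if (v == idx$root) break
        v <- idx$parent[v]
      }
      return(0)
    }
    s <- 0
    v <- x
    while (!insub[v] && !ontop[v]) {
      insub[v] <<- TRUE
      s <- s + idx$elen[v]
      v <- idx$parent[v]
    }
    if (!insub[v]) {
      # met the topnode's root path above the subtree: splice in the
      # segment from the old topnode up to the meeting point
      s <- s + idx$ldepth[topnode] - idx$ldepth[v]
      w <- topnode
      while (w != v) {
        w <- idx$parent[w]
        insub[w] <<- TRUE
      }
      topnode <<- v
    }
    s
  }
  environment()
}

#' Phylogenetic diversity of a taxon set
#'
#' @param tree A `phylo` object with branch lengths.
#' @param taxa Character vector of leaf labels (may be empty).
#' @param mode `"rooted"` (sum of branch lengths on all root-to-member
#'   paths; the default everywhere in this package) or `"unrooted"` (sum of
#'   branch lengths of the minimal spanning subgraph; 0 for fewer than two
#'   taxa).
#' @return A non-negative number; `pd(tree, leaf_labels(tree))` equals
#'   [total_branch_length()] in both modes.
#' @examples
#' tr <- read_newick("((A:1,B:2):1,(C:3,D:1):2);")
#' pd(tr, "C")                      # 5 (root path 2 + 3)
#' pd(tr, c("A", "C"), "unrooted")  # 7
#' @export
pd <- function(tree, taxa, mode = c("rooted", "unrooted")) {
  mode <- pd_mode_arg(mode)
  taxa <- unique(trimws(as.character(taxa)))
  if (length(taxa) == 0L) return(0)
  idx <- tree_index(tree)
  ids <- match_taxa(idx, taxa)
  eng <- new_pd_engine(idx, mode)
  s <- 0
  for (v in ids) s <- s + eng$add(v)
  s
}

#' Unique PD contribution of one taxon
#'
#' The PD lost if the taxon were dropped from the tree:
#' `pd(all leaves) - pd(all leaves minus taxon)`. In rooted mode this is the
#' taxon's pendant branch length (its ancestors are always shared with other
#' leaves once out-degree-1 nodes are collapsed); in unrooted mode a leaf
#' attached directly to a two-child root additionally owns its sibling
#' clade's stem edge.
#'
#' @inheritParams pd
#' @param taxon A single leaf label.
#' @return A non-negative number.
#' @export
unique_contribution <- function(tree, taxon, mode = c("rooted", "unrooted")) {
  mode <- pd_mode_arg(mode)
  stopifnot(length(taxon) == 1L)
  idx <- tree_index(tree)
  match_taxa(idx, taxon)
  rest <- setdiff(idx$labels, trimws(taxon))
  pd(tree, idx$labels, mode) - pd(tree, rest, mode)
}

#' Unique PD contributions of all leaves
#'
#' Closed-form equivalent of calling [unique_contribution()] on every leaf
#' (linear in tree size instead of quadratic). The `relative` column divides
#' by the total branch length, giving the score as a fraction of total PD.
#'
#' @inheritParams pd
#' @return A data frame with columns `taxon`, `contribution`, `relative`,
#'   ordered lexicographically by taxon.
#' @export
pd_contributions <- function(tree, mode = c("rooted", "unrooted")) {
  mode <- pd_mode_arg(mode)
  idx <- tree_index(tree)
  tips <- seq_len(idx$n_tips)
  contrib <- idx$elen[tips]
  if (mode == "unrooted") {
    root_kids <- idx$tree$edge[idx$tree$edge[, 1] == idx$root, 2]
    if (length(root_kids) == 2L) {
      for (i in 1:2) {
        x <- root_kids[i]
        if (x <= idx$n_tips) {
          contrib[x] <- contrib[x] + idx$elen[root_kids[3L - i]]
        }
      }
    }
  }
  total <- total_branch_length(tree)
  ord <- order(idx$labels, method = "radix")
  data.frame(taxon = idx$labels[ord],
             contribution = contrib[ord],
             relative = if (total > 0) contrib[ord] / total else 0,
             stringsAsFactors = FALSE)
}

#' PD coverage of named taxon sets
#'
#' For each named set, reports its PD and the fraction of the tree's total
#' PD it covers — the quantity used to state how much of the known
#' phylogenetic diversity a list of sequencing targets would capture.
#'
#' @inheritParams pd
#' @param named_sets Named list of character vectors of leaf labels.
#' @return An object of class `pd_coverage`: a list with `total_pd`, `mode`,
#'   and `sets` (data frame with columns `set`, `pd`, `fraction`).
#' @examples
#' tr <- read_newick("((A:1,B:2):1,(C:3,D:1):2);")
#' pd_coverage(tr, list(seq = "C", combined = c("C", "B")))
#' @export
pd_coverage <- function(tree, named_sets, mode = c("rooted", "unrooted")) {
  mode <- pd_mode_arg(mode)
  if (is.null(tree) || length(tree$tip.label) == 0L) {
    pd_stop("pdselect_validation_error", "empty tree")
  }
  if (length(named_sets) && (is.null(names(named_sets)) ||
                             any(!nzchar(names(named_sets))))) {
    pd_stop("pdselect_validation_error", "every taxon set must be named")
  }
  total <- total_branch_length(tree)
  pds <- vapply(named_sets, function(s) pd(tree, s, mode), numeric(1))
  out <- list(total_pd = total, mode = mode,
              sets = data.frame(set = names(named_sets),
                                pd = unname(pds),
                                fraction = if (total > 0) unname(pds) / total
                                           else rep(0, length(pds)),
                                stringsAsFactors = FALSE))
  class(out) <- "pd_coverage"
  out
}

#' @export
print.pd_coverage <- function(x, ...) {
  cat(sprintf("PD coverage (%s mode), total PD = %s\n", x$mode,
              format(x$total_pd, digits = 6)))
  df <- x$sets
  if (nrow(df)) {
    df$fraction <- sprintf("%.1f%%", 100 * df$fraction)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
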