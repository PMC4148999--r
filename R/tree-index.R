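# Internal traversal index shared by all PD code.
#
# ape's edge matrix is convenient for vectorized work but awkward for the
# repeated leaf-to-root walks greedy selection needs, so we flatten it once
# into parent/edge-length/depth vectors indexed by ape node id
# (tips 1..n, internals n+1..n+Nnode, root = n+1 after reordering).

tree_index <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tips <- length(tree$tip.label)
  n_nodes <- n_tips + tree$Nnode
  parent <- integer(n_nodes)           # 0 for the root
  elen <- numeric(n_nodes)             # length of the edge above each node
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  if (!is.null(tree$edge.length)) elen[tree$edge[, 2]] <- tree$edge.length
  root <- n_tips + 1L
  # depth in edges (for LCA walks) and in length units (for unrooted PD)
  ndepth <- integer(n_nodes)
  ldepth <- numeric(n_nodes)
  for (i in seq_len(nrow(tree$edge))) {  # cladewise: parents precede children
    p <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    ndepth[v] <- ndepth[p] + 1L
    ldepth[v] <- ldepth[p] + elen[v]
  }
  tip_of <- match(tree$tip.label, tree$tip.label)  # identity, kept for clarity
  list(tree = tree, n_tips = n_tips, n_nodes = n_nodes, root = root,
       parent = parent, elen = elen, ndepth = ndepth, ldepth = ldepth,
       labels = tree$tip.label)
}

# Node ids in postorder (every child before its parent).
postorder_nodes <- function(idx) {
  edge <- ape::reorder.phylo(idx$tree, "postorder")$edge
  c(edge[, 2][!duplicated(edge[, 2])], idx$root)
}

# Lowest common ancestor of two nodes by parent walking.
lca_pair <- function(idx, a, b) {
  while (idx$ndepth[a] > idx$ndepth[b]) a <- idx$parent[a]
  while (idx$ndepth[b] > idx$ndepth[a]) b <- idx$parent[b]
  while (a != b) { a <- idx$parent[a]; b <- idx$parent[b] }
  a
}

lca_set <- function(idx, nodes) {
  v <- nodes[1]
  for (w in nodes[-1]) v <- lca_pair(idx, v, w)
  v
}

# Map taxon names to tip ids, failing loudly on unknown names.
match_taxa <- function(idx, taxa) {
  taxa <- trimws(taxa)
  ids <- match(taxa, idx$labels)
  if (anyNA(ids)) {
    pd_stop("pdselect_taxon_error", "unknown taxon name(s): %s",
            paste(taxa[is.na(ids)], collapse = ", "))
  }
  ids
}

# Number of leaves below each node (a leaf counts itself).
leaves_below <- function(idx) {
  nl <- integer(idx$n_nodes)
  nl[seq_len(idx$n_tips)] <- 1L
  for (v in postorder_nodes(idx)) {
    if (v != idx$root) nl[idx$parent[v]] <- nl[idx$parent[v]] + nl[v]
  }
  nl
}

# Tip ids contained in the clade rooted at `node`.
clade_tips <- function(idx, node) {
  if (node <= idx$n_tips) return(node)
  kids <- vector("list", idx$n_nodes)
  for (i in seq_len(nrow(idx$tree$edge))) {
    p <- idx$tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], idx$tree$edge[i, 2])
  }
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= idx$n_tips) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  out
}
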