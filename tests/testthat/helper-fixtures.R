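# Shared fixtures and independent oracles.

# Worked 4-leaf quartet used throughout: total branch length 10,
# rooted PD({C}) = 5, unrooted PD({A,C}) = 7, optimal pair {B,C} with PD 8.
quartet_newick <- "((A:1,B:2):1,(C:3,D:1):2);"
quartet_tree <- function() read_newick(quartet_newick)

star_tree <- function(n, len = 1) {
  read_newick(paste0(
    "(", paste(sprintf("L%03d:%s", seq_len(n), format(len)), collapse = ","),
    ");"
  ))
}

small_yule <- function(n, seed) {
  simulate_yule_tree(simulation_spec(n_leaves = n, seed = seed, n_phyla = 1))
}

# Independent PD oracle: enumerate root-to-tip paths with ape::nodepath and
# take the union of edges (never touches the package's engine).
oracle_pd <- function(tree, taxa, mode = "rooted") {
  if (length(taxa) == 0) return(0)
  tips <- match(taxa, tree$tip.label)
  stopifnot(!anyNA(tips))
  root <- length(tree$tip.label) + 1L
  ukey <- function(a, b) paste(pmin(a, b), pmax(a, b))  # undirected edge key
  edge_tab <- ukey(tree$edge[, 1], tree$edge[, 2])
  path_edges <- function(p) ukey(p[-length(p)], p[-1])
  if (mode == "rooted") {
    keys <- unique(unlist(lapply(tips, function(t) {
      path_edges(ape::nodepath(tree, root, t))
    })))
  } else {
    if (length(tips) < 2) return(0)
    keys <- unique(unlist(lapply(utils::combn(tips, 2, simplify = FALSE),
                                 function(pr) {
                                   path_edges(ape::nodepath(tree, pr[1], pr[2]))
                                 })))
  }
  sum(tree$edge.length[match(keys, edge_tab)])
}

# Seeded evaluation that restores the caller's RNG state.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

make_records <- function(taxa, phylum = "P01", status = "none",
                         is_type = TRUE, growable = TRUE, proposed = FALSE) {
  data.frame(taxon_name = taxa, phylum = phylum,
             species_or_subspecies_id = taxa,
             is_type_strain = is_type, genome_status = status,
             genome_is_type = status != "none" & is_type,
             growable = growable, proposed = proposed,
             stringsAsFactors = FALSE)
}
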