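# Greedy PD-maximizing taxon selection, plus an exhaustive oracle.
#
# On rooted trees the stepwise choice of the largest marginal PD gain is
# provably optimal at every step; on unrooted trees it is optimal provided
# the run is seeded with an endpoint of a maximum-distance leaf pair (the
# farthest leaf from any starting point is such an endpoint, so a two-sweep
# suffices). Selection over thousands of leaves uses lazy re-evaluation:
# marginal gains can only shrink as the covered subtree grows, so cached
# gains are upper bounds and only the current maximum ever needs
# recomputation.

#' Greedy PD-maximizing selection
#'
#' Iteratively selects, among the eligible leaves, the taxon with the
#' largest marginal PD gain given the preselected set plus everything chosen
#' so far. Ties are broken lexicographically by taxon name, so runs are
#' reproducible across platforms. Already-sequenced taxa are passed as
#' `preselected`: their PD counts as covered (it appears in
#' `preselected_pd` and in every `cumulative_pd`) but they consume no
#' selection slots. Taxa failing eligibility screens are passed as
#' `excluded` and are ignored entirely.
#'
#' @inheritParams pd
#' @param k Number of taxa to select.
#' @param preselected,excluded Character vectors of leaf labels; must be
#'   disjoint.
#' @return An object of class `pd_selection`: a list with `steps` (data
#'   frame `taxon`, `marginal_gain`, `cumulative_pd`), `preselected_pd`,
#'   `total_pd`, and `mode`. `cumulative_pd` includes `preselected_pd`, so
#'   the last row divided by `total_pd` is the covered fraction.
#' @examples
#' tr <- read_newick("((A:1,B:2):1,(C:3,D:1):2);")
#' greedy_select(tr, k = 2)$steps  # C then B, cumulative PD 5 then 8
#' @export
greedy_select <- function(tree, k, preselected = character(),
                          excluded = character(),
                          mode = c("rooted", "unrooted")) {
  mode <- pd_mode_arg(mode)
  k <- as.integer(k)
  if (is.na(k) || k < 0L) pd_stop("pdselect_validation_error", "k must be >= 0")
  idx <- tree_index(tree)
  preselected <- unique(trimws(as.character(preselected)))
  excluded <- unique(trimws(as.character(excluded)))
  both <- intersect(preselected, excluded)
  if (length(both)) {
    pd_stop("pdselect_validation_error",
            "taxa both preselected and excluded: %s",
            paste(both, collapse = ", "))
  }
  pre_ids <- if (length(preselected)) match_taxa(idx, preselected) else integer(0)
  if (length(excluded)) match_taxa(idx, excluded)
  pool <- setdiff(idx$labels, c(preselected, excluded))
  pool <- sort(pool, method = "radix")
  if (k > length(pool)) {
    pd_stop("pdselect_validation_error",
            "k = %d exceeds the eligible pool of %d leaves", k, length(pool))
  }
  eng <- new_pd_engine(idx, mode)
  pre_pd <- 0
  for (v in pre_ids) pre_pd <- pre_pd + eng$add(v)

  taxa <- character(k); gains <- numeric(k)
  cum <- pre_pd
  step <- 0L
  pool_ids <- match(pool, idx$labels)

  if (k >= 1L && mode == "unrooted" && eng$topnode == 0L) {
    # seed with a diameter endpoint: the farthest eligible leaf from the
    # lexicographically first eligible leaf (all singleton PDs are 0, so
    # any diameter endpoint is an optimal first pick)
    a <- pool_ids[1]
    d <- vapply(pool_ids, function(x) {
      idx$ldepth[a] + idx$ldepth[x] - 2 * idx$ldepth[lca_pair(idx, a, x)]
    }, numeric(1))
    i <- which(d == max(d))[1]   # pool is lex-sorted, so first max is lex-min
    step <- 1L
    taxa[1] <- pool[i]; gains[1] <- 0
    eng$add(pool_ids[i])
    pool <- pool[-i]; pool_ids <- pool_ids[-i]
  }

  if (step < k) {
    g <- vapply(pool_ids, eng$gain, numeric(1))
    fresh <- rep(TRUE, length(g))
    while (step < k) {
      repeat {
        i <- which(g == max(g))[1]
        if (fresh[i]) break
        g[i] <- eng$gain(pool_ids[i])
        fresh[i] <- TRUE
      }
      step <- step + 1L
      taxa[step] <- pool[i]
      gains[step] <- eng$add(pool_ids[i])
      cum <- cum + gains[step]
      pool <- pool[-i]; pool_ids <- pool_ids[-i]
      g <- g[-i]; fresh <- fresh[-i]
      fresh[] <- FALSE
    }
  }

  steps <- data.frame(taxon = taxa, marginal_gain = gains,
                      cumulative_pd = pre_pd + cumsum(gains),
                      stringsAsFactors = FALSE)
  out <- list(steps = steps, preselected_pd = pre_pd,
              total_pd = total_branch_length(tree), mode = mode)
  class(out) <- "pd_selection"
  out
}

#' @export
print.pd_selection <- function(x, ...) {
  n <- nrow(x$steps)
  cat(sprintf("Greedy PD selection (%s mode): %d taxa\n", x$mode, n))
  cat(sprintf("  preselected PD: %s  total tree PD: %s\n",
              format(x$preselected_pd, digits = 6),
              format(x$total_pd, digits = 6)))
  if (n) {
    last <- x$steps$cumulative_pd[n]
    cat(sprintf("  final cumulative PD: %s (%.1f%% of total)\n",
                format(last, digits = 6), 100 * last / x$total_pd))
    print(utils::head(x$steps, 10), row.names = FALSE)
    if (n > 10) cat(sprintf("  ... %d more steps\n", n - 10))
  }
  invisible(x)
}

#' Exhaustive PD-optimal subset (verification oracle)
#'
#' Enumerates every k-subset of the eligible leaves and returns one
#' maximizing `pd(subset + preselected)`. Intended as an independent check
#' of [greedy_select()] on small instances; refuses pools larger than 20
#' leaves. Ties resolve to the lexicographically smallest subset.
#'
#' @inheritParams greedy_select
#' @return A list with `taxa` (character vector, sorted) and `pd` (the PD of
#'   `taxa` plus `preselected`).
#' @export
brute_force_select <- function(tree, k, preselected = character(),
                               excluded = character(),
                               mode = c("rooted", "unrooted")) {
  mode <- pd_mode_arg(mode)
  k <- as.integer(k)
  idx <- tree_index(tree)
  preselected <- unique(trimws(as.character(preselected)))
  excluded <- unique(trimws(as.character(excluded)))
  both <- intersect(preselected, excluded)
  if (length(both)) {
    pd_stop("pdselect_validation_error",
            "taxa both preselected and excluded: %s",
            paste(both, collapse = ", "))
  }
  pool <- sort(setdiff(idx$labels, c(preselected, excluded)), method = "radix")
  if (length(pool) > 20L) {
    pd_stop("pdselect_validation_error",
            "refusing exhaustive enumeration over %d eligible leaves (max 20)",
            length(pool))
  }
  if (k > length(pool)) {
    pd_stop("pdselect_validation_error",
            "k = %d exceeds the eligible pool of %d leaves", k, length(pool))
  }
  if (k == 0L) {
    return(list(taxa = character(0), pd = pd(tree, preselected, mode)))
  }
  best <- -Inf
  best_set <- NULL
  subsets <- utils::combn(pool, k, simplify = FALSE)  # lex order
  for (s in subsets) {
    v <- pd(tree, c(preselected, s), mode)
    if (v > best) {  # strict: first (lex-smallest) maximizer wins
      best <- v
      best_set <- s
    }
  }
  list(taxa = best_set, pd = best)
}
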