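# Newick input/output with strict validation.
#
# Trees are stored as ape "phylo" objects; every reader in this package
# guarantees on return: a single root of out-degree >= 2, no out-degree-1
# internal nodes, finite non-negative branch lengths on every edge, and
# unique non-empty leaf labels. All PD arithmetic relies on these
# invariants.

pd_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "pdselect_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Scan a newick string for structural errors before handing it to the
# parser, so malformed input is reported with a character offset.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  quote_char <- ""
  semi_at <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (quote_char != "") {
      if (ch == quote_char) quote_char <- ""
      next
    }
    if (semi_at > 0L && !grepl("^\\s$", ch)) {
      pd_stop("pdselect_parse_error",
              "newick parse error at character %d: content after ';'", i)
    }
    if (ch == "'" || ch == "\"") {
      quote_char <- ch
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        pd_stop("pdselect_parse_error",
                "newick parse error at character %d: unmatched ')'", i)
      }
    } else if (ch == ";") {
      if (depth > 0L) {
        pd_stop("pdselect_parse_error",
                "newick parse error at character %d: ';' inside %d unclosed '('",
                i, depth)
      }
      semi_at <- i
    }
  }
  if (quote_char != "") {
    pd_stop("pdselect_parse_error",
            "newick parse error at character %d: unterminated quoted label",
            length(chars) + 1L)
  }
  if (semi_at == 0L) {
    pd_stop("pdselect_parse_error",
            "newick parse error at character %d: missing terminating ';'",
            length(chars) + 1L)
  }
  invisible(TRUE)
}

# ape's reader chokes on quoted labels containing metacharacters or escaped
# quotes, so quoted tokens are swapped for plain placeholders before parsing
# and restored on the resulting labels afterwards.
QUOTED_TOKEN_RE <- "'(?:[^']|'')*'|\"[^\"]*\""

protect_quoted <- function(text) {
  m <- gregexpr(QUOTED_TOKEN_RE, text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  if (length(toks) == 0L) return(list(text = text, vals = character(0)))
  vals <- unquote_label(toks)
  regmatches(text, m) <- list(sprintf("PDQTOKEN%06d", seq_along(vals)))
  list(text = text, vals = vals)
}

restore_quoted <- function(labels, vals) {
  if (length(vals) == 0L) return(labels)
  i <- match(labels, sprintf("PDQTOKEN%06d", seq_along(vals)))
  ifelse(is.na(i), labels, vals[i])
}

# Strip one layer of newick quoting and surrounding whitespace from a label.
unquote_label <- function(x) {
  x <- trimws(x)
  sq <- nchar(x) >= 2 & startsWith(x, "'") & endsWith(x, "'")
  x[sq] <- gsub("''", "'", substr(x[sq], 2L, nchar(x[sq]) - 1L), fixed = TRUE)
  dq <- nchar(x) >= 2 & startsWith(x, "\"") & endsWith(x, "\"")
  x[dq] <- substr(x[dq], 2L, nchar(x[dq]) - 1L)
  trimws(x)
}

validate_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) {
    pd_stop("pdselect_parse_error", "newick parse error: unreadable tree")
  }
  ntip <- length(phy$tip.label)
  if (ntip < 2L || is.null(phy$edge) || nrow(phy$edge) < 2L) {
    pd_stop("pdselect_validation_error",
            "invalid tree: fewer than 2 leaves (root out-degree < 2)")
  }
  if (is.null(phy$edge.length)) {
    pd_stop("pdselect_validation_error",
            "invalid tree: branch lengths are missing; PD requires computed branch lengths")
  }
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length))) {
    pd_stop("pdselect_validation_error",
            "invalid tree: %d edge(s) have missing or non-finite branch lengths",
            sum(!is.finite(phy$edge.length)))
  }
  if (any(phy$edge.length < 0)) {
    pd_stop("pdselect_validation_error",
            "invalid tree: negative branch length (%g)",
            min(phy$edge.length))
  }
  phy$tip.label <- unquote_label(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unquote_label(phy$node.label)
  if (any(phy$tip.label == "")) {
    pd_stop("pdselect_validation_error", "invalid tree: empty leaf label")
  }
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup)) {
    pd_stop("pdselect_validation_error",
            "invalid tree: duplicate leaf label(s): %s",
            paste(dup, collapse = ", "))
  }
  # out-degree-1 internal nodes carry no information for PD; merge their
  # edges (lengths are summed, so all path lengths are preserved)
  outdeg <- tabulate(phy$edge[, 1], nbins = ntip + phy$Nnode)
  root <- ntip + 1L
  if (outdeg[root] < 2L) {
    pd_stop("pdselect_validation_error",
            "invalid tree: root out-degree %d < 2", outdeg[root])
  }
  if (any(outdeg[-seq_len(ntip)] == 1L)) {
    phy <- ape::collapse.singles(phy)
  }
  phy$root.edge <- NULL
  phy
}

#' Read and validate a phylogenetic tree in newick format
#'
#' Parses a single rooted newick statement (multifurcations allowed) and
#' enforces the invariants all PD computations in this package assume:
#' every edge carries a finite, non-negative branch length, leaf labels are
#' unique and non-empty, and the root has out-degree at least two. Trees
#' without branch lengths are rejected rather than defaulted: phylogenetic
#' diversity is meaningless without them, and a silent default of 1.0 would
#' corrupt every downstream score. Quoted labels (single or double quotes)
#' are unquoted; underscores in unquoted labels are kept literal.
#' Out-degree-1 internal nodes are collapsed (their edge lengths summed),
#' which leaves every leaf-to-leaf and root-to-leaf path length unchanged.
#'
#' @param text A newick string terminated by `;`.
#' @param file Path to a newick file (used when `text` is `NULL`).
#' @return An object of class `phylo` satisfying the invariants above.
#' @examples
#' tr <- read_newick("((A:1,B:2):1,(C:3,D:1):2);")
#' total_branch_length(tr)  # 10
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either `text` or `file`")
    if (!file.exists(file)) {
      pd_stop("pdselect_io_error", "tree file not found: %s", file)
    }
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  text <- trimws(text)
  if (!nzchar(text)) {
    pd_stop("pdselect_parse_error",
            "newick parse error at character 1: empty input")
  }
  check_newick_syntax(text)
  prot <- protect_quoted(text)
  text <- prot$text
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) {
    pd_stop("pdselect_parse_error", "newick parse error: %s",
            substr(text, 1L, 60L))
  }
  if (inherits(phy, "multiPhylo")) {
    pd_stop("pdselect_parse_error",
            "newick parse error: expected a single tree, got %d", length(phy))
  }
  if (length(prot$vals) && inherits(phy, "phylo")) {
    phy$tip.label <- restore_quoted(phy$tip.label, prot$vals)
    if (!is.null(phy$node.label)) {
      phy$node.label <- restore_quoted(phy$node.label, prot$vals)
    }
  }
  validate_phylo(phy)
}

needs_quoting <- function(x) grepl("[][ \t(),:;'\"]", x)

quote_label <- function(x) {
  q <- needs_quoting(x)
  x[q] <- paste0("'", gsub("'", "''", x[q], fixed = TRUE), "'")
  x
}

format_len <- function(x) {
  out <- formatC(x, digits = 15, format = "g", flag = "-")
  trimws(out)
}

#' Serialize a tree to newick
#'
#' Writes branch lengths at full double precision (15 significant digits)
#' and quotes labels containing newick metacharacters or whitespace, so
#' that `read_newick(write_newick(tr))` reproduces the tree exactly.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  idx <- tree_index(tree)
  n_all <- idx$n_nodes
  # children in original edge order, composed bottom-up (no recursion, so
  # caterpillar trees of any depth are fine)
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  labs <- character(n_all)
  labs[seq_len(idx$n_tips)] <- quote_label(tree$tip.label)
  str <- character(n_all)
  po <- postorder_nodes(idx)
  for (v in po) {
    if (v <= idx$n_tips) {
      str[v] <- labs[v]
    } else {
      str[v] <- paste0("(", paste(str[kids[[v]]], collapse = ","), ")")
    }
    if (v != idx$root) {
      str[v] <- paste0(str[v], ":", format_len(idx$elen[v]))
    }
  }
  out <- paste0(str[idx$root], ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Total branch length of a tree
#'
#' The sum of all branch lengths; this is the PD of the complete leaf set
#' and the denominator of every coverage fraction.
#'
#' @param tree A `phylo` object.
#' @return A non-negative number.
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) {
    pd_stop("pdselect_validation_error", "tree has no branch lengths")
  }
  sum(tree$edge.length)
}

#' Leaf labels in deterministic order
#'
#' @param tree A `phylo` object.
#' @return Character vector of leaf labels, sorted lexicographically
#'   (byte order, locale-independent).
#' @export
leaf_labels <- function(tree) {
  sort(tree$tip.label, method = "radix")
}
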