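# End-to-end target selection: join tree with records, screen candidates,
# run greedy selection for primary and backup lists, report coverage.

#' Selection configuration
#'
#' Defaults mirror the KMG-I study design: 1,000 prime targets augmented by
#' 685 backups, type strains only, growable strains only, with taxa whose
#' genome projects are already registered (ongoing or complete) treated as
#' covered diversity rather than candidates.
#'
#' @param n_primary Number of prime targets (>= 1).
#' @param n_backup Number of backup targets (>= 0); the backup list is the
#'   continuation of the same greedy run, i.e. the next-best scorers that
#'   substitute for primaries that fail downstream.
#' @param pd_mode `"rooted"` or `"unrooted"` (see [pd()]).
#' @param require_type_strain Drop non-type strains from eligibility.
#' @param require_growable Drop strains flagged non-growable.
#' @param exclude_statuses Genome statuses that preselect a taxon (its PD
#'   counts as already covered); subset of `c("ongoing", "complete")`.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_primary = 1000, n_backup = 685,
                             pd_mode = c("rooted", "unrooted"),
                             require_type_strain = TRUE,
                             require_growable = TRUE,
                             exclude_statuses = c("ongoing", "complete")) {
  pd_mode <- match.arg(pd_mode)
  n_primary <- as.integer(n_primary)
  n_backup <- as.integer(n_backup)
  if (is.na(n_primary) || n_primary < 1L) {
    pd_stop("pdselect_validation_error", "n_primary must be >= 1")
  }
  if (is.na(n_backup) || n_backup < 0L) {
    pd_stop("pdselect_validation_error", "n_backup must be >= 0")
  }
  if (!all(exclude_statuses %in% c("ongoing", "complete"))) {
    pd_stop("pdselect_validation_error",
            "exclude_statuses must be a subset of ongoing/complete")
  }
  structure(list(n_primary = n_primary, n_backup = n_backup,
                 pd_mode = pd_mode,
                 require_type_strain = isTRUE(require_type_strain),
                 require_growable = isTRUE(require_growable),
                 exclude_statuses = unique(exclude_statuses)),
            class = "selection_config")
}

#' Join a tree with a record table
#'
#' Exact string match (after trimming surrounding whitespace) between leaf
#' labels and `taxon_name`. Nothing is dropped silently: leaves without a
#' record and records without a leaf are returned for inspection. When a
#' strain has several nomenclature rows, the first is used.
#'
#' @param tree A `phylo` object.
#' @param records A validated record data frame.
#' @return A list with `matched` (records re-keyed to leaf labels, one row
#'   per matched leaf), `unmatched_leaves`, `unmatched_records` (character
#'   vectors of labels / taxon names).
#' @export
join_tree_records <- function(tree, records) {
  records <- validate_records(records)
  recs <- records[!duplicated(records$taxon_name), , drop = FALSE]
  leaves <- trimws(tree$tip.label)
  m <- match(leaves, recs$taxon_name)
  matched <- recs[m[!is.na(m)], , drop = FALSE]
  matched$taxon_name <- leaves[!is.na(m)]
  rownames(matched) <- NULL
  list(matched = matched,
       unmatched_leaves = leaves[is.na(m)],
       unmatched_records = setdiff(recs$taxon_name, leaves))
}

#' Screen matched leaves into preselected / eligible / excluded
#'
#' Taxa whose genome project status falls in `exclude_statuses` become the
#' preselected set: their diversity is already covered, so they are kept on
#' the tree and in every coverage number but consume no target slots. Of the
#' rest, non-type strains and non-growable strains (when the corresponding
#' screens are on) are excluded with a named reason; the remainder is the
#' eligible candidate pool.
#'
#' @param matched The `matched` element of [join_tree_records()].
#' @param config A [selection_config()].
#' @return A list with `eligible` and `preselected` (character vectors) and
#'   `excluded` (named character vector: reason by taxon).
#' @export
filter_candidates <- function(matched, config) {
  if (nrow(matched) == 0L) {
    pd_stop("pdselect_validation_error", "no matched taxa to screen")
  }
  pre <- matched$genome_status %in% config$exclude_statuses
  reason <- rep(NA_character_, nrow(matched))
  if (config$require_type_strain) {
    reason[!pre & is.na(reason) & !matched$is_type_strain] <- "not-type-strain"
  }
  if (config$require_growable) {
    reason[!pre & is.na(reason) & !matched$growable] <- "non-growable"
  }
  eligible <- matched$taxon_name[!pre & is.na(reason)]
  if (length(eligible) == 0L) {
    pd_stop("pdselect_validation_error",
            "eligible candidate pool is empty after screening")
  }
  excl <- stats::setNames(reason[!is.na(reason)],
                          matched$taxon_name[!is.na(reason)])
  list(eligible = eligible,
       preselected = matched$taxon_name[pre],
       excluded = excl)
}

#' Run the full target-selection pipeline
#'
#' Joins the tree with the records, screens candidates, runs one greedy
#' PD-maximizing selection of `n_primary + n_backup` steps, and splits it
#' into the primary list and its greedy continuation (the backups). Leaves
#' without a record stay on the tree — they contribute to total PD, i.e. to
#' every coverage denominator — but are never selected.
#'
#' @param tree A `phylo` object.
#' @param records A validated record data frame.
#' @param config A [selection_config()].
#' @return A list of class `pd_run` with elements `primary` and `backup`
#'   (both `pd_selection`), `coverage` (a `pd_coverage` over the preselected
#'   set, preselected + primary, preselected + primary + backup, and all
#'   matched type strains), `join`, `screen`, and `config`.
#' @export
run_selection <- function(tree, records, config = selection_config()) {
  join <- join_tree_records(tree, records)
  screen <- filter_candidates(join$matched, config)
  k <- config$n_primary + config$n_backup
  if (k > length(screen$eligible)) {
    pd_stop("pdselect_validation_error",
            "requested %d targets but only %d eligible leaves (shortfall %d)",
            k, length(screen$eligible), k - length(screen$eligible))
  }
  excluded_all <- c(names(screen$excluded), join$unmatched_leaves)
  sel <- greedy_select(tree, k, preselected = screen$preselected,
                       excluded = excluded_all, mode = config$pd_mode)
  primary <- sel
  primary$steps <- sel$steps[seq_len(config$n_primary), , drop = FALSE]
  backup <- sel
  backup$steps <- sel$steps[setdiff(seq_len(k), seq_len(config$n_primary)), ,
                            drop = FALSE]
  rownames(backup$steps) <- NULL
  backup$preselected_pd <-
    if (config$n_primary > 0) sel$steps$cumulative_pd[config$n_primary]
    else sel$preselected_pd
  type_strains <- join$matched$taxon_name[join$matched$is_type_strain]
  sets <- list(
    preselected = screen$preselected,
    preselected_plus_primary = c(screen$preselected, primary$steps$taxon),
    preselected_plus_primary_plus_backup =
      c(screen$preselected, sel$steps$taxon),
    all_matched_type_strains = type_strains
  )
  coverage <- pd_coverage(tree, sets, mode = config$pd_mode)
  out <- list(primary = primary, backup = backup, coverage = coverage,
              join = join, screen = screen, config = config)
  class(out) <- "pd_run"
  out
}

#' @export
print.pd_run <- function(x, ...) {
  cat(sprintf("PD target selection: %d primary + %d backup (%s mode)\n",
              nrow(x$primary$steps), nrow(x$backup$steps), x$config$pd_mode))
  cat(sprintf("  eligible %d | preselected %d | excluded %d | unmatched leaves %d\n",
              length(x$screen$eligible), length(x$screen$preselected),
              length(x$screen$excluded), length(x$join$unmatched_leaves)))
  print(x$coverage)
  invisible(x)
}

#' Write a selection result as TSV
#'
#' Columns: `taxon`, `rank`, `marginal_gain`, `cumulative_pd`,
#' `cumulative_fraction`, at full numeric precision.
#'
#' @param sel A `pd_selection`.
#' @param path Output path.
#' @param rank_offset Added to the step index (backups continue the primary
#'   ranking).
#' @return The path, invisibly.
#' @export
write_selection <- function(sel, path, rank_offset = 0L) {
  df <- data.frame(taxon = sel$steps$taxon,
                   rank = seq_len(nrow(sel$steps)) + as.integer(rank_offset),
                   marginal_gain = sel$steps$marginal_gain,
                   cumulative_pd = sel$steps$cumulative_pd,
                   cumulative_fraction = sel$steps$cumulative_pd / sel$total_pd,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a coverage report as JSON
#'
#' @param coverage A `pd_coverage`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_coverage_json <- function(coverage, path) {
  obj <- list(mode = coverage$mode, total_pd = coverage$total_pd,
              sets = coverage$sets)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
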