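# Taxonomy ledger: per-strain nomenclature/genome-status records and their
# per-phylum roll-up.
#
# One record is one validly named species or subspecies together with the
# strain that typifies it. Several records may share a strain (homotypic
# synonyms, new combinations, coordinate-status names all attach to the same
# type strain), which is why species/subspecies counts exceed type-strain
# counts and is exactly what the percent-synonyms column measures.

RECORD_COLUMNS <- c("taxon_name", "phylum", "species_or_subspecies_id",
                    "is_type_strain", "genome_status", "genome_is_type",
                    "growable", "proposed")
GENOME_STATUSES <- c("none", "ongoing", "complete")

parse_flag <- function(x, col, rows) {
  v <- toupper(trimws(x))
  ok <- v %in% c("TRUE", "FALSE", "1", "0")
  if (any(!ok)) {
    pd_stop("pdselect_schema_error",
            "row %d: invalid %s value '%s' (expected TRUE/FALSE)",
            rows[which(!ok)[1]], col, x[which(!ok)[1]])
  }
  v %in% c("TRUE", "1")
}

validate_records <- function(df) {
  missing <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing)) {
    pd_stop("pdselect_schema_error", "missing column(s): %s",
            paste(missing, collapse = ", "))
  }
  df <- df[RECORD_COLUMNS]
  rows <- if (is.null(attr(df, "row_number"))) seq_len(nrow(df)) + 1L
          else attr(df, "row_number")
  if (nrow(df) == 0L) {
    df$row_number <- integer(0)
    return(df)
  }
  for (col in c("taxon_name", "phylum", "species_or_subspecies_id")) {
    df[[col]] <- trimws(as.character(df[[col]]))
  }
  if (any(df$taxon_name == "")) {
    pd_stop("pdselect_schema_error", "row %d: empty taxon_name",
            rows[which(df$taxon_name == "")[1]])
  }
  if (any(df$phylum == "")) {
    pd_stop("pdselect_schema_error", "row %d: empty phylum",
            rows[which(df$phylum == "")[1]])
  }
  status <- trimws(as.character(df$genome_status))
  bad <- !(status %in% GENOME_STATUSES)
  if (any(bad)) {
    pd_stop("pdselect_schema_error",
            "row %d: unknown genome_status token '%s' (expected %s)",
            rows[which(bad)[1]], status[which(bad)[1]],
            paste(GENOME_STATUSES, collapse = "/"))
  }
  df$genome_status <- status
  for (col in c("is_type_strain", "genome_is_type", "growable", "proposed")) {
    df[[col]] <- parse_flag(df[[col]], col, rows)
  }
  contradict <- df$genome_is_type & df$genome_status == "none"
  if (any(contradict)) {
    pd_stop("pdselect_schema_error",
            "row %d: genome_is_type is TRUE but genome_status is 'none'",
            rows[which(contradict)[1]])
  }
  df$row_number <- rows
  df
}

#' Read a taxon-record table
#'
#' Reads a tab-separated table with the columns `taxon_name`, `phylum`,
#' `species_or_subspecies_id`, `is_type_strain`, `genome_status`
#' (`none`/`ongoing`/`complete`), `genome_is_type`, `growable`, `proposed`,
#' mirroring an export of nomenclatural events joined with genome-project
#' registrations (NamesforLife/GOLD style). Every row is validated; errors
#' name the offending row and token.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame of validated records with a `row_number` column for
#'   error reporting.
#' @export
read_taxon_records <- function(path) {
  if (!file.exists(path)) {
    pd_stop("pdselect_io_error", "records file not found: %s", path)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, quote = "")
  validate_records(df)
}

#' Write a taxon-record table
#'
#' @param records A record data frame (see [read_taxon_records()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_taxon_records <- function(records, path) {
  df <- records[RECORD_COLUMNS]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

count_distinct <- function(x) length(unique(x))

#' Per-phylum summary table
#'
#' Rolls records up into one row per phylum (input first-occurrence order)
#' plus a `Total` row: distinct type strains, distinct species/subspecies
#' names, percent homotypic synonyms, type and non-type genome sequences,
#' genome coverage of the type strains, and proposed-target counts.
#'
#' Percent synonyms is `100 * (species - type strains) / species`: every
#' name beyond one per type strain is a recorded synonym, new combination or
#' coordinate-status entry. Coverage is `100 * type genomes / type strains`.
#' The `coverage_incl_nontype_pct` column additionally counts non-type
#' genome sequences in the numerator; the two conventions are both reported
#' because published totals have used either. Percentages are kept at full
#' precision here; presentation rounding (half-up, one decimal) is applied
#' only by [format_phylum_summary()].
#'
#' @param records A validated record data frame.
#' @return A data frame with columns `phylum`, `n_type_strains`,
#'   `n_species_subsp`, `pct_synonyms`, `n_type_genomes`,
#'   `n_nontype_genomes`, `coverage_pct`, `coverage_incl_nontype_pct`,
#'   `n_proposed`; the last row is the `Total`.
#' @export
summarize_by_phylum <- function(records) {
  records <- validate_records(records)
  if (nrow(records) == 0L) {
    pd_stop("pdselect_validation_error", "no records to summarize")
  }
  phyla <- unique(records$phylum)
  one <- function(r, name) {
    has_genome <- r$genome_status != "none"
    nts <- count_distinct(r$taxon_name[r$is_type_strain])
    nsp <- count_distinct(r$species_or_subspecies_id)
    ntg <- count_distinct(r$taxon_name[has_genome & r$genome_is_type])
    nng <- count_distinct(r$taxon_name[has_genome & !r$genome_is_type])
    npr <- count_distinct(r$taxon_name[r$proposed])
    data.frame(
      phylum = name,
      n_type_strains = nts,
      n_species_subsp = nsp,
      pct_synonyms = if (nsp > 0) 100 * (nsp - nts) / nsp else 0,
      n_type_genomes = ntg,
      n_nontype_genomes = nng,
      coverage_pct = if (nts > 0) 100 * ntg / nts else 0,
      coverage_incl_nontype_pct = if (nts > 0) 100 * (ntg + nng) / nts else 0,
      n_proposed = npr,
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, lapply(phyla, function(p) {
    one(records[records$phylum == p, , drop = FALSE], p)
  }))
  tot <- data.frame(
    phylum = "Total",
    n_type_strains = sum(per$n_type_strains),
    n_species_subsp = sum(per$n_species_subsp),
    n_type_genomes = sum(per$n_type_genomes),
    n_nontype_genomes = sum(per$n_nontype_genomes),
    n_proposed = sum(per$n_proposed),
    stringsAsFactors = FALSE
  )
  tot$pct_synonyms <- if (tot$n_species_subsp > 0)
    100 * (tot$n_species_subsp - tot$n_type_strains) / tot$n_species_subsp else 0
  tot$coverage_pct <- if (tot$n_type_strains > 0)
    100 * tot$n_type_genomes / tot$n_type_strains else 0
  tot$coverage_incl_nontype_pct <- if (tot$n_type_strains > 0)
    100 * (tot$n_type_genomes + tot$n_nontype_genomes) / tot$n_type_strains else 0
  rbind(per, tot[names(per)])
}

#' Pretty-print a phylum summary
#'
#' Applies the presentation conventions of published summary tables:
#' half-up rounding to one decimal for percentages and comma grouping for
#' counts. Returns a character data frame; the full-precision numbers stay
#' in the [summarize_by_phylum()] output.
#'
#' @param summary Output of [summarize_by_phylum()].
#' @return A data frame of formatted strings.
#' @export
format_phylum_summary <- function(summary) {
  out <- summary
  for (col in c("n_type_strains", "n_species_subsp", "n_type_genomes",
                "n_nontype_genomes", "n_proposed")) {
    out[[col]] <- format(summary[[col]], big.mark = ",", trim = TRUE)
  }
  for (col in c("pct_synonyms", "coverage_pct", "coverage_incl_nontype_pct")) {
    out[[col]] <- sprintf("%.1f", round_half_up(summary[[col]], 1))
  }
  out
}

#' Candidate-pool partition
#'
#' Splits the distinct type strains into those with and without a known
#' genome project (ongoing or complete), the headline partition used to
#' motivate large-scale type-strain sequencing.
#'
#' @param records A validated record data frame.
#' @return A list with `n_type_strains`, `n_with_project`, `n_without`,
#'   `pct_with_project` (half-up, one decimal) and `frac_with_project`
#'   (full precision).
#' @export
candidate_pool_report <- function(records) {
  records <- validate_records(records)
  r <- records[records$is_type_strain, , drop = FALSE]
  strains <- unique(r$taxon_name)
  with_proj <- unique(r$taxon_name[r$genome_status != "none"])
  n <- length(strains)
  nw <- length(with_proj)
  frac <- if (n > 0) nw / n else 0
  list(n_type_strains = n, n_with_project = nw, n_without = n - nw,
       pct_with_project = round_half_up(100 * frac, 1),
       frac_with_project = frac)
}
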