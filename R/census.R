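# Published per-phylum census of validly named Bacteria and Archaea
# (mid-2011 snapshot of the NamesforLife nomenclature export joined with
# GOLD genome-project registrations), as used to motivate and size the
# one-thousand-genomes type-strain sequencing effort.

#' Per-phylum census of type strains and genome projects (mid-2011)
#'
#' Count columns of the published KMG planning table: distinct type strains,
#' validly named species/subspecies, type-strain genome sequences, non-type
#' genome sequences, and proposed sequencing targets, for the 31 phyla with
#' at least one validly named member plus two placeholder-free rows. These
#' are input data (a nomenclature/registry snapshot), not computed values;
#' the derived percentage columns are recomputed from them by
#' [summarize_by_phylum()].
#'
#' @return A data frame with columns `phylum`, `n_type_strains`,
#'   `n_species_subsp`, `n_type_genomes`, `n_nontype_genomes`, `n_proposed`.
#' @export
kmg_census <- function() {
  tab <- c(
    "Crenarchaeota",           57,   61,   33,  0,   0,
    "Euryarchaeota",          314,  388,  143,  4,   9,
    "Thaumarchaeota",           1,    1,    1,  0,   0,
    "Aquificae",               29,   31,    8,  0,   2,
    "Thermotogae",             37,   38,   14,  1,  13,
    "Thermodesulfobacteria",    7,    8,    2,  1,   4,
    "Deinococcus-Thermus",     71,   76,   19,  0,  18,
    "Chrysiogenetes",           4,    4,    2,  0,   0,
    "Chloroflexi",             27,   28,   11,  0,   0,
    "Nitrospirae",             12,   12,    2,  0,   3,
    "Deferribacteres",         12,   12,    6,  0,   1,
    "Cyanobacteria",           88,   90,    9,  2,   0,
    "Chlorobi",                16,   22,    9,  0,   0,
    "Proteobacteria",        3541, 4323,  364, 35, 385,
    "Firmicutes",            1875, 2263,  311, 14, 285,
    "Tenericutes",            234,  258,   25,  0,   2,
    "Actinobacteria",        2439, 2953,  145,  5, 129,
    "Planctomycetes",          15,   19,   10,  0,   2,
    "Chlamydiae",              17,   20,    8,  0,   0,
    "Spirochaetes",           112,  127,   25,  0,   2,
    "Fibrobacteres",            3,    5,    1,  0,   0,
    "Acidobacteria",           11,   11,    3,  0,   0,
    "Bacteroidetes",          767,  914,  131,  9, 134,
    "Fusobacteria",            38,   47,   12,  0,   7,
    "Verrucomicrobia",         35,   35,    6,  2,   3,
    "Gemmatimonadetes",         1,    1,    1,  0,   0,
    "Dictyoglomi",              2,    3,    2,  0,   0,
    "Lentisphaerae",            2,    2,    1,  0,   0,
    "Synergistetes",           17,   18,   10,  1,   1,
    "Caldiserica",              1,    1,    1,  0,   0,
    "Elusimicrobia",            1,    1,    1,  0,   0
  )
  m <- matrix(tab, ncol = 6, byrow = TRUE)
  data.frame(
    phylum = m[, 1],
    n_type_strains = as.integer(m[, 2]),
    n_species_subsp = as.integer(m[, 3]),
    n_type_genomes = as.integer(m[, 4]),
    n_nontype_genomes = as.integer(m[, 5]),
    n_proposed = as.integer(m[, 6]),
    stringsAsFactors = FALSE
  )
}

#' Expand per-phylum counts into a synthetic record table
#'
#' Reconstructs a taxon-record table whose per-phylum roll-up reproduces the
#' given count columns exactly: one row per species/subspecies name, with
#' surplus names attached to the phylum's first type strain (homotypic
#' synonyms), genome flags on the first `n_type_genomes` strains, proposed
#' flags on the next `n_proposed`, and additional non-type strain rows for
#' non-type genome sequences. Strain and species identifiers are synthetic
#' (`<phylum>_ts0001`, ...); only the counts are meaningful.
#'
#' @param census A data frame with the columns of [kmg_census()].
#' @return A validated record data frame (see [read_taxon_records()]).
#' @export
expand_census_records <- function(census = kmg_census()) {
  rows <- lapply(seq_len(nrow(census)), function(i) {
    p <- census$phylum[i]
    nts <- census$n_type_strains[i]
    nsp <- census$n_species_subsp[i]
    ntg <- census$n_type_genomes[i]
    nng <- census$n_nontype_genomes[i]
    npr <- census$n_proposed[i]
    stopifnot(nts <= nsp, ntg + npr <= nts)
    strains <- sprintf("%s_ts%04d", p, seq_len(nts))
    strain_of_name <- c(seq_len(nts), rep(1L, nsp - nts))
    sidx <- strain_of_name
    type_rows <- data.frame(
      taxon_name = strains[sidx],
      phylum = p,
      species_or_subspecies_id = sprintf("%s_sp%04d", p, seq_len(nsp)),
      is_type_strain = TRUE,
      genome_status = ifelse(sidx <= ntg, "complete", "none"),
      genome_is_type = sidx <= ntg,
      growable = TRUE,
      proposed = sidx > ntg & sidx <= ntg + npr,
      stringsAsFactors = FALSE
    )
    if (nng > 0) {
      m <- seq_len(nng)
      nontype_rows <- data.frame(
        taxon_name = sprintf("%s_nt%04d", p, m),
        phylum = p,
        species_or_subspecies_id = sprintf("%s_sp%04d", p,
                                           pmin(nsp, ntg + m)),
        is_type_strain = FALSE,
        genome_status = "complete",
        genome_is_type = FALSE,
        growable = TRUE,
        proposed = FALSE,
        stringsAsFactors = FALSE
      )
      type_rows <- rbind(type_rows, nontype_rows)
    }
    type_rows
  })
  validate_records(do.call(rbind, rows))
}
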