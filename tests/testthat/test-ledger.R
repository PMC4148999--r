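test_that("record tables load, validate, and report bad rows by number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_taxon_records(make_records(c("a", "b", "c")), path)
  recs <- read_taxon_records(path)
  expect_equal(nrow(recs), 3)
  expect_type(recs$is_type_strain, "logical")

  # header-only file -> empty record set
  writeLines(paste(c("taxon_name", "phylum", "species_or_subspecies_id",
                     "is_type_strain", "genome_status", "genome_is_type",
                     "growable", "proposed"), collapse = "\t"), path)
  expect_equal(nrow(read_taxon_records(path)), 0)

  bad <- make_records("a")
  bad$genome_status <- "sequenced"
  write_taxon_records(bad, path)
  expect_error(read_taxon_records(path), "row 2.*sequenced",
               class = "pdselect_schema_error")

  bad2 <- make_records("a")
  bad2$genome_is_type <- TRUE  # status stays "none": contradiction
  write_taxon_records(bad2, path)
  expect_error(read_taxon_records(path), "genome_is_type",
               class = "pdselect_schema_error")

  writeLines("taxon_name\tphylum\nx\ty", path)
  expect_error(read_taxon_records(path), "missing column",
               class = "pdselect_schema_error")
})

test_that("per-phylum roll-up reproduces the published derived cells", {
  recs <- expand_census_records(kmg_census())
  summ <- summarize_by_phylum(recs)
  pretty <- format_phylum_summary(summ)
  row <- function(p) pretty[pretty$phylum == p, ]
  # percent synonyms = (species - type strains) / species
  expect_equal(row("Crenarchaeota")$pct_synonyms, "6.6")
  expect_equal(row("Euryarchaeota")$pct_synonyms, "19.1")
  expect_equal(row("Proteobacteria")$pct_synonyms, "18.1")
  expect_equal(row("Actinobacteria")$pct_synonyms, "17.4")
  # coverage = type genomes / type strains
  expect_equal(row("Crenarchaeota")$coverage_pct, "57.9")
  expect_equal(row("Thermotogae")$coverage_pct, "37.8")
  expect_equal(row("Proteobacteria")$coverage_pct, "10.3")
  expect_equal(row("Firmicutes")$coverage_pct, "16.6")
  expect_equal(row("Actinobacteria")$coverage_pct, "5.9")
  expect_equal(row("Thaumarchaeota")$coverage_pct, "100.0")
})

test_that("totals row sums the count columns and recomputes percentages", {
  summ <- summarize_by_phylum(expand_census_records())
  tot <- summ[summ$phylum == "Total", ]
  per <- summ[summ$phylum != "Total", ]
  expect_equal(tot$n_type_strains, 9786)
  expect_equal(tot$n_species_subsp, 11772)
  expect_equal(tot$n_type_genomes, 1316)
  expect_equal(tot$n_nontype_genomes, 74)
  expect_equal(tot$n_proposed, 1000)
  for (col in c("n_type_strains", "n_species_subsp", "n_type_genomes",
                "n_nontype_genomes", "n_proposed")) {
    expect_equal(tot[[col]], sum(per[[col]]))
  }
  # the two total-coverage conventions: type-only vs including non-type
  expect_equal(sprintf("%.1f", floor(tot$coverage_pct * 10 + 0.5) / 10), "13.4")
  expect_equal(sprintf("%.1f", floor(tot$coverage_incl_nontype_pct * 10 + 0.5) / 10), "14.2")
})

test_that("summaries are invariant under record reordering", {
  recs <- expand_census_records()
  set.seed(1)
  shuffled <- recs[sample(nrow(recs)), ]
  a <- summarize_by_phylum(recs)
  b <- summarize_by_phylum(shuffled)
  b <- b[match(a$phylum, b$phylum), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[-1], b[-1])
})

test_that("percentages are rounded half-up only at presentation", {
  recs <- rbind(make_records(sprintf("t%d", 1:57)),
                make_records(sprintf("s%d", 1:4)))
  recs$species_or_subspecies_id[58:61] <- recs$taxon_name[1:4]
  recs$species_or_subspecies_id[1:57] <- sprintf("sp%d", 1:57)
  recs$taxon_name[58:61] <- recs$taxon_name[1:4]
  summ <- summarize_by_phylum(recs)
  expect_equal(summ$n_type_strains[1], 57)
  expect_equal(summ$n_species_subsp[1], 61)
  expect_equal(summ$pct_synonyms[1], 100 * 4 / 61)  # full precision kept
  expect_equal(format_phylum_summary(summ)$pct_synonyms[1], "6.6")
})

test_that("candidate pool partition counts strains with genome projects", {
  recs <- make_records(sprintf("t%02d", 1:10))
  recs$genome_status[1:2] <- c("complete", "ongoing")
  recs$genome_is_type[1:2] <- TRUE
  pool <- candidate_pool_report(recs)
  expect_equal(pool$n_type_strains, 10)
  expect_equal(pool$n_with_project, 2)
  expect_equal(pool$n_without, 8)
  expect_equal(pool$pct_with_project, 20.0)
  recs$genome_status[] <- "complete"
  recs$genome_is_type[] <- TRUE
  expect_equal(candidate_pool_report(recs)$pct_with_project, 100.0)
})

test_that("the census pool fraction is 13.4% with type genomes only", {
  pool <- candidate_pool_report(expand_census_records())
  expect_equal(pool$n_type_strains, 9786)
  expect_equal(pool$n_with_project, 1316)
  expect_equal(pool$pct_with_project, 13.4)
})
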