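test_that("simulation specs validate their inputs", {
  expect_error(simulation_spec(n_leaves = 1), class = "pdselect_validation_error")
  expect_error(simulation_spec(n_leaves = 10, birth_rate = 0),
               class = "pdselect_validation_error")
  expect_error(simulation_spec(n_leaves = 10, frac_sequenced = 0.8,
                               frac_ongoing = 0.4),
               class = "pdselect_validation_error")
})

test_that("Yule trees have the right shape and strictly positive lengths", {
  spec <- simulation_spec(n_leaves = 2, seed = 3, n_phyla = 1)
  tr <- simulate_yule_tree(spec)
  expect_length(tr$tip.label, 2)
  expect_equal(nrow(tr$edge), 2)
  expect_true(all(tr$edge.length > 0))
  for (n in c(5, 64, 301)) {
    tr <- simulate_yule_tree(simulation_spec(n_leaves = n, seed = n, n_phyla = 1))
    expect_length(tr$tip.label, n)
    expect_equal(tr$Nnode, n - 1L)        # binary rooted
    expect_true(all(tr$edge.length > 0))
    expect_length(unique(tr$tip.label), n)
  }
})

test_that("identical specs give identical newick output; seeds decorrelate", {
  spec <- simulation_spec(n_leaves = 40, seed = 11, n_phyla = 4)
  expect_identical(write_newick(simulate_yule_tree(spec)),
                   write_newick(simulate_yule_tree(spec)))
  spec2 <- simulation_spec(n_leaves = 40, seed = 12, n_phyla = 4)
  expect_false(identical(write_newick(simulate_yule_tree(spec)),
                         write_newick(simulate_yule_tree(spec2))))
})

test_that("simulation does not disturb the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_dataset(simulation_spec(n_leaves = 20, seed = 5, n_phyla = 2)))
  expect_identical(.Random.seed, before)
})

test_that("total Yule tree length matches its analytic expectation", {
  # growing from 2 lineages with a final Exp(n*lambda) interval, the time
  # with k lineages is Exp(k*lambda), so E[total] = sum_k k/(k*lambda)
  # = (n - 1) / lambda, with variance (n - 1) / lambda^2
  n <- 200; lambda <- 2; reps <- 50
  tot <- vapply(seq_len(reps), function(s) {
    total_branch_length(simulate_yule_tree(
      simulation_spec(n_leaves = n, birth_rate = lambda, seed = 7000 + s,
                      n_phyla = 1)))
  }, numeric(1))
  expected <- (n - 1) / lambda
  se <- sqrt((n - 1) / lambda^2 / reps)
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("phylum assignment is monophyletic with the requested group count", {
  spec <- simulation_spec(n_leaves = 150, seed = 8, n_phyla = 12)
  tr <- simulate_yule_tree(spec)
  recs <- assign_records(tr, spec)
  expect_equal(length(unique(recs$phylum)), 12)
  expect_equal(nrow(recs), 150)
  # monophyly: the spanning clade of each phylum contains no foreign leaves
  for (p in unique(recs$phylum)) {
    members <- recs$taxon_name[recs$phylum == p]
    if (length(members) >= 2) {
      node <- ape::getMRCA(tr, members)
      clade <- ape::extract.clade(tr, node)$tip.label
      expect_setequal(clade, members)
    }
  }
  expect_error(assign_records(tr, simulation_spec(n_leaves = 150, seed = 8,
                                                  n_phyla = 151)),
               class = "pdselect_validation_error")
})

test_that("status fractions converge to the spec probabilities", {
  spec <- simulation_spec(n_leaves = 4000, seed = 17, frac_sequenced = 0.07,
                          frac_ongoing = 0.06, frac_nongrowable = 0.05,
                          n_phyla = 10)
  recs <- assign_records(simulate_yule_tree(spec), spec)
  n <- nrow(recs)
  for (chk in list(c(mean(recs$genome_status == "complete"), 0.07),
                   c(mean(recs$genome_status == "ongoing"), 0.06),
                   c(mean(!recs$growable), 0.05))) {
    se <- sqrt(chk[2] * (1 - chk[2]) / n)
    expect_lt(abs(chk[1] - chk[2]), 3 * se + 1e-9)
  }
})

test_that("degenerate status fractions propagate through the pipeline", {
  spec <- simulation_spec(n_leaves = 30, seed = 2, frac_sequenced = 0,
                          frac_ongoing = 0, n_phyla = 2)
  dat <- simulate_dataset(spec)
  j <- join_tree_records(dat$tree, dat$records)
  f <- filter_candidates(j$matched, selection_config(n_primary = 1))
  expect_length(f$preselected, 0)

  spec1 <- simulation_spec(n_leaves = 30, seed = 2, frac_sequenced = 1,
                           frac_ongoing = 0, n_phyla = 2)
  dat1 <- simulate_dataset(spec1)
  j1 <- join_tree_records(dat1$tree, dat1$records)
  expect_error(filter_candidates(j1$matched, selection_config(n_primary = 1)),
               "empty", class = "pdselect_validation_error")
})

test_that("end-to-end smoke run: simulate then select raises coverage", {
  spec <- simulation_spec(n_leaves = 500, seed = 123, n_phyla = 10)
  dat <- simulate_dataset(spec)
  run <- run_selection(dat$tree, dat$records,
                       selection_config(n_primary = 50, n_backup = 0))
  fr <- setNames(run$coverage$sets$fraction, run$coverage$sets$set)
  expect_lt(fr["preselected"], fr["preselected_plus_primary"])
  summ <- summarize_by_phylum(dat$records)
  expect_equal(nrow(summ), 11)  # 10 phyla + totals
})
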