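test_that("PD of the worked quartet matches hand enumeration", {
  tr <- quartet_tree()
  expect_equal(pd(tr, "C", "rooted"), 5)          # 3 + 2 on the root path
  expect_equal(pd(tr, c("A", "C"), "unrooted"), 7) # 1 + 1 + 2 + 3
  expect_equal(pd(tr, character(0)), 0)
  expect_equal(pd(tr, "C", "unrooted"), 0)
  expect_equal(pd(tr, leaf_labels(tr), "rooted"), total_branch_length(tr))
  expect_equal(pd(tr, leaf_labels(tr), "unrooted"), total_branch_length(tr))
})

test_that("unknown taxa are reported by name", {
  expect_error(pd(quartet_tree(), c("A", "Zeta")), "Zeta",
               class = "pdselect_taxon_error")
})

test_that("PD agrees with an independent path-enumeration oracle", {
  set.seed(3)
  for (i in 1:15) {
    tr <- small_yule(sample(4:15, 1), seed = 200 + i)
    lv <- leaf_labels(tr)
    for (j in 1:4) {
      s <- sample(lv, sample(seq_along(lv), 1))
      expect_equal(pd(tr, s, "rooted"), oracle_pd(tr, s, "rooted"))
      expect_equal(pd(tr, s, "unrooted"), oracle_pd(tr, s, "unrooted"))
    }
  }
})

test_that("rooted PD agrees with picante's Faith PD", {
  skip_if_not_installed("picante")
  set.seed(4)
  for (i in 1:8) {
    tr <- small_yule(12, seed = 300 + i)
    lv <- leaf_labels(tr)
    s <- sample(lv, sample(2:10, 1))
    comm <- matrix(as.integer(lv %in% s), nrow = 1,
                   dimnames = list("x", lv))
    expect_equal(pd(tr, s, "rooted"),
                 picante::pd(comm, tr, include.root = TRUE)$PD)
  }
})

test_that("PD is monotone under set inclusion in both modes", {
  set.seed(5)
  for (i in 1:10) {
    tr <- small_yule(sample(5:20, 1), seed = 400 + i)
    lv <- leaf_labels(tr)
    small <- sample(lv, sample(seq_len(length(lv) - 1), 1))
    big <- union(small, sample(lv, sample(seq_along(lv), 1)))
    for (m in c("rooted", "unrooted")) {
      expect_lte(pd(tr, small, m), pd(tr, big, m) + 1e-12)
      expect_lte(pd(tr, big, m), total_branch_length(tr) + 1e-12)
    }
  }
})

test_that("coverage fractions are invariant under uniform rescaling", {
  tr <- small_yule(25, seed = 17)
  sets <- list(a = leaf_labels(tr)[1:5], b = leaf_labels(tr)[3:20])
  cov1 <- pd_coverage(tr, sets)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 37.5
  cov2 <- pd_coverage(tr2, sets)
  expect_equal(cov1$sets$fraction, cov2$sets$fraction)
})

test_that("coverage of the quartet reproduces the worked fractions", {
  cov <- pd_coverage(quartet_tree(),
                     list(seq = "C", combined = c("C", "B"),
                          all = c("A", "B", "C", "D")))
  expect_equal(cov$sets$fraction, c(0.5, 0.8, 1.0))
  expect_equal(cov$sets$pd, c(5, 8, 10))
  expect_equal(cov$total_pd, 10)
})

test_that("unique contribution matches the leave-one-out definition", {
  tr <- quartet_tree()
  expect_equal(unique_contribution(tr, "B", "unrooted"), 2)  # 10 - pd({A,C,D})
  tr2 <- read_newick("((A:1,B:2):5,C:3);")
  # dropping C loses its pendant edge and the now-unspanned stem: 11 - 3
  expect_equal(unique_contribution(tr2, "C", "unrooted"), 8)
  tr0 <- read_newick("((A:0,B:2):1,C:3);")
  expect_equal(unique_contribution(tr0, "A", "rooted"), 0)
})

test_that("closed-form contributions equal per-taxon subtraction", {
  set.seed(6)
  for (i in 1:10) {
    tr <- small_yule(sample(4:15, 1), seed = 500 + i)
    for (m in c("rooted", "unrooted")) {
      tab <- pd_contributions(tr, m)
      direct <- vapply(tab$taxon,
                       function(x) unique_contribution(tr, x, m), numeric(1))
      expect_equal(tab$contribution, unname(direct))
    }
  }
})

test_that("summed unique contributions never exceed total PD", {
  for (i in 1:5) {
    tr <- small_yule(sample(5:30, 1), seed = 600 + i)
    for (m in c("rooted", "unrooted")) {
      expect_lte(sum(pd_contributions(tr, m)$contribution),
                 total_branch_length(tr) + 1e-9)
    }
  }
})
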