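test_that("CDR3 identity is the fraction of matching positions", {
  expect_equal(cdr3_identity("ARDW", "ARDW"), 1.0)
  expect_equal(cdr3_identity("ARDW", "ARDY"), 0.75)
  expect_error(cdr3_identity("ARD", "ARDW"), "equal-length")

  set.seed(31)
  for (i in 1:50) {
    L <- sample(3:20, 1)
    a <- rand_aa(L); b <- rand_aa(L)
    hamming <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(cdr3_identity(a, b), 1 - hamming / L)
  }
})

test_that("identical CDR3s merge and sub-threshold pairs stay apart", {
  cf <- build_clonal_families(make_cells(c("ARDWGQ", "ARDWGQ")))
  expect_equal(nrow(cf$families), 1L)
  expect_equal(cf$families$n_cells, 2L)

  # identity 0.69 < 0.70: two singletons
  a <- rand_aa(100)
  b <- mutate_positions(a, sample(100, 31))  # 69 matches
  expect_equal(cdr3_identity(a, b), 0.69)
  cf2 <- build_clonal_families(make_cells(c(a, b)))
  expect_equal(nrow(cf2$families), 2L)
})

test_that("small groups match exhaustive connected-component enumeration", {
  set.seed(53)
  for (rep_i in 1:25) {
    n <- sample(3:8, 1)
    L <- sample(c(10, 12, 15), 1)
    founder <- rand_aa(L)
    seqs <- vapply(seq_len(n), function(i) {
      k <- sample(0:L, 1)  # anywhere from identical to unrelated
      if (k > 0) mutate_positions(founder, sample(L, k)) else founder
    }, character(1))
    cf <- build_clonal_families(make_cells(seqs), threshold = 0.70)
    inferred <- as.integer(factor(cf$cells$cf_id[order(cf$cells$cell_id)]))
    expected <- components_closure(seqs, 0.70)
    # same partition up to labelling: co-membership matrices agree
    expect_equal(length(unique(inferred)), length(unique(expected)))
    expect_true(all(outer(inferred, inferred, "==") ==
                      outer(expected, expected, "==")))
  }
})

test_that("partition covers all cells and is invariant to input order", {
  sim <- small_clean_sim()
  qc <- pair_cells(sim$rearrangements, sim$expression)
  cf <- build_clonal_families(qc$cells)
  expect_equal(sum(cf$families$n_cells), nrow(qc$cells))
  expect_setequal(cf$cells$cell_id, qc$cells$cell_id)

  set.seed(7)
  shuffled <- qc$cells[sample(nrow(qc$cells)), ]
  cf2 <- build_clonal_families(shuffled)
  expect_identical(cf$cells, cf2$cells)
  expect_identical(cf$families, cf2$families)
})

test_that("raising the threshold only refines the partition", {
  sim <- small_clean_sim()
  qc <- pair_cells(sim$rearrangements, sim$expression)
  lo <- build_clonal_families(qc$cells, threshold = 0.70)
  hi <- build_clonal_families(qc$cells, threshold = 0.85)
  map_lo <- setNames(lo$cells$cf_id, lo$cells$cell_id)
  # every high-threshold family sits inside one low-threshold family
  for (fam in split(hi$cells$cell_id, hi$cells$cf_id)) {
    expect_length(unique(map_lo[fam]), 1L)
  }
})

test_that("planted families are recovered with near-perfect agreement", {
  skip_if_not_installed("mclust")
  sim <- small_clean_sim()
  qc <- pair_cells(sim$rearrangements, sim$expression)
  cf <- build_clonal_families(qc$cells)
  truth <- sim$truth$cells
  ari <- mclust::adjustedRandIndex(
    cf$cells$cf_id, truth$family_id[match(cf$cells$cell_id, truth$cell_id)])
  expect_gte(ari, 0.95)
})

test_that("convergence means members from at least two subjects", {
  cf <- build_clonal_families(make_cells(c("ARDWGQ", "ARDWGQ", "PPPPPP"),
                                         subjects = c("A", "Q", "A")))
  cf <- annotate_convergence(cf)
  two_subj <- cf$families[cf$families$n_cells == 2L, ]
  expect_true(two_subj$is_convergent)
  expect_equal(two_subj$n_subjects, 2L)
  expect_false(cf$families$is_convergent[cf$families$n_cells == 1L])
})

test_that("persistence lists the samples contributing per subject", {
  cells <- make_cells(rep("ARDWGQ", 5), subjects = rep("A", 5))
  cells$sample_id <- c("A-1", "A-1", "A-3", "A-3", "A-3")
  cf <- annotate_convergence(build_clonal_families(cells))
  expect_false(any(cf$families$is_convergent))
  expect_equal(cf$persistence$n_samples, 2L)
  expect_equal(cf$persistence$sample_ids, "A-1,A-3")
})

test_that("consensus takes the modal residue with alphabetical ties", {
  expect_equal(consensus_cdr3(c("ARD", "ARD", "AKD")), "ARD")
  expect_equal(consensus_cdr3("CARW"), "CARW")
  # position 2 ties D vs E -> D
  expect_equal(consensus_cdr3(c("ADX", "AEX")), "ADX")
})
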