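test_that("edit distance matches its definition and the recursive oracle", {
  expect_equal(edit_distance("KITTEN", "KITTEN"), 0L)
  expect_equal(edit_distance("A", ""), 1L)
  expect_equal(edit_distance("KITTEN", "SITTING"), 3L)

  set.seed(17)
  for (i in 1:100) {
    a <- rand_aa(sample(0:8, 1), alphabet = LETTERS[1:5])
    b <- rand_aa(sample(0:8, 1), alphabet = LETTERS[1:5])
    expect_equal(edit_distance(a, b), lev_recursive(a, b))
  }
})

test_that("distance matrices are metric and consistent with pairwise calls", {
  cells <- make_cells(c("ARDW", "ARDW", "PPPP"))
  dm <- distance_matrix(cells, chain = "VH")
  expect_equal(unname(diag(dm$values)), rep(0L, 3))
  expect_true(isSymmetric(unname(dm$values)))
  # the two identical cells are adjacent in the clustering order
  ident <- which(dm$labels %in% cells$cell_id[1:2])
  expect_equal(abs(diff(match(ident, dm$order))), 1L)

  sim <- small_clean_sim()
  qc <- pair_cells(sim$rearrangements, sim$expression)
  sub <- qc$cells[1:20, ]
  dm2 <- distance_matrix(sub, chain = "VH")
  for (i in c(1, 5, 12)) {
    for (j in c(3, 9, 20)) {
      a <- sub$heavy_sequence_aa[sub$cell_id == dm2$labels[i]]
      b <- sub$heavy_sequence_aa[sub$cell_id == dm2$labels[j]]
      expect_equal(dm2$values[i, j], edit_distance(a, b))
    }
  }
  # triangle inequality on sampled triples
  set.seed(5)
  for (k in 1:30) {
    ijk <- sample(20, 3)
    expect_lte(dm2$values[ijk[1], ijk[3]],
               dm2$values[ijk[1], ijk[2]] + dm2$values[ijk[2], ijk[3]])
  }
})

test_that("a missing chain sequence names the offending cell", {
  cells <- make_cells(c("ARDW", "AKDW"))
  cells$light_sequence_aa[2] <- ""
  expect_error(distance_matrix(cells, chain = "VL"), "c002")
})

test_that("SHM is the mismatch fraction with N positions excluded", {
  germ <- rand_nt(300)
  expect_equal(shm_estimate(germ, germ)$f, 0)

  mut <- mutate_positions(germ, c(10, 100, 250),
                          alphabet = c("A", "C", "G", "T"))
  est <- shm_estimate(mut, germ)
  expect_equal(est$n, 3L)
  expect_equal(est$f, 0.01)

  # case-insensitive; N masks a position from both counts
  expect_equal(shm_estimate(tolower(mut), germ)$f, 0.01)
  mut_n <- mut
  substr(mut_n, 10, 10) <- "N"
  est_n <- shm_estimate(mut_n, germ)
  expect_equal(est_n$n, 2L)
  expect_equal(est_n$len, 299L)

  expect_error(shm_estimate(mut, ""), "no_germline")
})

test_that("realized SHM tracks the planted per-site rate", {
  sim <- small_clean_sim()
  qc <- pair_cells(sim$rearrangements, sim$expression)
  shm <- shm_table(qc$cells, chains = "VH")
  rate <- sim$config$shm_rate_per_site
  n_sites <- sum(shm$v_length_compared_nt)
  se <- sqrt(rate * (1 - rate) / n_sites)
  expect_lt(abs(mean(shm$shm_fraction) - rate), 3 * se)
})

test_that("logo PFMs are normalized and apply the centre-gap policy", {
  pfm <- logo_pfm(c("ARD", "ARD"))
  expect_equal(pfm$frequencies["A", 1], 1.0)

  # "ABD" against width 4 becomes "AB-D"
  pfm2 <- logo_pfm(c("ABCD", "ABD"))
  expect_equal(pfm2$gap_fraction, c(0, 0, 0.5, 0))
  expect_equal(pfm2$frequencies["D", 4], 1.0)

  set.seed(23)
  for (i in 1:10) {
    seqs <- vapply(1:8, function(j) rand_aa(sample(8:14, 1)), character(1))
    p <- logo_pfm(seqs)
    expect_equal(unname(colSums(p$frequencies)),
                 rep(1, ncol(p$frequencies)), tolerance = 1e-9)
  }

  # equal-length input: alignment policy is irrelevant
  seqs_eq <- c("ARDWGQ", "AKDWGQ", "ARDYGQ")
  expect_equal(logo_pfm(seqs_eq, "center_gap")$frequencies,
               logo_pfm(seqs_eq, "left")$frequencies)
  expect_equal(logo_pfm(seqs_eq, "left")$frequencies,
               logo_pfm(seqs_eq, "right")$frequencies)
})
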