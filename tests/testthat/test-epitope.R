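test_that("tiling emits every window and nothing else", {
  p15 <- rand_aa(15)
  t1 <- tile_protein(p15)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$sequence, p15)

  expect_equal(nrow(tile_protein(rand_aa(20))), 6L)
  expect_error(tile_protein(rand_aa(10), k = 15), "protein_too_short")

  set.seed(41)
  for (i in 1:10) {
    L <- sample(15:80, 1)
    k <- sample(5:15, 1)
    off <- sample(1:3, 1)
    p <- rand_aa(L)
    tl <- tile_protein(p, k = k, offset = off)
    expect_equal(nrow(tl), floor((L - k) / off) + 1)
    expect_true(all(tl$sequence ==
                      substring(p, tl$start + 1, tl$start + tl$length)))
  }
})

test_that("motif scanning finds all occurrences, overlaps included", {
  hits <- scan_motif("AAAA", "AA")
  expect_equal(hits$start, c(0L, 1L, 2L))
  expect_equal(nrow(scan_motif("AAAA", "AA", allow_overlap = FALSE)), 2L)

  s <- rand_aa(30)
  self <- scan_motif(s, s)
  expect_equal(self$start, 0L)
  expect_equal(self$end, 30L)

  set.seed(47)
  for (i in 1:200) {
    s <- rand_aa(sample(10:60, 1), alphabet = LETTERS[1:4])
    m <- rand_aa(sample(1:4, 1), alphabet = LETTERS[1:4])
    expect_equal(scan_motif(s, m)$start, scan_naive(s, m))
  }
})

test_that("array signals project by max over covering tiles", {
  p <- rand_aa(30)
  tiles <- tile_protein(p, k = 15)
  zero <- map_array_signal(tiles, rep(0, nrow(tiles)))
  expect_equal(zero$profile, rep(0, 30))
  expect_equal(nrow(zero$intervals), 0L)

  one_hot <- rep(0, nrow(tiles)); one_hot[4] <- 5
  hit <- map_array_signal(tiles, one_hot)
  expect_equal(hit$intervals, data.frame(start = 3L, end = 18L))

  set.seed(59)
  sig <- runif(nrow(tiles))
  prof <- map_array_signal(tiles, sig)$profile
  for (r in c(1, 10, 22, 30)) {
    covering <- which(tiles$start < r & r <= tiles$start + tiles$length)
    expect_equal(prof[r], max(sig[covering]))
  }
  expect_error(map_array_signal(tiles, sig[-1]), "match")
})

test_that("global alignment scores, gaps and unique regions are exact", {
  set.seed(71)
  s <- rand_aa(12)
  same <- align_global(s, s)
  expect_equal(same$percent_identity, 1.0)
  expect_equal(same$score, 12)

  # one gap column: 2 matches + 1 gap = 0
  acd <- align_global("ACD", "AD")
  expect_equal(acd$score, 0)
  expect_equal(acd$aligned_a, "ACD")
  expect_equal(acd$aligned_b, "A-D")

  # a 6-residue insertion in a is recovered as the region absent from b
  left <- rand_aa(20); right <- rand_aa(20); loop <- "DPYSPS"
  a <- paste0(left, loop, right)
  b <- paste0(left, right)
  aln <- align_global(a, b)
  expect_equal(aln$unmatched_region_b, data.frame(start = 20L, end = 26L))
})

test_that("alignment scores are symmetric and match an independent aligner", {
  set.seed(61)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:20) {
    a <- rand_nt(sample(5:25, 1))
    b <- rand_nt(sample(5:25, 1))
    ours <- align_global(a, b)
    expect_equal(align_global(b, a)$score, ours$score)
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
      type = "global", scoreOnly = TRUE)
    expect_equal(ours$score, ref)
  }
})

test_that("simulated peptide arrays are recovered by the signal mapper", {
  flank <- function(n) rand_aa(n, alphabet = LETTERS[1:10])
  set.seed(67)
  prot <- paste0(flank(25), "DPYSPSQDPYSPSQ", flank(25))

  clean <- simulate_peptide_array(prot, noise_sd = 0)
  res <- map_array_signal(clean$tiles, clean$signals)
  covered <- rep(FALSE, nchar(prot))
  for (i in which(clean$tile_has_motif)) {
    covered[(clean$tiles$start[i] + 1):(clean$tiles$start[i] + 15)] <- TRUE
  }
  in_interval <- rep(FALSE, nchar(prot))
  for (r in seq_len(nrow(res$intervals))) {
    in_interval[(res$intervals$start[r] + 1):res$intervals$end[r]] <- TRUE
  }
  expect_equal(in_interval, covered)

  # no planted motif: no intervals
  none <- simulate_peptide_array(flank(60), noise_sd = 0)
  expect_false(any(none$tile_has_motif))
  expect_equal(nrow(map_array_signal(none$tiles, none$signals)$intervals), 0L)

  # every planted copy is overlapped by a recovered interval
  noisy <- simulate_peptide_array(prot, noise_sd = 0.5, seed = 5L)
  res2 <- map_array_signal(noisy$tiles, noisy$signals)
  for (h in seq_len(nrow(noisy$motif_hits))) {
    overlaps <- any(res2$intervals$start < noisy$motif_hits$end[h] &
                      noisy$motif_hits$start[h] < res2$intervals$end)
    expect_true(overlaps)
  }
})
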