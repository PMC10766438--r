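test_that("sequence criteria produce complete reason codes", {
  ok <- make_rec(v_sequence_length = 251L)
  expect_true(check_sequence(ok)$pass)

  # boundary: exactly the minimum V length fails ("greater than 250 nt")
  expect_match(check_sequence(make_rec(v_sequence_length = 250L))$reasons,
               "short_v")

  stopped <- make_rec()
  substr(stopped$sequence, 10, 12) <- "TAA"
  v <- check_sequence(stopped)
  expect_false(v$pass)
  expect_match(v$reasons, "stop_codon")

  ambig <- make_rec()
  substr(ambig$sequence, 5, 5) <- "N"
  expect_match(check_sequence(ambig)$reasons, "ambiguous_nt")

  expect_match(check_sequence(make_rec(cdr3_aa = "WRONG"))$reasons,
               "cdr3_frame")
  expect_match(check_sequence(make_rec(c_call = "IGHE,IGHG1"))$reasons,
               "ambiguous_c_call")
  expect_match(check_sequence(make_rec(c_call = ""))$reasons,
               "ambiguous_c_call")
  expect_match(check_sequence(make_rec(productive = FALSE))$reasons,
               "nonproductive")

  # all failures are enumerated, not just the first
  multi <- make_rec(v_sequence_length = 100L, productive = FALSE)
  codes <- strsplit(check_sequence(multi)$reasons, ",")[[1]]
  expect_true(all(c("short_v", "nonproductive") %in% codes))
})

test_that("verdicts are pure: independent of row order and repeatable", {
  recs <- rbind(make_rec("c1"), make_rec("c2", v_sequence_length = 100L),
                make_rec("c3", c_call = ""))
  v1 <- check_sequence(recs)
  v2 <- check_sequence(recs[c(3, 1, 2), ])
  expect_identical(v1$pass, v2$pass[c(2, 3, 1)])
  expect_identical(v1, check_sequence(recs))
})

test_that("cells are paired iff a single passing heavy and light plus enough genes", {
  recs <- rbind(make_rec("c1", locus = "IGH"),
                make_rec("c1", locus = "IGK", v_call = "IGKV1-1*01",
                         j_call = "IGKJ1*01"))
  expr <- make_expr("c1", n_genes = 600L)
  out <- pair_cells(recs, expr)
  expect_equal(nrow(out$cells), 1L)
  expect_equal(out$cells$isotype, "IgE")
  expect_equal(out$report$per_cell$outcome, "retained")

  # boundary: 499 expressed genes rejects with reason min_genes
  out499 <- pair_cells(recs, make_expr("c1", n_genes = 499L))
  expect_equal(nrow(out499$cells), 0L)
  expect_match(out499$report$per_cell$reasons, "min_genes")
  out500 <- pair_cells(recs, make_expr("c1", n_genes = 500L))
  expect_equal(nrow(out500$cells), 1L)

  # two passing heavies: multiplet
  multi <- rbind(recs, make_rec("c1", locus = "IGH", v_call = "IGHV2-1*01"))
  outm <- pair_cells(multi, expr)
  expect_equal(nrow(outm$cells), 0L)
  expect_match(outm$report$per_cell$reasons, "multiplet")

  # unknown cell in expression: rejected with no_expression, no error
  expr2 <- make_expr("other_cell")
  outx <- pair_cells(recs, expr2)
  expect_match(outx$report$per_cell$reasons, "no_expression")
})

test_that("retained plus rejected always equals the input cell count", {
  sim <- default_sim()
  out <- pair_cells(sim$rearrangements, sim$expression)
  n_cells <- length(unique(sim$rearrangements$cell_id))
  expect_equal(out$report$n_input, n_cells)
  expect_equal(nrow(out$cells) +
                 sum(out$report$per_cell$outcome == "rejected"), n_cells)
  expect_equal(sum(out$report$per_cell$outcome == "retained"),
               nrow(out$cells))
})

test_that("planted defect labels are recovered exactly, cell by cell", {
  sim <- default_sim()
  out <- pair_cells(sim$rearrangements, sim$expression)
  truth <- sim$truth$cells
  reason_for <- c(stop_codon = "stop_codon", ambiguous_nt = "ambiguous_nt",
                  short_v = "short_v", low_genes = "min_genes",
                  multiplet = "multiplet",
                  ambiguous_c_call = "ambiguous_c_call")
  rep <- out$report$per_cell
  for (defect in names(reason_for)) {
    planted <- sort(truth$cell_id[truth$defect == defect])
    hit <- vapply(strsplit(rep$reasons, ","), function(x) {
      reason_for[[defect]] %in% x
    }, logical(1))
    expect_equal(sort(rep$cell_id[hit]), planted, info = defect)
  }
  # cells with no planted defect are all retained
  clean <- truth$cell_id[truth$defect == "none"]
  expect_setequal(out$cells$cell_id, clean)
})

test_that("a defect-free repertoire is retained in full", {
  sim <- small_clean_sim()
  out <- pair_cells(sim$rearrangements, sim$expression)
  expect_equal(out$report$n_retained, out$report$n_input)
})
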