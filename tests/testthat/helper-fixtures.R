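# Shared fixtures, built in code at test time.

.fixture_env <- new.env(parent = emptyenv())

# One moderately sized simulated repertoire shared across tests
# (the generator's default study conditions, fixed seed).
default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_repertoire(simulation_config(seed = 101L))
  }
  .fixture_env$sim
}

# A small clean repertoire (no planted defects) for fast tests.
small_clean_sim <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_repertoire(simulation_config(
      n_subjects = 3L, cells_per_subject = 40L, n_public_families = 2L,
      n_private_families = 10L,
      defect_rates = c(stop_codon = 0, ambiguous_nt = 0, short_v = 0,
                       low_genes = 0, multiplet = 0, ambiguous_c_call = 0),
      n_genes = 800L, seed = 202L))
  }
  .fixture_env$small
}

# Hand-built canonical rearrangement record that passes every sequence
# criterion; fields overridable.
make_rec <- function(cell_id = "c1", subject_id = "S1", sample_id = "S1-1",
                     locus = "IGH", v_call = "IGHV1-1*01",
                     j_call = "IGHJ1*01",
                     cdr3_nt = "GCTAGGGATTGG",  # "ARDW"
                     v_sequence_length = 300L, productive = TRUE,
                     c_call = if (locus == "IGH") "IGHE" else "IGKC",
                     frame_offset = 0L, sequence = NULL,
                     cdr3_aa = NULL, v_germline = NULL) {
  germ <- toy_germline()
  v <- if (locus == "IGH") germ$IGH$V[[1]] else germ$IGK$V[[1]]
  j <- if (locus == "IGH") germ$IGH$J[[1]] else germ$IGK$J[[1]]
  if (is.null(sequence)) sequence <- paste0(v, cdr3_nt, j)
  if (is.null(cdr3_aa)) cdr3_aa <- clonverge:::translate_dna(cdr3_nt)
  if (is.null(v_germline)) v_germline <- v
  data.frame(cell_id = cell_id, subject_id = subject_id,
             sample_id = sample_id, locus = locus, v_call = v_call,
             j_call = j_call, sequence = sequence, sequence_aa = "",
             junction_aa = "", cdr3_aa = cdr3_aa, cdr3_nt = cdr3_nt,
             v_sequence_length = v_sequence_length,
             v_germline = v_germline, productive = productive,
             c_call = c_call, frame_offset = frame_offset,
             row.names = NULL)
}

# Minimal expression matrix giving every listed cell `n_genes` expressed
# genes (PRDM1 and MS4A1 included in the universe).
make_expr <- function(cell_ids, n_genes = 600L, total_genes = 800L) {
  m <- matrix(0L, total_genes, length(cell_ids),
              dimnames = list(c("PRDM1", "MS4A1",
                                sprintf("G%04d", seq_len(total_genes - 2L))),
                              cell_ids))
  if (length(n_genes) == 1L) n_genes <- rep(n_genes, length(cell_ids))
  for (j in seq_along(cell_ids)) m[seq_len(n_genes[j]), j] <- 1L
  m
}

# A paired-cell data frame (as produced by pair_cells) built directly,
# for clustering tests that need exact CDR3 control.
make_cells <- function(cdr3s, subjects = NULL, cell_ids = NULL,
                       v_call = "IGHV1-1*01", j_call = "IGHJ1*01") {
  n <- length(cdr3s)
  if (is.null(subjects)) subjects <- rep("S1", n)
  if (is.null(cell_ids)) cell_ids <- sprintf("c%03d", seq_len(n))
  data.frame(cell_id = cell_ids, subject_id = subjects,
             sample_id = paste0(subjects, "-1"), isotype = "IgE",
             n_genes_expressed = 600L,
             heavy_v_call = v_call, heavy_j_call = j_call,
             heavy_cdr3_aa = cdr3s, heavy_cdr3_nt = strrep("NNN", nchar(cdr3s)),
             heavy_sequence_aa = paste0("MA", cdr3s),
             light_sequence_aa = paste0("ML", cdr3s),
             row.names = NULL)
}
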