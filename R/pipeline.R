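# End-to-end orchestration: qc -> cluster -> metrics -> state, with a
# machine-readable run manifest.

#' Run the full repertoire pipeline
#'
#' Executes QC, clonal-family construction with convergence annotation,
#' sequence metrics (VH/VL edit-distance matrices, SHM table, CDR3 logo
#' PFMs for convergent families) and cell-state classification, writing
#' every stage output as TSV/JSON under `out_dir` together with a run
#' manifest (tool version, effective config, input digests, per-stage row
#' counts, seed, timestamps). Any stage failure aborts with a partial
#' manifest marking the failed stage; completed outputs are preserved.
#'
#' @param rearrangements_path AIRR-style TSV (see [read_rearrangements()]).
#' @param expression_path Count matrix TSV/MTX
#'   (see [read_expression_matrix()]).
#' @param out_dir Output directory (created if needed).
#' @param dialect Rearrangement dialect.
#' @param min_genes,min_v_length QC thresholds (see [qc_config()]).
#' @param threshold,linkage,on Clustering parameters
#'   (see [build_clonal_families()]).
#' @param state_method Cell-state method (see [classify_state()]).
#' @param seed Seed used by seeded stages (k-means).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(rearrangements_path, expression_path, out_dir,
                         dialect = "airr", min_genes = 500L,
                         min_v_length = 250L, threshold = 0.70,
                         linkage = "single", on = "aa",
                         state_method = "marker_rule", seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(dialect = dialect, min_genes = min_genes,
              min_v_length = min_v_length, threshold = threshold,
              linkage = linkage, on = on, state_method = state_method,
              seed = seed)
  manifest <- list(
    tool = "clonverge", version = as.character(packageVersion("clonverge")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    inputs = list(
      rearrangements = list(path = rearrangements_path,
                            md5 = unname(tools::md5sum(rearrangements_path))),
      expression = list(path = expression_path,
                        md5 = unname(tools::md5sum(expression_path)))),
    stages = list())
  write_manifest <- function() {
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    res
  }

  inputs <- run_stage("read", function() {
    reads <- read_rearrangements(rearrangements_path, dialect = dialect)
    expr <- read_expression_matrix(expression_path)
    list(reads = reads, expr = expr)
  })
  manifest$stages$read <- list(
    status = "ok", n_records = nrow(inputs$reads$records),
    n_rejected_rows = nrow(inputs$reads$rejects),
    n_expression_cells = ncol(inputs$expr))

  qc <- run_stage("qc", function() {
    out <- pair_cells(inputs$reads$records, inputs$expr,
                      qc_config(min_genes, min_v_length))
    write.table(out$cells, file.path(out_dir, "cells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_qc_report(out$report, file.path(out_dir, "qc_report.tsv"),
                    file.path(out_dir, "qc_summary.json"))
    out
  })
  manifest$stages$qc <- list(status = "ok",
                             n_input_cells = qc$report$n_input,
                             n_retained = qc$report$n_retained)

  cf <- run_stage("cluster", function() {
    cf <- annotate_convergence(
      build_clonal_families(qc$cells, threshold = threshold,
                            linkage = linkage, on = on))
    write.table(cf$cells[, c("cell_id", "subject_id", "sample_id",
                             "cf_id", "isotype")],
                file.path(out_dir, "cf_membership.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cf$families, file.path(out_dir, "cf_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cf$persistence, file.path(out_dir, "cf_persistence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_families = nrow(cf$families),
           n_convergent = sum(cf$families$is_convergent),
           threshold = threshold, linkage = linkage, on = on),
      file.path(out_dir, "cf_stats.json"), auto_unbox = TRUE, digits = NA)
    cf
  })
  manifest$stages$cluster <- list(
    status = "ok", n_cells = nrow(cf$cells),
    n_families = nrow(cf$families),
    n_convergent = sum(cf$families$is_convergent))

  metrics <- run_stage("metrics", function() {
    shm <- shm_table(qc$cells)
    write.table(shm, file.path(out_dir, "shm.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    # clustermap-style distance matrices over the cells of convergent
    # families (the deep-characterization set), not the whole repertoire
    conv <- cf$families$cf_id[cf$families$is_convergent]
    conv_cells <- cf$cells[cf$cells$cf_id %in% conv, , drop = FALSE]
    if (nrow(conv_cells) >= 2L) {
      for (ch in c("VH", "VL")) {
        dm <- distance_matrix(conv_cells, chain = ch)
        df <- data.frame(cell_id = dm$labels, dm$values,
                         check.names = FALSE)
        write.table(df, file.path(out_dir, paste0("edit_distance_",
                                                  ch, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    for (id in conv) {
      pfm <- logo_pfm(cf$cells$heavy_cdr3_aa[cf$cells$cf_id == id])
      write_pfm(pfm, file.path(out_dir, paste0("pfm_", id, "_VH.tsv")))
    }
    list(shm = shm, n_pfms = length(conv))
  })
  manifest$stages$metrics <- list(status = "ok",
                                  n_shm_rows = nrow(metrics$shm),
                                  n_logo_pfms = metrics$n_pfms)

  states <- run_stage("state", function() {
    st <- classify_state(inputs$expr, method = state_method, seed = seed)
    write.table(st, file.path(out_dir, "cell_state.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    st
  })
  manifest$stages$state <- list(
    status = "ok", n_cells = nrow(states),
    n_plasmablast = sum(states$state == "plasmablast"))

  invisible(write_manifest())
}
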