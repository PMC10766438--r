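# Cell- and sequence-level retention criteria.
#
# A cell is retained iff it has at least the configured number of expressed
# genes and a single productive heavy/light pair in which both chains pass
# all sequence criteria: V segment longer than the minimum, no stop codon
# before the junction end, no ambiguous nucleotides, an in-frame CDR3
# consistent with its translation, an unambiguous constant region, and a
# productive rearrangement call.

# c_call prefix -> isotype (heavy); light-chain constants map to "light".
.isotype_map <- c(
  IGHE = "IgE", IGHG = "IgG", IGHA = "IgA", IGHM = "IgM", IGHD = "IgD",
  IGKC = "light", IGLC = "light"
)

.c_call_isotypes <- function(c_call) {
  parts <- trimws(strsplit(as.character(c_call), ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  iso <- vapply(parts, function(p) {
    hit <- which(startsWith(p, names(.isotype_map)))
    if (length(hit)) .isotype_map[[hit[1]]] else "other"
  }, character(1))
  unique(iso)
}

#' QC configuration
#'
#' @param min_genes Minimum number of expressed genes per cell (default 500).
#' @param min_v_length V segment length must be strictly greater than this
#'   many nucleotides (default 250).
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes = 500L, min_v_length = 250L) {
  structure(list(min_genes = as.integer(min_genes),
                 min_v_length = as.integer(min_v_length)),
            class = "qc_config")
}

#' Sequence-level QC verdicts
#'
#' Evaluates every retention criterion for each rearrangement record and
#' reports all failures, not just the first. Reason codes: `short_v`,
#' `stop_codon`, `ambiguous_nt`, `cdr3_frame`, `ambiguous_c_call`,
#' `nonproductive`.
#'
#' The stop-codon scan covers the variable-region translation up to the end
#' of the junction (constant-region trailers, which some assemblers append,
#' are ignored).
#'
#' @param records Rearrangement data frame (canonical columns).
#' @param config A [qc_config()].
#' @return Data frame with `pass` (logical) and `reasons`
#'   (comma-separated codes, empty when passing), one row per record.
#' @export
check_sequence <- function(records, config = qc_config()) {
  n <- nrow(records)
  short_v <- is.na(records$v_sequence_length) |
    records$v_sequence_length <= config$min_v_length
  ambiguous <- grepl("[^ACGT]", records$sequence)

  # stop-codon scan: translate up to junction end when the CDR3 can be
  # located in the contig, otherwise the whole sequence
  scan_nt <- records$sequence
  for (i in seq_len(n)) {
    if (!nzchar(records$cdr3_nt[i])) next
    pos <- regexpr(records$cdr3_nt[i], records$sequence[i], fixed = TRUE)
    if (pos > 0) {
      scan_nt[i] <- substr(records$sequence[i], 1L,
                           pos + attr(pos, "match.length") - 1L + 3L)
    }
  }
  stop_codon <- grepl("*", translate_dna(scan_nt, records$frame_offset),
                      fixed = TRUE)

  translatable <- nzchar(records$cdr3_nt) &
    nchar(records$cdr3_nt) %% 3L == 0L & !grepl("[^ACGT]", records$cdr3_nt)
  cdr3_trans <- character(n)
  cdr3_trans[translatable] <- translate_dna(records$cdr3_nt[translatable])
  cdr3_frame <- !(translatable & cdr3_trans == records$cdr3_aa)

  ambiguous_c <- vapply(records$c_call, function(cc) {
    length(.c_call_isotypes(cc)) != 1L
  }, logical(1), USE.NAMES = FALSE)
  nonproductive <- !records$productive

  fails <- cbind(short_v = short_v, stop_codon = stop_codon,
                 ambiguous_nt = ambiguous, cdr3_frame = cdr3_frame,
                 ambiguous_c_call = ambiguous_c,
                 nonproductive = nonproductive)
  reasons <- apply(fails, 1, function(f) {
    paste(colnames(fails)[f], collapse = ",")
  })
  data.frame(pass = rowSums(fails) == 0L, reasons = unname(reasons),
             row.names = NULL)
}

#' Pair heavy and light chains into QC-passing cells
#'
#' A cell is retained iff it has exactly one passing heavy (IGH) and
#' exactly one passing light (IGK/IGL) chain and at least `min_genes`
#' expressed genes. Cells with two or more passing chains of the same
#' class are rejected as `multiplet`; cells absent from the expression
#' matrix as `no_expression`. A rejected cell's reasons include the
#' sequence-level failure codes of its failing chains.
#'
#' @param records Rearrangement data frame (canonical columns).
#' @param expression Gene-by-cell count matrix
#'   (see [read_expression_matrix()]).
#' @param config A [qc_config()].
#' @return List with `cells` — one row per retained cell, heavy/light
#'   fields prefixed `heavy_` / `light_`, plus `isotype`,
#'   `n_genes_expressed` — and `report`, a `qc_report` with per-cell
#'   outcomes and per-reason tallies.
#' @export
pair_cells <- function(records, expression, config = qc_config()) {
  stopifnot(is.data.frame(records), is.matrix(expression))
  verdicts <- check_sequence(records, config)
  expr_sum <- expression_summary(expression)
  n_genes <- setNames(expr_sum$n_genes_expressed, expr_sum$cell_id)

  cell_ids <- unique(records$cell_id)
  cells <- list()
  outcome <- character(length(cell_ids))
  cell_reasons <- character(length(cell_ids))

  for (k in seq_along(cell_ids)) {
    id <- cell_ids[k]
    idx <- which(records$cell_id == id)
    heavy_i <- idx[records$locus[idx] == "IGH"]
    light_i <- idx[records$locus[idx] %in% c("IGK", "IGL")]
    heavy_pass <- heavy_i[verdicts$pass[heavy_i]]
    light_pass <- light_i[verdicts$pass[light_i]]

    codes <- character(0)
    chain_fail <- setdiff(idx, c(heavy_pass, light_pass))
    if (length(chain_fail)) {
      codes <- unique(unlist(strsplit(verdicts$reasons[chain_fail], ",")))
      codes <- codes[nzchar(codes)]
    }
    if (length(heavy_pass) > 1L || length(light_pass) > 1L) {
      codes <- c(codes, "multiplet")
    }
    if (length(heavy_pass) == 0L) codes <- c(codes, "no_heavy")
    if (length(light_pass) == 0L) codes <- c(codes, "no_light")
    if (!id %in% names(n_genes)) {
      codes <- c(codes, "no_expression")
    } else if (n_genes[[id]] < config$min_genes) {
      codes <- c(codes, "min_genes")
    }

    retained <- length(heavy_pass) == 1L && length(light_pass) == 1L &&
      id %in% names(n_genes) && n_genes[[id]] >= config$min_genes &&
      !"multiplet" %in% codes
    if (retained) {
      h <- records[heavy_pass, ]; l <- records[light_pass, ]
      cells[[length(cells) + 1L]] <- data.frame(
        cell_id = id, subject_id = h$subject_id, sample_id = h$sample_id,
        isotype = .c_call_isotypes(h$c_call),
        n_genes_expressed = n_genes[[id]],
        heavy_v_call = h$v_call, heavy_j_call = h$j_call,
        heavy_sequence = h$sequence, heavy_frame_offset = h$frame_offset,
        heavy_sequence_aa = h$sequence_aa,
        heavy_cdr3_aa = h$cdr3_aa, heavy_cdr3_nt = h$cdr3_nt,
        heavy_v_sequence_length = h$v_sequence_length,
        heavy_v_germline = h$v_germline, heavy_c_call = h$c_call,
        light_v_call = l$v_call, light_j_call = l$j_call,
        light_locus = l$locus, light_sequence = l$sequence,
        light_frame_offset = l$frame_offset,
        light_sequence_aa = l$sequence_aa,
        light_cdr3_aa = l$cdr3_aa, light_cdr3_nt = l$cdr3_nt,
        light_v_sequence_length = l$v_sequence_length,
        light_v_germline = l$v_germline,
        row.names = NULL)
      outcome[k] <- "retained"
      cell_reasons[k] <- ""
    } else {
      outcome[k] <- "rejected"
      cell_reasons[k] <- paste(unique(codes), collapse = ",")
    }
  }

  per_cell <- data.frame(cell_id = cell_ids, outcome = outcome,
                         reasons = cell_reasons, row.names = NULL)
  rejected <- per_cell[per_cell$outcome == "rejected", ]
  all_codes <- unlist(strsplit(rejected$reasons, ","))
  all_codes <- all_codes[nzchar(all_codes)]
  tallies <- if (length(all_codes)) {
    as.data.frame(table(reason = all_codes), stringsAsFactors = FALSE)
  } else {
    data.frame(reason = character(0), Freq = integer(0))
  }
  names(tallies) <- c("reason", "n_cells")

  report <- structure(
    list(per_cell = per_cell, tallies = tallies,
         n_input = length(cell_ids), n_retained = sum(outcome == "retained"),
         config = config),
    class = "qc_report")
  cells <- do.call(rbind, cells) %||% data.frame()
  if (nrow(cells)) {
    # derive missing variable-region translations in one batch
    need <- !nzchar(cells$heavy_sequence_aa)
    cells$heavy_sequence_aa[need] <-
      translate_dna(cells$heavy_sequence[need],
                    cells$heavy_frame_offset[need])
    need <- !nzchar(cells$light_sequence_aa)
    cells$light_sequence_aa[need] <-
      translate_dna(cells$light_sequence[need],
                    cells$light_frame_offset[need])
  }
  list(cells = cells, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_retained, "of", x$n_input, "cells retained\n")
  cat("thresholds: min_genes =", x$config$min_genes,
      "| min V length >", x$config$min_v_length, "nt\n")
  if (nrow(x$tallies)) {
    cat("reject reasons (cells may carry several):\n")
    print(x$tallies, row.names = FALSE)
  }
  invisible(x)
}

#' Write a QC report as TSV (per-cell) plus JSON summary
#'
#' @param report A `qc_report` from [pair_cells()].
#' @param tsv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_qc_report <- function(report, tsv_path, json_path) {
  write.table(report$per_cell, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(n_input = report$n_input, n_retained = report$n_retained,
         thresholds = unclass(report$config),
         tallies = report$tallies),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}
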