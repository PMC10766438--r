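# AIRR rearrangement tables, count matrices and FASTA: read, write, validate.
#
# Canonical rearrangement columns used throughout the package (one row per
# chain per cell):
#   cell_id, subject_id, sample_id, locus, v_call, j_call, sequence,
#   sequence_aa, junction_aa, cdr3_aa, cdr3_nt, v_sequence_length,
#   v_germline, productive, c_call, frame_offset
# All positional outputs written by this package are 0-based, half-open.

.canonical_cols <- c(
  "cell_id", "subject_id", "sample_id", "locus", "v_call", "j_call",
  "sequence", "sequence_aa", "junction_aa", "cdr3_aa", "cdr3_nt",
  "v_sequence_length", "v_germline", "productive", "c_call", "frame_offset"
)

# Columns that must carry a non-empty value for a row to be accepted.
.required_fields <- c("cell_id", "subject_id", "locus", "v_call", "j_call",
                      "sequence", "cdr3_nt", "v_sequence_length")

# AIRR standard name -> canonical name (applied after canonical names,
# so a file in either convention reads identically).
.airr_aliases <- c(
  sequence_nt = "sequence", cdr3 = "cdr3_nt",
  germline_alignment = "v_germline", v_germline_nt = "v_germline",
  v_sequence_length_nt = "v_sequence_length"
)

#' Read an AIRR-style rearrangement table
#'
#' Reads a tab-separated rearrangement table (one row per chain per cell)
#' into the package's canonical column set. Rows missing a required field
#' are not silently dropped: they are returned in a `rejects` data frame
#' with one reason per missing field.
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect `"airr"` accepts AIRR Rearrangement column names and
#'   their canonical equivalents; `"minimal"` requires exactly the columns
#'   the pipeline strictly needs (`cell_id`, `subject_id`, `locus`,
#'   `v_call`, `j_call`, `sequence`, `cdr3_nt`, `v_sequence_length`,
#'   `productive`).
#' @return A list with `records` (data frame in canonical columns) and
#'   `rejects` (data frame with `row`, `cell_id`, `reason`).
#' @export
read_rearrangements <- function(path, dialect = c("airr", "minimal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read rearrangement file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, na.strings = NULL)
  # map AIRR-standard names onto canonical ones
  nm <- names(df)
  hit <- nm %in% names(.airr_aliases) & !(.airr_aliases[nm] %in% nm)
  nm[hit] <- .airr_aliases[nm[hit]]
  names(df) <- nm

  required_cols <- if (dialect == "minimal") {
    c(.required_fields, "productive")
  } else {
    c("cell_id", "locus", "v_call", "j_call", "sequence", "cdr3_nt")
  }
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols)) {
    stop("rearrangement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(.canonical_cols, names(df))) df[[col]] <- ""
  df <- df[.canonical_cols]

  # field-level validation: every missing required field is a reject reason
  rejects <- data.frame(row = integer(0), cell_id = character(0),
                        reason = character(0))
  bad <- rep(FALSE, nrow(df))
  for (field in .required_fields) {
    miss <- is.na(df[[field]]) | !nzchar(trimws(df[[field]]))
    if (any(miss)) {
      rejects <- rbind(rejects, data.frame(
        row = which(miss), cell_id = df$cell_id[miss],
        reason = paste0("missing ", field)))
      bad <- bad | miss
    }
  }
  rec <- df[!bad, , drop = FALSE]
  rownames(rec) <- NULL

  rec$v_sequence_length <- as.integer(rec$v_sequence_length)
  rec$frame_offset <- ifelse(nzchar(rec$frame_offset),
                             as.integer(rec$frame_offset), 0L)
  rec$productive <- toupper(rec$productive) %in% c("T", "TRUE", "1", "YES")
  rec$sequence <- toupper(rec$sequence)
  rec$cdr3_nt <- toupper(rec$cdr3_nt)
  rec$v_germline <- toupper(rec$v_germline)
  # derive aa fields when absent
  need_aa <- !nzchar(rec$cdr3_aa) & nzchar(rec$cdr3_nt) &
    nchar(rec$cdr3_nt) %% 3L == 0L
  if (any(need_aa)) rec$cdr3_aa[need_aa] <- translate_dna(rec$cdr3_nt[need_aa])
  # AIRR convention: CDR3 is the junction minus the two anchor residues
  from_junction <- !nzchar(rec$cdr3_aa) & nchar(rec$junction_aa) > 2L
  if (any(from_junction)) {
    j <- rec$junction_aa[from_junction]
    rec$cdr3_aa[from_junction] <- substr(j, 2L, nchar(j) - 1L)
  }
  rejects <- rejects[order(rejects$row), , drop = FALSE]
  rownames(rejects) <- NULL
  list(records = rec, rejects = rejects)
}

#' Write a rearrangement table
#'
#' Inverse of [read_rearrangements()]: writes canonical columns as TSV.
#' Coordinates in any positional column are 0-based, half-open.
#'
#' @param records Data frame of rearrangements in canonical columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  missing_cols <- setdiff(.canonical_cols, names(records))
  if (length(missing_cols)) {
    stop("records lack canonical column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  write.table(records[.canonical_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-cell count matrix
#'
#' Accepts either a dense TSV (genes as rows, first column gene symbols,
#' remaining columns cells) or a MatrixMarket `.mtx` triplet with sibling
#' `<path>.rows` / `<path>.cols` label files. Entries must be non-negative
#' integers.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix, genes x cells, with dimnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read count matrix: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "%%MatrixMarket")) {
    m <- as.matrix(Matrix::readMM(path))
    rows_f <- paste0(path, ".rows"); cols_f <- paste0(path, ".cols")
    if (!file.exists(rows_f) || !file.exists(cols_f)) {
      stop("MTX matrix requires label files ", rows_f, " and ", cols_f)
    }
    dimnames(m) <- list(readLines(rows_f), readLines(cols_f))
  } else {
    df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "count matrix entry at gene '%s', cell '%s' is not a non-negative integer",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a gene-by-cell count matrix
#'
#' @param m Integer matrix, genes x cells, with dimnames.
#' @param path Output path; a `.mtx` extension selects MatrixMarket triplet
#'   format (with `<path>.rows` / `<path>.cols` label files), anything else
#'   a dense TSV whose first column is `gene`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), paste0(path, ".rows"))
    writeLines(colnames(m), paste0(path, ".cols"))
  } else {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Per-cell expression summary
#'
#' @param m Count matrix from [read_expression_matrix()].
#' @return Data frame with `cell_id`, `n_genes_expressed` (genes with
#'   count > 0) and `total_counts`.
#' @export
expression_summary <- function(m) {
  data.frame(cell_id = colnames(m),
             n_genes_expressed = as.integer(colSums(m > 0)),
             total_counts = as.integer(colSums(m)),
             row.names = NULL)
}

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased; `X` is permitted but flagged with a warning.
#' Duplicate ids are an error.
#'
#' @param path FASTA file path.
#' @return Named character vector (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(grepl("X", seqs, fixed = TRUE))) {
    warning("FASTA contains 'X' residues")
  }
  seqs
}

#' Write protein sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::BStringSet(toupper(as.character(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
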