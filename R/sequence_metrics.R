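# Pairwise edit distances, somatic hypermutation, aligned logo PFMs.

#' Levenshtein edit distance
#'
#' Unit-cost substitution/insertion/deletion distance between two
#' sequences (amino acids or nucleotides).
#'
#' @param a,b Character scalars.
#' @return Non-negative integer.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Pairwise edit-distance matrix over paired cells
#'
#' Computes the full symmetric Levenshtein matrix over the chosen chain's
#' amino-acid sequences (full variable region by default, CDR3 only on
#' request) and an ordering from average-linkage hierarchical clustering
#' for clustermap rendering. Ties are broken deterministically by sorting
#' cells by label before clustering.
#'
#' @param cells Paired-cell data frame from [pair_cells()] (>= 2 rows).
#' @param chain `"VH"` or `"VL"`.
#' @param region `"full"` (FR1-FR4 translation) or `"cdr3"`.
#' @return A `distance_matrix` object: `labels`, `values` (integer matrix),
#'   `chain`, `region`, and `order` (clustering leaf order).
#' @export
distance_matrix <- function(cells, chain = c("VH", "VL"),
                            region = c("full", "cdr3")) {
  chain <- match.arg(chain)
  region <- match.arg(region)
  stopifnot(nrow(cells) >= 2L)
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  col <- switch(paste(chain, region),
                "VH full" = "heavy_sequence_aa", "VH cdr3" = "heavy_cdr3_aa",
                "VL full" = "light_sequence_aa", "VL cdr3" = "light_cdr3_aa")
  seqs <- cells[[col]]
  missing <- !nzchar(seqs) | is.na(seqs)
  if (any(missing)) {
    stop("missing ", chain, " sequence for cell(s): ",
         paste(cells$cell_id[missing], collapse = ", "))
  }
  m <- utils::adist(seqs)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(cells$cell_id, cells$cell_id)
  hc <- hclust(as.dist(m), method = "average")
  structure(list(labels = cells$cell_id, values = m, chain = chain,
                 region = region, order = hc$order, hclust = hc),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("%s %s edit-distance matrix over %d cells (max %d aa)\n",
              x$chain, x$region, length(x$labels), max(x$values)))
  invisible(x)
}

#' @export
plot.distance_matrix <- function(x, ...) {
  stats::heatmap(x$values, Rowv = stats::as.dendrogram(x$hclust),
                 Colv = "Rowv", scale = "none",
                 main = paste(x$chain, "pairwise edit distance"), ...)
  invisible(x)
}

#' Somatic hypermutation estimates
#'
#' Position-wise nucleotide mismatch fraction between the observed V
#' segment and its germline alignment (IMGT-style percent mutation).
#' Positions with `N` in either string are excluded from numerator and
#' denominator. Cells lacking a germline get `NA` estimates, never zero.
#'
#' @param cells Paired-cell data frame from [pair_cells()].
#' @param chains Chains to evaluate, subset of `c("VH", "VL")`.
#' @return Data frame: `cell_id`, `chain`, `n_mismatches_nt`,
#'   `v_length_compared_nt`, `shm_fraction`.
#' @export
shm_table <- function(cells, chains = c("VH", "VL")) {
  rows <- list()
  for (ch in chains) {
    pre <- if (ch == "VH") "heavy_" else "light_"
    for (i in seq_len(nrow(cells))) {
      obs <- substr(cells[[paste0(pre, "sequence")]][i], 1L,
                    cells[[paste0(pre, "v_sequence_length")]][i])
      germ <- cells[[paste0(pre, "v_germline")]][i]
      est <- if (!nzchar(germ) || is.na(germ)) {
        list(n = NA_integer_, len = NA_integer_, f = NA_real_)
      } else {
        shm_estimate(obs, germ)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cells$cell_id[i], chain = ch,
        n_mismatches_nt = est$n, v_length_compared_nt = est$len,
        shm_fraction = est$f, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Somatic hypermutation of one V segment
#'
#' @param observed_v,germline_v Position-aligned nucleotide strings of
#'   equal length (case-insensitive).
#' @return List with `n` (mismatches), `len` (positions compared, `N`
#'   positions excluded) and `f` (mismatch fraction).
#' @export
shm_estimate <- function(observed_v, germline_v) {
  if (is.na(germline_v) || !nzchar(germline_v)) stop("no_germline")
  a <- strsplit(toupper(observed_v), "")[[1]]
  b <- strsplit(toupper(germline_v), "")[[1]]
  if (length(a) != length(b)) {
    stop("observed V and germline V are not position-aligned (",
         length(a), " vs ", length(b), " nt)")
  }
  usable <- a != "N" & b != "N"
  n <- sum(a[usable] != b[usable])
  len <- sum(usable)
  list(n = as.integer(n), len = as.integer(len),
       f = if (len > 0) n / len else NA_real_)
}

# Apply the center-gap policy: keep ceiling(L/2) left-anchored and
# floor(L/2) right-anchored residues, inserting gaps centrally up to
# `width`. Junction conservation is strongest at both ends, so the
# diverse center absorbs the gaps.
.center_gap_pad <- function(s, width) {
  L <- nchar(s)
  if (L >= width) return(s)
  keep_left <- ceiling(L / 2)
  paste0(substr(s, 1L, keep_left),
         strrep("-", width - L),
         substr(s, keep_left + 1L, L))
}

#' Position frequency matrix for aligned CDR3 logos
#'
#' Aligns sequences of unequal length by the chosen policy and tabulates
#' per-position residue frequencies, gap symbol included, so each column
#' sums to one.
#'
#' @param cdr3s Character vector (>= 1 sequence).
#' @param align `"center_gap"` (default; left-anchor the first half,
#'   right-anchor the second, gaps in the middle), `"left"` or `"right"`.
#' @return A `logo_pfm` object: `frequencies` (residues x positions
#'   matrix), `n_sequences`, `gap_fraction` per position, `align`.
#' @export
logo_pfm <- function(cdr3s, align = c("center_gap", "left", "right")) {
  align <- match.arg(align)
  stopifnot(length(cdr3s) >= 1L, all(nzchar(cdr3s)))
  width <- max(nchar(cdr3s))
  padded <- switch(align,
    center_gap = vapply(cdr3s, .center_gap_pad, character(1), width = width),
    left = sprintf("%-*s", width, cdr3s),
    right = sprintf("%*s", width, cdr3s))
  padded <- gsub(" ", "-", padded, fixed = TRUE)
  chars <- matrix(unlist(strsplit(unname(padded), "")), nrow = width)
  alphabet <- sort(unique(as.vector(chars)))
  freq <- vapply(seq_len(width), function(p) {
    tab <- table(factor(chars[p, ], levels = alphabet))
    as.numeric(tab) / length(cdr3s)
  }, numeric(length(alphabet)))
  freq <- matrix(freq, nrow = length(alphabet),
                 dimnames = list(alphabet, seq_len(width) - 1L))
  gap <- if ("-" %in% alphabet) freq["-", ] else rep(0, width)
  structure(list(frequencies = freq, n_sequences = length(cdr3s),
                 gap_fraction = unname(gap), align = align),
            class = "logo_pfm")
}

#' @export
print.logo_pfm <- function(x, ...) {
  cat(sprintf("PFM over %d sequences, %d positions (%s alignment)\n",
              x$n_sequences, ncol(x$frequencies), x$align))
  consensus <- rownames(x$frequencies)[apply(x$frequencies, 2, which.max)]
  cat("consensus:", paste(consensus, collapse = ""), "\n")
  invisible(x)
}

#' @export
plot.logo_pfm <- function(x, ...) {
  f <- x$frequencies
  np <- ncol(f)
  graphics::plot(NULL, xlim = c(0, np), ylim = c(0, 1), xaxs = "i",
                 xlab = "position (0-based)", ylab = "frequency",
                 xaxt = "n", main = "CDR3 logo (stacked frequencies)", ...)
  graphics::axis(1, at = seq_len(np) - 0.5, labels = seq_len(np) - 1L)
  for (p in seq_len(np)) {
    ys <- cumsum(sort(f[f[, p] > 0, p], decreasing = TRUE))
    res <- names(ys)
    y0 <- c(0, utils::head(ys, -1))
    for (k in seq_along(ys)) {
      graphics::rect(p - 1, y0[k], p, ys[k], col = "grey95", border = "grey70")
      graphics::text(p - 0.5, (y0[k] + ys[k]) / 2, res[k],
                     cex = 0.5 + 1.5 * (ys[k] - y0[k]))
    }
  }
  invisible(x)
}

#' Write a PFM as TSV for external logo renderers
#'
#' Rows are residues (gap as `-`), columns 0-based positions.
#'
#' @param pfm A `logo_pfm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(residue = rownames(pfm$frequencies), pfm$frequencies,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
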