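# Plasmablast vs naive/memory classification from expression counts.
#
# Two routes to the partition: a marker rule anchored directly on the
# plasmablast transcription factor PRDM1 and the naive/memory marker
# MS4A1 (CD20), and a confirmatory PCA + k-means route on log2(cpm + 1)
# of the top-variance genes.

# Case-insensitive gene lookup after stripping version suffixes
# (e.g. "PRDM1.2" or "prdm1" both resolve).
.find_gene <- function(m, symbol) {
  clean <- toupper(sub("\\.\\d+$", "", rownames(m)))
  hit <- which(clean == toupper(symbol))
  if (!length(hit)) stop("gene '", symbol, "' absent from count matrix")
  hit[1]
}

#' Counts-per-million normalization
#'
#' @param m Gene-by-cell count matrix; every cell must have positive
#'   total counts.
#' @return Numeric matrix of the same shape; each column sums to 1e6.
#' @export
cpm_normalize <- function(m) {
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop("empty_cell: zero total counts for cell(s) ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  }
  sweep(m, 2, totals, "/") * 1e6
}

#' Classify cells as plasmablast vs naive/memory
#'
#' `marker_rule` (default): a cell is a plasmablast iff
#' `log2(cpm(PRDM1)+1) > log2(cpm(MS4A1)+1)`, `unassigned` iff both
#' markers are zero; the margin is the signed log difference.
#' `pca_kmeans`: PCA (gene-mean centred, unscaled) on log2(cpm+1) of the
#' `n_top_genes` highest-variance genes, k-means with k = 2 on the first
#' two PCs under a fixed seed; the cluster with higher mean PRDM1
#' expression is labelled plasmablast and the margin is the difference of
#' distances to the two centroids.
#'
#' @param m Gene-by-cell count matrix (PRDM1 and MS4A1 must be present).
#' @param method `"marker_rule"` or `"pca_kmeans"`.
#' @param seed RNG seed for k-means (default 1); the caller's RNG state
#'   is untouched.
#' @param n_top_genes Number of top-variance genes for PCA (default 500).
#' @return Data frame: `cell_id`, `state`, `margin`, `log_cpm_prdm1`,
#'   `log_cpm_ms4a1`, `pc1`, `pc2` (PCs are `NA` for `marker_rule`).
#' @export
classify_state <- function(m, method = c("marker_rule", "pca_kmeans"),
                           seed = 1L, n_top_genes = 500L) {
  method <- match.arg(method)
  i_prdm1 <- .find_gene(m, "PRDM1")
  i_ms4a1 <- .find_gene(m, "MS4A1")
  cpm <- cpm_normalize(m)
  lp <- log2(cpm[i_prdm1, ] + 1)
  lm <- log2(cpm[i_ms4a1, ] + 1)

  out <- data.frame(cell_id = colnames(m), state = NA_character_,
                    margin = NA_real_, log_cpm_prdm1 = unname(lp),
                    log_cpm_ms4a1 = unname(lm),
                    pc1 = NA_real_, pc2 = NA_real_, row.names = NULL)

  if (method == "marker_rule") {
    out$state <- ifelse(lp == 0 & lm == 0, "unassigned",
                        ifelse(lp > lm, "plasmablast", "naive_memory"))
    out$margin <- lp - lm
    return(out)
  }

  if (ncol(m) < 2L) stop("pca_kmeans requires at least 2 cells")
  lc <- log2(cpm + 1)
  vars <- apply(lc, 1, stats::var)
  top <- order(vars, decreasing = TRUE)[seq_len(min(n_top_genes, nrow(lc)))]
  pca <- prcomp(t(lc[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  scores <- pca$x[, 1:2, drop = FALSE]
  km <- with_seed(seed, kmeans(scores, centers = 2L, nstart = 10L))
  pb_cluster <- which.max(tapply(lp, km$cluster, mean))
  out$state <- ifelse(km$cluster == pb_cluster, "plasmablast", "naive_memory")
  d <- vapply(1:2, function(k) {
    sqrt(rowSums(sweep(scores, 2, km$centers[k, ])^2))
  }, numeric(nrow(scores)))
  other <- if (pb_cluster == 1L) 2L else 1L
  out$margin <- d[, other] - d[, pb_cluster]
  out$pc1 <- unname(scores[, 1])
  out$pc2 <- unname(scores[, 2])
  out
}
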