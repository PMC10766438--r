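# Clonal family construction and cross-subject convergence.
#
# Cells are first grouped by shared heavy-chain V gene, J gene (allele
# suffixes stripped) and CDR3 length; within a group, members are assigned
# to the same clonal family when their CDR3 identity reaches the threshold
# (default 0.70, "70% or higher") under the configured linkage. A family
# whose members come from two or more subjects is convergent (public).

#' Position-wise CDR3 identity
#'
#' Fraction of matching positions between two equal-length sequences
#' (Hamming-based; no gaps — equal length is guaranteed upstream by the
#' clone-key grouping on CDR3 length).
#'
#' @param a,b Character scalars of equal, positive length.
#' @return Fraction in \[0, 1\].
#' @export
cdr3_identity <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) == 0L) {
    stop("cdr3_identity requires equal-length non-empty sequences")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

# All pairwise identities for equal-length sequences: 1 - hamming/len.
.identity_matrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = L)
  m <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      id <- mean(chars[, i] == chars[, j])
      m[i, j] <- id; m[j, i] <- id
    }
  }
  m
}

# Connected components of the >=threshold graph (single linkage),
# breadth-first, deterministic given input order.
.single_linkage_components <- function(identity, threshold) {
  n <- nrow(identity)
  adj <- identity >= threshold - 1e-9
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Build clonal families
#'
#' Partitions QC-passing cells into clonal families: grouping by heavy V
#' gene, heavy J gene and CDR3 length, then identity-threshold clustering
#' within each group. Family ids are deterministic and independent of
#' input order (cells are sorted by subject then cell id internally;
#' families are numbered by decreasing size, ties broken lexicographically).
#'
#' @param cells Paired-cell data frame from [pair_cells()].
#' @param threshold Minimum CDR3 identity for co-membership (default 0.70;
#'   a pair at exactly the threshold merges).
#' @param linkage `"single"` (connected components of the at-threshold
#'   graph; the standard clonotyping realization, default) or
#'   `"complete"` (every within-family pair must reach the threshold).
#' @param on Compute identity on amino-acid (`"aa"`, default) or
#'   nucleotide (`"nt"`) CDR3.
#' @return A `clonal_families` object: list with `cells` (input plus
#'   `cf_id`), `families` (per-family summary with convergence flags and
#'   consensus CDR3) and the clustering parameters.
#' @export
build_clonal_families <- function(cells, threshold = 0.70,
                                  linkage = c("single", "complete"),
                                  on = c("aa", "nt")) {
  linkage <- match.arg(linkage)
  on <- match.arg(on)
  stopifnot(is.data.frame(cells), nrow(cells) > 0)
  cells <- cells[order(cells$subject_id, cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL

  cdr3 <- if (on == "aa") cells$heavy_cdr3_aa else cells$heavy_cdr3_nt
  vh_v <- strip_allele(cells$heavy_v_call)
  vh_j <- strip_allele(cells$heavy_j_call)
  key <- paste(vh_v, vh_j, nchar(cdr3), sep = "|")

  member <- integer(nrow(cells))
  next_id <- 0L
  for (g in split(seq_along(key), key)) {
    if (length(g) == 1L) {
      member[g] <- next_id + 1L; next_id <- next_id + 1L; next
    }
    idm <- .identity_matrix(cdr3[g])
    cl <- if (linkage == "single") {
      .single_linkage_components(idm, threshold)
    } else {
      h <- hclust(as.dist(1 - idm), method = "complete")
      unname(cutree(h, h = 1 - threshold + 1e-9))
    }
    member[g] <- next_id + cl
    next_id <- next_id + max(cl)
  }

  # deterministic family numbering: by size desc, then first member's
  # subject/cell id (cells already sorted)
  sizes <- table(member)
  firsts <- tapply(seq_along(member), member, min)
  ord <- order(-as.integer(sizes[as.character(names(firsts))]),
               cells$subject_id[firsts], cells$cell_id[firsts])
  relabel <- setNames(seq_along(ord), names(firsts)[ord])
  cf_index <- relabel[as.character(member)]
  cells$cf_id <- sprintf("CF%04d", cf_index)

  fam_rows <- lapply(split(seq_len(nrow(cells)), cells$cf_id), function(ix) {
    subj <- sort(unique(cells$subject_id[ix]))
    iso <- table(cells$isotype[ix])
    data.frame(
      cf_id = cells$cf_id[ix[1]],
      vh_v_gene = vh_v[ix[1]], vh_j_gene = vh_j[ix[1]],
      cdr3_length = nchar(cells$heavy_cdr3_aa[ix[1]]),
      n_cells = length(ix),
      n_subjects = length(subj),
      subjects = paste(subj, collapse = ","),
      is_convergent = length(subj) >= 2L,
      isotype_composition = paste(sprintf("%s:%d", names(iso), iso),
                                  collapse = ","),
      consensus_cdr3_aa = consensus_cdr3(cells$heavy_cdr3_aa[ix]),
      row.names = NULL)
  })
  families <- do.call(rbind, fam_rows)
  families <- families[order(families$cf_id), , drop = FALSE]
  rownames(families) <- NULL

  structure(list(cells = cells, families = families, threshold = threshold,
                 linkage = linkage, on = on),
            class = "clonal_families")
}

#' Annotate convergence and clonal persistence
#'
#' Re-derives the convergence flag (a family is convergent iff its members
#' come from at least two subjects) and adds a per-family persistence
#' table listing, for each subject, the blood-draw samples that
#' contributed members — the support for longitudinal persistence claims.
#'
#' @param cf A `clonal_families` object.
#' @return The object with an added `persistence` data frame
#'   (`cf_id`, `subject_id`, `sample_ids`, `n_samples`).
#' @export
annotate_convergence <- function(cf) {
  stopifnot(inherits(cf, "clonal_families"))
  cells <- cf$cells
  keys <- unique(cells[, c("cf_id", "subject_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- cells$cf_id == keys$cf_id[i] & cells$subject_id == keys$subject_id[i]
    samples <- sort(unique(cells$sample_id[sel]))
    data.frame(cf_id = keys$cf_id[i], subject_id = keys$subject_id[i],
               sample_ids = paste(samples, collapse = ","),
               n_samples = length(samples), row.names = NULL)
  })
  persistence <- do.call(rbind, rows)
  persistence <- persistence[order(persistence$cf_id, persistence$subject_id), ]
  rownames(persistence) <- NULL
  n_subj <- tapply(cf$cells$subject_id, cf$cells$cf_id,
                   function(s) length(unique(s)))
  cf$families$n_subjects <- as.integer(n_subj[cf$families$cf_id])
  cf$families$is_convergent <- cf$families$n_subjects >= 2L
  cf$persistence <- persistence
  cf
}

#' Position-wise consensus CDR3
#'
#' Modal residue at each position; ties broken by alphabetical order.
#' All inputs must share one length (guaranteed within a clonal family).
#'
#' @param cdr3s Character vector of equal-length sequences.
#' @return Consensus sequence.
#' @export
consensus_cdr3 <- function(cdr3s) {
  stopifnot(length(cdr3s) >= 1L, length(unique(nchar(cdr3s))) == 1L)
  L <- nchar(cdr3s[1])
  chars <- matrix(unlist(strsplit(cdr3s, "")), nrow = L)
  paste(apply(chars, 1, function(col) {
    tab <- table(col)
    names(tab)[which.max(tab)]  # table is alphabetical; which.max takes first
  }), collapse = "")
}

#' @export
print.clonal_families <- function(x, ...) {
  cat("Clonal families:", nrow(x$families), "families over",
      nrow(x$cells), "cells\n")
  cat(sprintf("threshold %.2f (%s identity, %s linkage)\n",
              x$threshold, x$on, x$linkage))
  conv <- x$families[x$families$is_convergent, ]
  cat(nrow(conv), "convergent (multi-subject) families\n")
  if (nrow(conv)) {
    print(utils::head(conv[, c("cf_id", "n_cells", "n_subjects",
                               "consensus_cdr3_aa")], 10), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.clonal_families <- function(object, ...) {
  f <- object$families
  structure(list(
    n_families = nrow(f), n_cells = nrow(object$cells),
    n_convergent = sum(f$is_convergent),
    n_singletons = sum(f$n_cells == 1L),
    largest = f[which.max(f$n_cells), ],
    threshold = object$threshold, linkage = object$linkage, on = object$on
  ), class = "summary.clonal_families")
}

#' @export
print.summary.clonal_families <- function(x, ...) {
  cat("families:", x$n_families, "| cells:", x$n_cells,
      "| convergent:", x$n_convergent, "| singletons:", x$n_singletons, "\n")
  cat("largest family:\n")
  print(x$largest, row.names = FALSE)
  invisible(x)
}
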