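# Linear epitope mapping: peptide tiling, repeat-motif scanning,
# signal projection and global homolog alignment.
#
# All coordinates are 0-based, half-open.

#' Tile a protein into overlapping k-mers
#'
#' Windows start at 0, offset, 2*offset, ... while `start + k <= L`,
#' emulating a linear peptide array (default 15-mers offset by 1).
#'
#' @param sequence Protein sequence (character scalar).
#' @param k Tile length (default 15).
#' @param offset Start-to-start distance (default 1).
#' @param id Parent protein id recorded on each tile.
#' @return Data frame: `parent_id`, `start` (0-based), `length`,
#'   `sequence`.
#' @export
tile_protein <- function(sequence, k = 15L, offset = 1L, id = "protein") {
  L <- nchar(sequence)
  if (k > L) stop("protein_too_short: length ", L, " < k = ", k)
  starts <- seq.int(0L, L - k, by = offset)
  data.frame(parent_id = id, start = starts, length = k,
             sequence = substring(sequence, starts + 1L, starts + k),
             row.names = NULL)
}

#' Scan a sequence for exact motif occurrences
#'
#' @param sequence Sequence to scan.
#' @param motif Non-empty exact motif.
#' @param allow_overlap Include overlapping occurrences (default TRUE).
#' @param id Parent id recorded on each hit.
#' @return Data frame: `parent_id`, `motif`, `start`, `end`
#'   (0-based, half-open).
#' @export
scan_motif <- function(sequence, motif, allow_overlap = TRUE,
                       id = "protein") {
  stopifnot(nzchar(motif))
  esc <- gsub("([^A-Za-z0-9])", "\\\\\\1", motif)
  pat <- if (allow_overlap) paste0("(?=", esc, ")") else esc
  m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
  starts <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  data.frame(parent_id = rep(id, length(starts)),
             motif = rep(motif, length(starts)), start = starts,
             end = starts + nchar(motif), row.names = NULL)
}

#' Project peptide-array signals onto residues
#'
#' Per-residue signal is the maximum over all tiles covering the residue
#' (a single strongly bound peptide suffices to localize an epitope).
#' Contiguous runs at or above `threshold_frac` of the maximum signal are
#' reported as candidate epitope intervals.
#'
#' @param tiles Data frame from [tile_protein()].
#' @param signals Numeric vector, one value per tile.
#' @param threshold_frac Interval threshold as a fraction of the profile
#'   maximum (default 0.5).
#' @return List: `profile` (per-residue numeric) and `intervals`
#'   (data frame `start`, `end`, 0-based half-open).
#' @export
map_array_signal <- function(tiles, signals, threshold_frac = 0.5) {
  if (length(signals) != nrow(tiles)) {
    stop("signals length (", length(signals),
         ") does not match tile count (", nrow(tiles), ")")
  }
  L <- max(tiles$start + tiles$length)
  profile <- rep(0, L)
  for (i in seq_len(nrow(tiles))) {
    span <- (tiles$start[i] + 1L):(tiles$start[i] + tiles$length[i])
    profile[span] <- pmax(profile[span], signals[i])
  }
  intervals <- if (max(profile) > 0) {
    runs_to_intervals(profile >= threshold_frac * max(profile))
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  list(profile = profile, intervals = intervals)
}

#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Optimal global alignment under match/mismatch/linear-gap scoring with
#' a deterministic traceback that prefers diagonal over a gap in `b`
#' over a gap in `a` at score ties. Intervals of `a` aligned entirely to
#' gaps in `b` are reported — these are the candidate regions unique to
#' `a` (e.g. the flexible loop present in Ara h 2 but absent from
#' Ara h 6).
#'
#' @param a,b Non-empty sequences.
#' @param match,mismatch,gap Scoring parameters (defaults +1, -1, -2).
#' @return An `alignment` object: `aligned_a`, `aligned_b` (equal-length
#'   gapped strings), `score`, `percent_identity` (matches over aligned
#'   columns), `unmatched_region_b` (data frame of `a` coordinates,
#'   0-based half-open, where `b` is gapped).
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nzchar(a), nzchar(b))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1] <- gap * 0:n
  S[1, ] <- gap * 0:m
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  # traceback, tie preference: diagonal > up (gap in b) > left (gap in a)
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
          S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  matches <- sum(ra == rb & ra != "-")
  # columns where a has a residue and b a gap, in a coordinates
  a_pos <- cumsum(ra != "-")
  b_gap_at_a <- rep(FALSE, n)
  b_gap_at_a[a_pos[ra != "-" & rb == "-"]] <- TRUE
  structure(list(
    aligned_a = paste(ra, collapse = ""),
    aligned_b = paste(rb, collapse = ""),
    score = S[n + 1L, m + 1L],
    percent_identity = matches / length(ra),
    unmatched_region_b = runs_to_intervals(b_gap_at_a)
  ), class = "alignment")
}

#' @export
print.alignment <- function(x, width = 60L, ...) {
  cat(sprintf("global alignment: score %g, identity %.1f%%\n",
              x$score, 100 * x$percent_identity))
  L <- nchar(x$aligned_a)
  for (s in seq(1L, L, by = width)) {
    e <- min(s + width - 1L, L)
    pa <- substr(x$aligned_a, s, e)
    pb <- substr(x$aligned_b, s, e)
    bar <- paste(ifelse(strsplit(pa, "")[[1]] == strsplit(pb, "")[[1]] &
                          strsplit(pa, "")[[1]] != "-", "|", " "),
                 collapse = "")
    cat(pa, "\n", bar, "\n", pb, "\n\n", sep = "")
  }
  if (nrow(x$unmatched_region_b)) {
    cat("regions of sequence a absent from b (0-based, half-open):\n")
    print(x$unmatched_region_b, row.names = FALSE)
  }
  invisible(x)
}

#' Write an alignment in plain gapped-pair text format
#'
#' @param aln An `alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(utils::capture.output(print(aln)), path)
  invisible(path)
}
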