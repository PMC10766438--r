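# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state (the global .Random.seed is saved and restored).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Strip allele suffix (text after "*") and keep the first gene of a
# multi-gene call: "IGHV3-30*01,IGHV3-30-3*02" -> "IGHV3-30".
strip_allele <- function(call) {
  first <- vapply(strsplit(as.character(call), ",", fixed = TRUE),
                  function(x) if (length(x)) x[[1]] else NA_character_,
                  character(1))
  sub("\\*.*$", "", trimws(first))
}

# Translate DNA to protein, frame offset in {0,1,2}; trailing partial
# codons are dropped; codons containing N translate to X. Vectorized:
# one Biostrings call for the whole batch.
translate_dna <- function(nt, frame_offset = 0L) {
  nt <- toupper(as.character(nt))
  n <- length(nt)
  if (n == 0L) return(character(0))
  off <- rep_len(as.integer(frame_offset), n)
  s <- substr(nt, off + 1L, nchar(nt))
  usable <- nchar(s) - nchar(s) %% 3L
  s <- substr(s, 1L, usable)
  out <- character(n)
  ok <- !is.na(usable) & usable >= 3L
  if (any(ok)) {
    out[ok] <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(s[ok]),
                            if.fuzzy.codon = "X")))
  }
  out
}

# Collapse a logical vector into 0-based half-open [start, end) runs of TRUE.
runs_to_intervals <- function(flag) {
  if (!any(flag)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
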