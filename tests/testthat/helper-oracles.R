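# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Levenshtein distance by the plain recursive definition (no DP).
lev_recursive <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  ta <- substr(a, 2, nchar(a))
  tb <- substr(b, 2, nchar(b))
  min(lev_recursive(ta, b) + 1L,
      lev_recursive(a, tb) + 1L,
      lev_recursive(ta, tb) + cost)
}

# Naive O(|s||m|) motif scanner returning 0-based starts.
scan_naive <- function(s, m) {
  L <- nchar(s); k <- nchar(m)
  starts <- integer(0)
  if (k > L) return(starts)
  for (i in 0:(L - k)) {
    if (substr(s, i + 1, i + k) == m) starts <- c(starts, i)
  }
  starts
}

# Connected components of the >=threshold identity graph via boolean
# transitive closure of the adjacency matrix (independent of the
# package's BFS).
components_closure <- function(seqs, threshold) {
  n <- length(seqs)
  A <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mean(strsplit(seqs[i], "")[[1]] == strsplit(seqs[j], "")[[1]]) >=
            threshold - 1e-9) {
        A[i, j] <- TRUE
      }
    }
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  match(apply(A, 1, paste, collapse = ""),
        unique(apply(A, 1, paste, collapse = "")))
}

# Replace the characters of `s` at 1-based positions `pos` with different
# letters from `alphabet` (substring<- does not vectorize over one string).
mutate_positions <- function(s, pos, alphabet = LETTERS[1:20]) {
  for (p in pos) {
    substr(s, p, p) <- sample(setdiff(alphabet, substr(s, p, p)), 1)
  }
  s
}

rand_aa <- function(L, alphabet = LETTERS[!LETTERS %in% c("B", "J", "O",
                                                          "U", "X", "Z")]) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

rand_nt <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                    replace = TRUE), collapse = "")
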