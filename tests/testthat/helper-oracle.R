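# Independent brute-force global alignment oracle (Gotoh affine-gap DP),
# kept deliberately separate from the package's alignment path. Scoring
# mirrors the package convention: a length-L gap costs open + extend * L.
oracle_align_score <- function(a, b, match = 1, mismatch = -1, open = 4, extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1)
  X <- matrix(neg, n + 1, m + 1) # gap in b (vertical)
  Y <- matrix(neg, n + 1, m + 1) # gap in a (horizontal)
  M[1, 1] <- 0
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -open - extend * (j - 1)
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -open - extend * (i - 1)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend, Y[i - 1, j] - open - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend, X[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# apply k random substitutions to a sequence, returning the mutant
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}
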