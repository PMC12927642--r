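# Independent brute-force oracles (plain-R Gotoh dynamic programming).
# Deliberately implemented without the package's alignment engine so that
# aligner tests compare two independent routes to the same score.
# Gap convention: a gap of length L costs gap_open + gap_extend * L.

oracle_align_score <- function(a, b, scheme = scoring_scheme(),
                               type = c("local", "global")) {
  type <- match.arg(type)
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  open <- scheme$gap_open + scheme$gap_extend  # first gap position
  ext <- scheme$gap_extend
  NEG <- -1e15
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in A (consumes B)
  F <- matrix(NEG, n + 1, m + 1)  # gap in B (consumes A)
  local <- type == "local"
  H[1, 1] <- 0
  if (local) {
    H[, 1] <- 0; H[1, ] <- 0
  } else {
    if (m >= 1) for (j in 2:(m + 1)) {
      E[1, j] <- max(H[1, j - 1] - open, E[1, j - 1] - ext)
      H[1, j] <- E[1, j]
    }
    if (n >= 1) for (i in 2:(n + 1)) {
      F[i, 1] <- max(H[i - 1, 1] - open, F[i - 1, 1] - ext)
      H[i, 1] <- F[i, 1]
    }
  }
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      sc <- H[i - 1, j - 1] + scheme$matrix[A[i - 1], B[j - 1]]
      H[i, j] <- max(sc, E[i, j], F[i, j], if (local) 0 else NEG)
    }
  }
  if (local) max(H) else H[n + 1, m + 1]
}

# exhaustive 1-D k-means oracle: try every contiguous partition of the
# sorted values and return the minimal total within-group SSE
oracle_kmeans1d_sse <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(sse(xs))
  cuts <- combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (cc in cuts) {
    bounds <- c(0, cc, n)
    tot <- 0
    for (g in seq_len(k))
      tot <- tot + sse(xs[(bounds[g] + 1):bounds[g + 1]])
    best <- min(best, tot)
  }
  best
}

kmeans1d_group_sse <- function(x, grp) {
  sum(vapply(split(x, grp), function(v) sum((v - mean(v))^2), 0))
}

# frozen NCBI BLOSUM62 (generated from an independent source and stored as
# a plain-text fixture); used as the oracle for substitution classification
load_blosum_fixture <- function() {
  tab <- read.delim(test_path("fixtures", "blosum62_ncbi.tsv"),
                    check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$res
  m
}

random_aa_string <- function(n, alphabet = c("A", "R", "N", "D")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
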