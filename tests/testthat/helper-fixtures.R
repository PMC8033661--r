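# Shared fixture builders (everything generated in code, nothing stored).

toy_records <- function(ids, seqs, moltype = "protein") {
  sequence_records(ids, seqs, moltype)
}

# small gapped seed alignment with noisy termini for trimming tests
toy_seed_alignment <- function() {
  c(s1 = "--ACDEFGHIK--",
    s2 = "G-ACDEFGHIR-W",
    s3 = "--ACDEWGHIK--")
}

# brute-force global alignment oracle: enumerate every global alignment of
# a and b, score under the package's gap convention
# (gap of length L costs gap_open + (L-1)*gap_extend), return best score
brute_force_global <- function(a, b, scoring = scoring_scheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, xa, xb) {
    if (i > length(A) && j > length(B)) {
      score <- 0
      run_a <- 0; run_b <- 0
      for (k in seq_along(xa)) {
        if (xa[k] == "-") {
          score <- score + if (run_a == 0) scoring$gap_open else
            scoring$gap_extend
          run_a <- run_a + 1; run_b <- 0
        } else if (xb[k] == "-") {
          score <- score + if (run_b == 0) scoring$gap_open else
            scoring$gap_extend
          run_b <- run_b + 1; run_a <- 0
        } else {
          score <- score + scoring$matrix[xa[k], xb[k]]
          run_a <- 0; run_b <- 0
        }
      }
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      rec(i + 1, j + 1, c(xa, A[i]), c(xb, B[j]))
    if (i <= length(A)) rec(i + 1, j, c(xa, A[i]), c(xb, "-"))
    if (j <= length(B)) rec(i, j + 1, c(xa, "-"), c(xb, B[j]))
  }
  rec(1, 1, character(0), character(0))
  best
}

# exhaustive hypergeometric tail oracle via binomial coefficients
hypergeom_greater_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}
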