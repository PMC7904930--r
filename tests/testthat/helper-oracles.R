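# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops, no shared helpers.

# Naive iterative correction: explicit row-sum loop until the relative
# variance of corrected row sums drops below tol. Returns mean-1 weights.
bruteIce <- function(C, tol = 1e-12, maxIter = 10000) {
  n <- nrow(C)
  w <- rep(1, n)
  for (it in seq_len(maxIter)) {
    rs <- numeric(n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        rs[i] <- rs[i] + w[i] * C[i, j] * w[j]
    mu <- mean(rs)
    if (var(rs) / mu^2 <= tol) break
    for (i in seq_len(n)) w[i] <- w[i] / (rs[i] / mu)
  }
  w / mean(w)
}

# Stratified Pearson with variance weights, computed with plain loops on
# the unsmoothed matrices (the h = 0 case of SCC).
bruteStratumScc <- function(A, B, maxK) {
  num <- 0; den <- 0
  n <- nrow(A)
  for (k in 0:maxK) {
    va <- vb <- numeric(n - k)
    for (i in seq_len(n - k)) {
      va[i] <- A[i, i + k]
      vb[i] <- B[i, i + k]
    }
    if (length(va) < 2) next
    if (sd(va) == 0 || sd(vb) == 0) next
    w <- length(va) * sd(va) * sd(vb)
    num <- num + w * cor(va, vb)
    den <- den + w
  }
  num / den
}

# Mean of diagonal d of a matrix, plain indexing.
diagMean <- function(M, d) {
  n <- nrow(M)
  mean(M[cbind(seq_len(n - d), seq_len(n - d) + d)])
}
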