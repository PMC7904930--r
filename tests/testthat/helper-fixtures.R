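# Shared fixture builders. Everything is generated in code; no data files.

# Random symmetric non-negative integer count matrix.
randomCounts <- function(n, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Wrap a plain matrix as a balanced ContactMatrix with unit weights
# (useful for noise-free expected maps and toys where the values are
# already coverage-uniform).
unitBalanced <- function(m, chrom = "toy", binSize = 1e4,
                         chromLength = nrow(m) * binSize) {
  ContactMatrix(m, chrom = chrom, binSize = binSize,
                chromLength = chromLength,
                weights = rep(1, nrow(m)), balanced = TRUE)
}

oneChromGenome <- function(len, chrom = "c") {
  data.frame(chrom = chrom, length = len)
}

# Fraction of reference positions with a called position within tol.
hitRate <- function(reference, called, tol) {
  if (!length(reference)) return(NA_real_)
  if (!length(called)) return(0)
  mean(vapply(reference, function(p) any(abs(called - p) <= tol), logical(1)))
}

# Compartment sign-flip positions (bp) of a +/-1 label vector.
flipPositions <- function(e, binSize) {
  which(diff(e) != 0) * binSize
}
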