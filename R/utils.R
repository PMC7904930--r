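## Internal numeric helpers.

## Evaluate expr with a temporary RNG state; restores the caller's stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Centered moving average with shrinking windows at the edges; NA-aware.
## w is the full window width (made odd by the caller).
.movAvg <- function(x, w) {
  if (w <= 1) return(x)
  half <- (w - 1) %/% 2
  n <- length(x)
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- cumsum(c(0, xs))
  cn <- cumsum(c(0, as.numeric(ok)))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  num <- cs[hi + 1] - cs[lo]
  den <- cn[hi + 1] - cn[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

## Per-diagonal sums and valid-pair counts of a (possibly NA-masked)
## symmetric matrix.  Returns data.frame(d, sum, n) for offsets 0..n-1.
.diagStats <- function(B) {
  n <- nrow(B)
  sums <- numeric(n)
  cnts <- numeric(n)
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    v <- B[cbind(i, i + d)]
    ok <- !is.na(v)
    sums[d + 1] <- sum(v[ok])
    cnts[d + 1] <- sum(ok)
  }
  data.frame(d = 0:(n - 1), sum = sums, n = cnts)
}

## Summed-area table for O(1) rectangle sums; NA treated as 0, with a
## companion count table so callers can form NA-aware means.
.satBuild <- function(B) {
  ok <- !is.na(B)
  Bz <- B
  Bz[!ok] <- 0
  S <- apply(apply(Bz, 2, cumsum), 1, cumsum)   # S[j, i]! transpose back
  S <- t(S)
  N <- t(apply(apply(ok * 1, 2, cumsum), 1, cumsum))
  list(S = rbind(0, cbind(0, S)), N = rbind(0, cbind(0, N)))
}

## Sum and count over rows r1..r2, cols c1..c2 (1-based, inclusive).
.satRect <- function(sat, r1, r2, c1, c2) {
  S <- sat$S; N <- sat$N
  s <- S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  n <- N[r2 + 1, c2 + 1] - N[r1, c2 + 1] - N[r2 + 1, c1] + N[r1, c1]
  c(sum = s, n = n)
}

## Observed/expected transform: divide each diagonal by its NA-aware mean.
## Returns a matrix with NA where the input is NA or the diagonal mean is 0.
.obsExp <- function(B) {
  n <- nrow(B)
  st <- .diagStats(B)
  mu <- ifelse(st$n > 0, st$sum / st$n, NA_real_)
  mu[mu == 0] <- NA_real_
  d <- abs(row(B) - col(B))
  OE <- B / matrix(mu[d + 1], n, n)
  OE
}

## Geometric distance grid: edges 10^(k/b) intersected with [smin, smax].
## Anchored at integer powers so the grid is data-independent.
.geomEdges <- function(smin, smax, binsPerDecade) {
  k0 <- floor(binsPerDecade * log10(smin))
  k1 <- ceiling(binsPerDecade * log10(smax))
  10^(seq(k0, k1) / binsPerDecade)
}
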