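## Replicate reproducibility: stratum-adjusted correlation coefficient.

## 2D mean filter with half-width h; shrinking windows at the matrix edges
## (mean over the cells actually available), NA-aware.
.smooth2d <- function(B, h) {
  if (h <= 0) return(B)
  sat <- .satBuild(B)
  n <- nrow(B); m <- ncol(B)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    r1 <- max(1, i - h); r2 <- min(n, i + h)
    lo <- pmax(1, seq_len(m) - h)
    hi <- pmin(m, seq_len(m) + h)
    ## row strip sums via SAT, vectorized over columns
    S <- sat$S; N <- sat$N
    s <- S[r2 + 1, hi + 1] - S[r1, hi + 1] - S[r2 + 1, lo] + S[r1, lo]
    k <- N[r2 + 1, hi + 1] - N[r1, hi + 1] - N[r2 + 1, lo] + N[r1, lo]
    v <- s / k
    v[k == 0] <- NA_real_
    out[i, ] <- v
  }
  out
}

#' Stratum-adjusted correlation coefficient (SCC) between two maps
#'
#' HiCRep-style reproducibility score: both matrices are smoothed with a
#' `(2h+1) x (2h+1)` mean filter (shrinking at the edges); for each stratum
#' `k` (diagonal offset with `k * resolution <= maxDist`) the Pearson
#' correlation `r_k` is computed over bin pairs present in both maps, and
#' the score is the variance-weighted mean
#' `scc = sum(w_k r_k) / sum(w_k)` with `w_k = N_k * sd(a_k) * sd(b_k)`.
#' Strata with zero variance in either map are skipped.
#'
#' @param a,b [ContactMatrix-class] objects on the same chromosome and
#'   binning.  Raw counts are used by default; set `useBalanced = TRUE` to
#'   compare balanced values (both matrices must then be balanced).
#' @param h smoothing half-width in bins.
#' @param maxDist maximal genomic distance (bp) of the strata.
#' @param useBalanced compare balanced values instead of raw counts.
#' @return an [SCCResult-class].
#' @export
scc <- function(a, b, h = 3L, maxDist = 5e6, useBalanced = FALSE) {
  if (chromName(a) != chromName(b) || binSize(a) != binSize(b) ||
      nbins(a) != nbins(b))
    stop("matrices disagree in chromosome, bin size or shape")
  res <- binSize(a)
  A <- if (useBalanced) balancedCounts(a) else contactCounts(a)
  B <- if (useBalanced) balancedCounts(b) else contactCounts(b)
  h <- as.integer(h)
  As <- .smooth2d(A, h)
  Bs <- .smooth2d(B, h)
  n <- nrow(As)
  kmax <- min(n - 1, floor(maxDist / res))
  rows <- list()
  for (k in 0:kmax) {
    i <- seq_len(n - k)
    va <- As[cbind(i, i + k)]
    vb <- Bs[cbind(i, i + k)]
    ok <- is.finite(va) & is.finite(vb)
    if (sum(ok) < 2) next
    va <- va[ok]; vb <- vb[ok]
    sa <- stats::sd(va); sb <- stats::sd(vb)
    if (sa == 0 || sb == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      distance = k * res, r = stats::cor(va, vb), N = sum(ok),
      weight = sum(ok) * sa * sb)
  }
  if (!length(rows)) stop("all strata degenerate; SCC undefined")
  strata <- do.call(rbind, rows)
  val <- sum(strata$weight * strata$r) / sum(strata$weight)
  new("SCCResult", scc = val, strata = strata, h = h,
      maxDist = as.numeric(maxDist), resolution = res)
}
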