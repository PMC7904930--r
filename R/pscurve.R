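## Contact-probability P(s) curves and their log-log derivatives.

#' Construct a PsCurve from explicit values
#'
#' Builds a curve object directly from per-distance contact frequencies —
#' useful for analytic curves and for feeding the band detector a known
#' shape.  `s` must be strictly increasing and equally spaced (the raw
#' diagonal grid of a binned matrix).
#'
#' @param s distances (bp), equally spaced.
#' @param P contact frequencies.
#' @param n pair counts per distance (default 1).
#' @param scope label, default `"custom"`.
#' @param binsPerDecade geometric-grid density for the binned view.
#' @return a [PsCurve-class].
#' @export
psCurve <- function(s, P, n = rep(1, length(s)), scope = "custom",
                    binsPerDecade = 10) {
  if (length(s) < 2) stop("need at least two distances")
  step <- diff(s)
  if (any(step <= 0)) stop("s must be strictly increasing")
  raw <- data.frame(s = s, P = P, n = n)
  new("PsCurve", scope = scope, binSize = step[1], raw = raw,
      binned = .binPs(raw, binsPerDecade))
}

## Aggregate a raw per-diagonal track onto the geometric grid.
.binPs <- function(raw, binsPerDecade) {
  raw <- raw[raw$s > 0 & raw$n > 0, , drop = FALSE]
  if (!nrow(raw))
    return(data.frame(s_lo = numeric(0), s_hi = numeric(0),
                      s_mid = numeric(0), P = numeric(0),
                      n_pairs = numeric(0)))
  edges <- .geomEdges(min(raw$s), max(raw$s), binsPerDecade)
  idx <- findInterval(raw$s, edges, rightmost.closed = FALSE)
  keep <- idx >= 1 & idx < length(edges)
  raw <- raw[keep, , drop = FALSE]
  idx <- idx[keep]
  agg <- function(v) tapply(v, idx, sum)
  sums <- agg(raw$P * raw$n)
  ns <- agg(raw$n)
  ## representative s: pair-weighted geometric mean of the member
  ## distances (bin-edge midpoints misplace sparse bins and bias the
  ## log-log derivative)
  slog <- agg(log(raw$s) * raw$n)
  k <- as.integer(names(ns))
  data.frame(s_lo = edges[k], s_hi = edges[k + 1],
             s_mid = exp(as.numeric(slog / ns)),
             P = as.numeric(sums / ns), n_pairs = as.numeric(ns),
             row.names = NULL)
}

#' Contact frequency as a function of genomic distance
#'
#' Computes P(s) from balanced contact matrices: for every raw diagonal the
#' mean balanced value over unmasked bin pairs, then aggregation onto a
#' geometric grid with `binsPerDecade` bins per decade.  Chromosomes shorter
#' than `minChromLength` are excluded.  The genome-average curve pools pairs
#' across passing chromosomes (pair-count weighted) before geometric
#' binning; per-chromosome curves are truncated at the chromosome length.
#'
#' @param matrices named list of balanced [ContactMatrix-class] (a single
#'   matrix is accepted).
#' @param minChromLength minimal chromosome length (bp) to contribute.
#' @param binsPerDecade geometric-grid density.
#' @return list with elements `genome` (a [PsCurve-class]) and `perChrom`
#'   (named list of per-chromosome [PsCurve-class]).
#' @export
computePs <- function(matrices, minChromLength = 9e6, binsPerDecade = 10) {
  if (is(matrices, "ContactMatrix")) {
    matrices <- stats::setNames(list(matrices), chromName(matrices))
  }
  pass <- vapply(matrices, function(m) chromLength(m) >= minChromLength,
                 logical(1))
  if (!any(pass))
    stop(sprintf("no chromosome longer than the %.1f Mb minimum-length filter",
                 minChromLength / 1e6))
  matrices <- matrices[pass]
  bs <- unique(vapply(matrices, binSize, numeric(1)))
  if (length(bs) != 1) stop("matrices must share a bin size")
  perChrom <- list()
  pool <- NULL
  for (m in matrices) {
    B <- balancedCounts(m)
    st <- .diagStats(B)
    st <- st[st$d > 0, , drop = FALSE]           # skip the s = 0 diagonal
    raw <- data.frame(s = st$d * bs,
                      P = ifelse(st$n > 0, st$sum / st$n, NA_real_),
                      n = st$n)
    raw <- raw[raw$s <= chromLength(m) & raw$n > 0, , drop = FALSE]
    perChrom[[chromName(m)]] <-
      new("PsCurve", scope = chromName(m), binSize = bs, raw = raw,
          binned = .binPs(raw, binsPerDecade))
    contrib <- data.frame(s = raw$s, sum = raw$P * raw$n, n = raw$n)
    pool <- if (is.null(pool)) contrib else rbind(pool, contrib)
  }
  sums <- tapply(pool$sum, pool$s, sum)
  ns <- tapply(pool$n, pool$s, sum)
  s <- as.numeric(names(sums))
  o <- order(s)
  raw <- data.frame(s = s[o], P = as.numeric(sums / ns)[o],
                    n = as.numeric(ns)[o])
  genome <- new("PsCurve", scope = "genome", binSize = bs, raw = raw,
                binned = .binPs(raw, binsPerDecade))
  list(genome = genome, perChrom = perChrom)
}

#' Log-log derivative of a P(s) curve
#'
#' Finite differences of `log10 P` against `log10 s` on the geometric grid,
#' evaluated at inter-bin midpoints (geometric mean of adjacent `s_mid`),
#' with optional moving-average smoothing.
#'
#' @param curve a [PsCurve-class].
#' @param smoothWindow moving-average window in grid bins (1 = none).
#' @return data.frame with columns `s` (midpoint, bp) and `dlogP`.
#' @export
psDerivative <- function(curve, smoothWindow = 1) {
  b <- psBinned(curve)
  b <- b[is.finite(b$P) & b$P > 0, , drop = FALSE]
  if (nrow(b) < 3) stop("need at least three positive P(s) bins for a derivative")
  lS <- log10(b$s_mid)
  lP <- log10(b$P)
  d <- diff(lP) / diff(lS)
  s <- sqrt(b$s_mid[-1] * b$s_mid[-nrow(b)])
  w <- max(1L, as.integer(smoothWindow))
  if (w %% 2 == 0) w <- w + 1L
  data.frame(s = s, dlogP = .movAvg(d, w))
}
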