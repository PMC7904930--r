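## Detection and localization of the second-diagonal (helical-turn) band.
##
## The band appears on P(s) as a local hump riding on the distance decay at
## s = T, the helical period.  Localization runs on the raw per-diagonal
## curve (the geometric plotting grid is too coarse to separate, say, 15
## from 17 Mb): smooth log10 P with a fixed-width moving average, subtract a
## two-point log-log chord baseline over the search range, and call the
## maximal interior local maximum of the residual.

#' Detect the second-diagonal band on a P(s) curve
#'
#' @param curve a [PsCurve-class] (raw per-diagonal track is used).
#' @param searchRange numeric(2): band search window in bp; clipped to the
#'   data extent with a warning when it reaches past the curve.
#' @param theta detection threshold on the residual (log10 units).
#' @param smooth moving-average width in bp applied to `log10 P` before
#'   baseline subtraction.
#' @param maxSpanFraction fraction of the curve extent the detector trusts:
#'   the search is confined to `s <= maxSpanFraction * max(s)`.  The last
#'   third of a chromosome's P(s) rests on few, strongly covarying bin
#'   pairs (chromosome ends, single compartment blocks) and routinely shows
#'   spurious upturns larger than a genuine band.
#' @return a [SecondDiagonalCall-class]; position ties break toward
#'   smaller `s`.
#' @export
detectSecondDiagonal <- function(curve, searchRange = c(5e6, 5e7),
                                 theta = 0.10, smooth = 5e5,
                                 maxSpanFraction = 2/3) {
  raw <- psRaw(curve)
  if (searchRange[1] >= searchRange[2] || searchRange[1] <= 0)
    stop("searchRange must be an increasing positive interval")
  smax <- max(raw$s) * maxSpanFraction
  smin <- min(raw$s)
  rng <- searchRange
  if (rng[2] > smax || rng[1] < smin) {
    rng <- c(max(rng[1], smin), min(rng[2], smax))
    warning(sprintf("search range clipped to usable data extent: %.2f-%.2f Mb",
                    rng[1] / 1e6, rng[2] / 1e6))
  }
  if (rng[1] >= rng[2]) stop("search range is empty after clipping")
  lP <- ifelse(raw$P > 0, log10(raw$P), NA_real_)
  w <- max(1L, as.integer(round(smooth / curve@binSize)))
  if (w %% 2 == 0) w <- w + 1L
  sm <- .movAvg(lP, w)
  inside <- which(raw$s >= rng[1] & raw$s <= rng[2] & is.finite(sm))
  if (length(inside) < 3)
    stop("fewer than three usable diagonals in the search range")
  i0 <- inside[1]; i1 <- inside[length(inside)]
  ## two-point chord in log-log space
  x <- log10(raw$s[inside])
  base <- sm[i0] + (sm[i1] - sm[i0]) *
    (x - log10(raw$s[i0])) / (log10(raw$s[i1]) - log10(raw$s[i0]))
  resid <- sm[inside] - base
  k <- length(resid)
  isMax <- rep(FALSE, k)
  if (k >= 3) {
    interior <- 2:(k - 1)
    isMax[interior] <- resid[interior] >= resid[interior - 1] &
                       resid[interior] >= resid[interior + 1]
  }
  prom <- max(resid[isMax], -Inf)
  detected <- is.finite(prom) && prom >= theta
  position <- NA_real_
  if (detected) {
    cand <- which(isMax & resid >= prom - 1e-12)
    position <- raw$s[inside[cand[1]]]        # ties toward smaller s
  }
  if (!is.finite(prom)) prom <- max(resid)
  new("SecondDiagonalCall", detected = detected, position = position,
      prominence = prom, searchRange = rng, theta = theta,
      table = data.frame())
}

#' Assess the band on every chromosome
#'
#' A chromosome is assessable when its length is at least twice the lower
#' edge of the search range and at least 10 raw diagonals fall inside the
#' (clipped) range; detection then proceeds as in
#' [detectSecondDiagonal()].
#'
#' @param perChrom named list of per-chromosome [PsCurve-class]
#'   (the `perChrom` element of [computePs()]).
#' @param searchRange,theta,smooth,maxSpanFraction as in
#'   [detectSecondDiagonal()].
#' @return a [SecondDiagonalCall-class] whose `table` slot holds one row
#'   per chromosome (chrom, length, assessable, detected, position,
#'   prominence); the top-level flag summarizes the assessable rows.
#' @export
assessChromosomes <- function(perChrom, searchRange = c(5e6, 5e7),
                              theta = 0.10, smooth = 5e5,
                              maxSpanFraction = 2/3) {
  rows <- lapply(names(perChrom), function(cn) {
    curve <- perChrom[[cn]]
    raw <- psRaw(curve)
    len <- max(raw$s)
    nIn <- sum(raw$s >= searchRange[1] &
               raw$s <= min(searchRange[2], len * maxSpanFraction))
    assessable <- len >= 2 * searchRange[1] && nIn >= 10
    if (!assessable)
      return(data.frame(chrom = cn, length = len, assessable = FALSE,
                        detected = NA, position = NA_real_,
                        prominence = NA_real_))
    call <- suppressWarnings(
      detectSecondDiagonal(curve, searchRange, theta, smooth,
                           maxSpanFraction))
    data.frame(chrom = cn, length = len, assessable = TRUE,
               detected = call@detected, position = call@position,
               prominence = call@prominence)
  })
  tab <- do.call(rbind, rows)
  det <- tab$assessable & !is.na(tab$detected) & tab$detected
  pos <- if (any(det)) stats::median(tab$position[det]) else NA_real_
  prom <- if (any(tab$assessable)) max(tab$prominence[tab$assessable], na.rm = TRUE) else NA_real_
  new("SecondDiagonalCall", detected = any(det), position = pos,
      prominence = prom, searchRange = as.numeric(searchRange),
      theta = theta, table = tab)
}
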