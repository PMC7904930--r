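## TAD-level analyses: TAD-separation (insulation) score and boundary
## calling, the P(s) TAD-shoulder metric, and aggregate corner/loop pileups.

#' TAD-separation score
#'
#' For each window size `w` and each bin `i`, the mean balanced contact
#' within the `w x w` square straddling the diagonal at `i` (rows
#' `i-k..i-1`, columns `i+1..i+k` with `k = w / binSize`): the contacts
#' crossing position `i`.  Each window's track is z-scored across the
#' chromosome, and tracks are averaged over windows.  Insulating positions
#' score low.  Bins within the window of a chromosome end are `NA`.
#'
#' @param x a balanced [ContactMatrix-class].
#' @param windows window sizes in bp; windows longer than the chromosome are
#'   skipped with a warning.
#' @return an [InsulationScore-class].
#' @export
tadSeparationScore <- function(x, windows = c(1e5, 2e5, 3e5, 5e5)) {
  B <- balancedCounts(x)
  n <- nrow(B)
  ks <- unique(pmax(1L, as.integer(round(windows / binSize(x)))))
  ks <- ks[ks >= 2]
  drop <- ks > n - 2
  if (any(drop)) {
    warning("window(s) larger than the chromosome skipped: ",
            paste(ks[drop] * binSize(x), collapse = ", "))
    ks <- ks[!drop]
  }
  if (!length(ks)) stop("no usable window size")
  sat <- .satBuild(B)
  tracks <- matrix(NA_real_, n, length(ks))
  for (wi in seq_along(ks)) {
    k <- ks[wi]
    v <- rep(NA_real_, n)
    for (i in (k + 1):(n - k)) {
      rs <- .satRect(sat, i - k, i - 1, i + 1, i + k)
      if (rs["n"] > 0) v[i] <- rs["sum"] / rs["n"]
    }
    mu <- mean(v, na.rm = TRUE)
    sdv <- stats::sd(v, na.rm = TRUE)
    tracks[, wi] <- if (is.na(sdv) || sdv == 0) ifelse(is.na(v), NA_real_, 0)
                    else (v - mu) / sdv
  }
  score <- rowMeans(tracks, na.rm = TRUE)
  score[!is.finite(score)] <- NA_real_
  new("InsulationScore", chrom = chromName(x), binSize = binSize(x),
      score = score, windows = ks * binSize(x))
}

#' Call TAD boundaries from a TAD-separation score
#'
#' Boundaries are local minima of the score whose value lies at least
#' `delta` below the mean score of the flanking bins (flank span = largest
#' window).  Minima closer than 2 bins keep only the deeper one.  The call
#' is deterministic.
#'
#' @param ins an [InsulationScore-class].
#' @param delta minimal score drop (z units) below the flank mean.
#' @param minDepthZ maximal score (z units) a minimum may have to qualify
#'   as a boundary; shallow dips that a delta test alone would admit are
#'   rejected.  Set to `Inf` to disable.
#' @return a [BoundarySet-class]; boundary positions are the start (bp) of
#'   the minimum bin.
#' @export
callTads <- function(ins, delta = 0.05, minDepthZ = -1.5) {
  v <- ins@score
  n <- length(v)
  k <- max(1L, as.integer(round(max(ins@windows) / ins@binSize)))
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (is.na(v[i]) || is.na(v[i - 1]) || is.na(v[i + 1])) next
    if (v[i] > v[i - 1] || v[i] > v[i + 1]) next
    if (v[i] == v[i - 1] && v[i] == v[i + 1]) next      # flat plateau
    if (v[i] > minDepthZ) next
    lo <- max(1, i - k); hi <- min(n, i + k)
    flank <- c(v[lo:(i - 1)], v[(i + 1):hi])
    fm <- mean(flank, na.rm = TRUE)
    if (is.finite(fm) && fm - v[i] >= delta) cand <- c(cand, i)
  }
  ## one boundary per insulation valley: greedy suppression around the
  ## deepest minima, radius = smallest window (valleys are wider than a bin)
  if (length(cand) > 1) {
    minSep <- max(2L, as.integer(round(min(ins@windows) / ins@binSize)))
    ord <- cand[order(v[cand])]
    kept <- integer(0)
    for (i in ord)
      if (!length(kept) || all(abs(kept - i) >= minSep)) kept <- c(kept, i)
    cand <- sort(kept)
  }
  new("BoundarySet", chrom = ins@chrom, binSize = ins@binSize,
      boundaries = (cand - 1) * ins@binSize, delta = delta, score = ins)
}

#' P(s) TAD-shoulder metric
#'
#' Maximal positive deviation of `log10 P` from the log-log chord joining
#' the curve at the range endpoints — the shoulder that TAD-scale compaction
#' puts on P(s) between 100 kb and 1 Mb.  Zero or negative means no
#' shoulder.
#'
#' @param curve a [PsCurve-class] covering the range.
#' @param range numeric(2), bp.
#' @return shoulder prominence in log10 units.
#' @export
psShoulderMetric <- function(curve, range = c(1e5, 1e6)) {
  b <- psBinned(curve)
  b <- b[is.finite(b$P) & b$P > 0, , drop = FALSE]
  if (!nrow(b) || min(b$s_mid) > range[1] || max(b$s_mid) < range[2])
    stop(sprintf("curve does not cover the %.0f kb - %.1f Mb range",
                 range[1] / 1e3, range[2] / 1e6))
  lS <- log10(b$s_mid)
  lP <- log10(b$P)
  ends <- stats::approx(lS, lP, xout = log10(range))$y
  inside <- which(b$s_mid >= range[1] & b$s_mid <= range[2])
  x <- lS[inside]
  chord <- ends[1] + (ends[2] - ends[1]) *
    (x - log10(range[1])) / (log10(range[2]) - log10(range[1]))
  max(lP[inside] - chord)
}

#' Read a BEDPE anchor list
#'
#' Six or more tab-separated columns (chrom1, start1, end1, chrom2, start2,
#' end2); extra columns ignored.
#'
#' @param path file path.
#' @return data.frame with the six BEDPE coordinate columns.
#' @export
readBedpe <- function(path) {
  a <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(a) < 6) stop("BEDPE needs at least 6 columns")
  a <- a[, 1:6]
  names(a) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  a
}

#' Write a BEDPE anchor list
#' @param anchors data.frame with columns chrom1, start1, end1, chrom2,
#'   start2, end2.
#' @param path file path.
#' @export
writeBedpe <- function(anchors, path) {
  write.table(anchors, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Aggregate observed/expected pileup around anchor pairs (APA)
#'
#' Each anchor pair is mapped to its bin pair; a window of `flank` bp on
#' each side is extracted from the observed/expected matrix (expected =
#' per-diagonal chromosome mean) and windows are averaged entrywise.
#' Windows clipped by the chromosome ends are dropped and counted.  Central
#' enrichment is the center pixel over the mean of the four corner blocks
#' (block side `min(3, flank / binSize)`).
#'
#' @param x a [ContactMatrix-class] (balanced values are used when
#'   available, raw counts otherwise).
#' @param anchors BEDPE-style data.frame (`chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`), intra-chromosomal; rows on other
#'   chromosomes are ignored.
#' @param flank window half-width in bp; must be a positive multiple of the
#'   bin size.
#' @return a [PileupResult-class].
#' @export
apaPileup <- function(x, anchors, flank = 1e4) {
  bs <- binSize(x)
  f <- as.integer(round(flank / bs))
  if (f < 1 || abs(f * bs - flank) > 1e-6)
    stop("flank must be a positive multiple of the bin size")
  B <- if (isBalanced(x)) balancedCounts(x) else contactCounts(x)
  OE <- .obsExp(B)
  n <- nrow(OE)
  sel <- anchors$chrom1 == chromName(x) & anchors$chrom2 == chromName(x)
  anchors <- anchors[sel, , drop = FALSE]
  if (!nrow(anchors)) stop("no usable anchors on ", chromName(x))
  bi <- floor((anchors$start1 + anchors$end1) / 2 / bs) + 1L
  bj <- floor((anchors$start2 + anchors$end2) / 2 / bs) + 1L
  swap <- bi > bj
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  ok <- bi - f >= 1 & bj + f <= n & bi + f <= n & bj - f >= 1
  nDropped <- sum(!ok)
  bi <- bi[ok]; bj <- bj[ok]
  if (!length(bi)) stop("zero usable anchors after clipping")
  acc <- matrix(0, 2 * f + 1, 2 * f + 1)
  cnt <- matrix(0, 2 * f + 1, 2 * f + 1)
  for (a in seq_along(bi)) {
    wnd <- OE[(bi[a] - f):(bi[a] + f), (bj[a] - f):(bj[a] + f)]
    okw <- is.finite(wnd)
    acc[okw] <- acc[okw] + wnd[okw]
    cnt <- cnt + okw
  }
  mat <- acc / cnt
  mat[cnt == 0] <- NA_real_
  ctr <- f + 1L
  cb <- min(3L, f)
  corner <- function(r, c) mat[r:(r + cb - 1), c:(c + cb - 1)]
  corners <- c(corner(1, 1), corner(1, 2 * f + 2 - cb),
               corner(2 * f + 2 - cb, 1), corner(2 * f + 2 - cb, 2 * f + 2 - cb))
  enr <- mat[ctr, ctr] / mean(corners, na.rm = TRUE)
  new("PileupResult", mat = mat, enrichment = as.numeric(enr),
      nAnchors = length(bi), nDropped = as.integer(nDropped),
      flank = as.numeric(flank))
}
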