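## Contact-matrix I/O, binning of contact pairs, replicate merging and
## iterative (ICE) balancing.
##
## Coordinate convention used throughout: 0-based half-open bp positions;
## bin index = floor(pos / binSize); bin i covers
## [i * binSize, min((i + 1) * binSize, chromLength)).

## ---------------------------------------------------------------------------
## Genome / bin tables
## ---------------------------------------------------------------------------

#' Read a chrom.sizes table
#'
#' Two-column TSV (chromosome name, length in bp), the standard UCSC
#' chrom.sizes layout.
#'
#' @param path file path.
#' @return data.frame with columns `chrom` (character) and `length` (numeric).
#' @export
readChromSizes <- function(path) {
  g <- read.table(path, header = FALSE, sep = "\t",
                  colClasses = c("character", "numeric"),
                  col.names = c("chrom", "length"))
  validateGenome(g)
}

#' Write a chrom.sizes table
#' @param genome data.frame with columns `chrom`, `length`.
#' @param path file path.
#' @export
writeChromSizes <- function(genome, path) {
  genome <- validateGenome(genome)
  write.table(genome, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a genome table
#'
#' @param genome data.frame with columns `chrom`, `length`.
#' @return the validated genome table (chrom coerced to character).
#' @export
validateGenome <- function(genome) {
  if (!all(c("chrom", "length") %in% names(genome)))
    stop("genome table needs columns 'chrom' and 'length'")
  genome$chrom <- as.character(genome$chrom)
  if (any(!is.finite(genome$length)) || any(genome$length <= 0))
    stop("chromosome lengths must be positive")
  if (anyDuplicated(genome$chrom))
    stop("chromosome names must be unique")
  genome
}

#' Bin table for a genome at a fixed resolution
#'
#' One row per bin, `ceil(length / binSize)` bins per chromosome, 0-based
#' half-open coordinates; the last bin of a chromosome is clipped to its
#' length.  `bin_id` is a global 0-based index in genome order.
#'
#' @param genome data.frame with columns `chrom`, `length`.
#' @param binSize bin width (bp).
#' @return data.frame with columns `chrom`, `start`, `end`, `bin_id`.
#' @export
makeBinTable <- function(genome, binSize) {
  genome <- validateGenome(genome)
  if (binSize <= 0) stop("binSize must be positive")
  out <- do.call(rbind, lapply(seq_len(nrow(genome)), function(k) {
    len <- genome$length[k]
    nb <- ceiling(len / binSize)
    start <- (seq_len(nb) - 1) * binSize
    data.frame(chrom = genome$chrom[k], start = start,
               end = pmin(start + binSize, len))
  }))
  out$bin_id <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Contact pairs
## ---------------------------------------------------------------------------

#' Read a contact-pair list
#'
#' Four-column TSV: chrom1, pos1, chrom2, pos2 with 0-based bp positions.
#' Malformed lines (non-numeric positions, wrong field count) raise an error
#' naming the line.
#'
#' @param path file path.
#' @return data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @export
readContactPairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad))
    stop(sprintf("malformed pair record at line %d: expected 4 tab-separated fields", bad[1]))
  m <- matrix(unlist(parts), ncol = 4, byrow = TRUE)
  p1 <- suppressWarnings(as.numeric(m[, 2]))
  p2 <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(p1) | is.na(p2))
  if (length(bad))
    stop(sprintf("malformed pair record at line %d: non-numeric position", bad[1]))
  data.frame(chrom1 = m[, 1], pos1 = p1, chrom2 = m[, 3], pos2 = p2)
}

#' Write a contact-pair list
#' @param pairs data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @param path file path.
#' @export
writeContactPairs <- function(pairs, path) {
  write.table(pairs[, c("chrom1", "pos1", "chrom2", "pos2")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bin contact pairs into per-chromosome contact matrices
#'
#' Only intra-chromosomal (cis) pairs are binned; trans pairs are dropped and
#' their count reported in the `dropped` attribute.  Pairs whose position
#' falls outside the chromosome are rejected (counted, not binned); a pair
#' naming an unknown chromosome is an error.
#'
#' @param pairs data.frame with columns `chrom1`, `pos1`, `chrom2`, `pos2`
#'   (0-based bp).
#' @param genome data.frame with columns `chrom`, `length`.
#' @param binSize bin width (bp).
#' @return named list of [ContactMatrix-class], one per chromosome of
#'   `genome`, with attribute `dropped = c(trans = ..., outside = ...)`.
#' @examples
#' g <- data.frame(chrom = "c1", length = 200)
#' p <- data.frame(chrom1 = "c1", pos1 = c(50, 50), chrom2 = "c1", pos2 = c(150, 150))
#' contactCounts(binPairs(p, g, 100)$c1)
#' @export
binPairs <- function(pairs, genome, binSize) {
  genome <- validateGenome(genome)
  if (binSize <= 0) stop("binSize must be positive")
  known <- genome$chrom
  if (nrow(pairs)) {
    unk <- setdiff(unique(c(pairs$chrom1, pairs$chrom2)), known)
    if (length(unk))
      stop("unknown chromosome in pair list: ", paste(unk, collapse = ", "))
  }
  cis <- pairs$chrom1 == pairs$chrom2
  nTrans <- sum(!cis)
  pairs <- pairs[cis, , drop = FALSE]
  lens <- stats::setNames(genome$length, genome$chrom)
  inside <- pairs$pos1 >= 0 & pairs$pos1 < lens[pairs$chrom1] &
            pairs$pos2 >= 0 & pairs$pos2 < lens[pairs$chrom2]
  nOutside <- sum(!inside)
  if (nOutside)
    message(nOutside, " pair(s) with positions outside the chromosome rejected")
  pairs <- pairs[inside, , drop = FALSE]
  out <- lapply(seq_len(nrow(genome)), function(k) {
    cn <- genome$chrom[k]
    len <- genome$length[k]
    nb <- as.integer(ceiling(len / binSize))
    sel <- pairs$chrom1 == cn
    i <- floor(pairs$pos1[sel] / binSize)
    j <- floor(pairs$pos2[sel] / binSize)
    lo <- pmin(i, j) + 1L
    hi <- pmax(i, j) + 1L
    M <- as.matrix(Matrix::sparseMatrix(i = lo, j = hi, x = 1,
                                        dims = c(nb, nb)))
    M <- M + t(M)
    diag(M) <- diag(M) / 2
    ContactMatrix(M, chrom = cn, binSize = binSize, chromLength = len)
  })
  names(out) <- genome$chrom
  attr(out, "dropped") <- c(trans = nTrans, outside = nOutside)
  out
}

## ---------------------------------------------------------------------------
## Replicate merging
## ---------------------------------------------------------------------------

#' Merge replicate contact matrices by entrywise summation
#'
#' Replicates must agree in chromosome, bin size and shape and must be
#' unbalanced raw counts (merging balanced values is meaningless).
#'
#' @param matrices list of [ContactMatrix-class] replicates.
#' @return a [ContactMatrix-class] with summed counts.
#' @export
mergeReplicates <- function(matrices) {
  if (!length(matrices)) stop("no matrices to merge")
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (chromName(m) != chromName(ref) || binSize(m) != binSize(ref) ||
        nbins(m) != nbins(ref))
      stop("replicates disagree in chromosome, bin size or shape")
    if (isBalanced(m)) stop("merge unbalanced counts, not balanced matrices")
  }
  tot <- Reduce(`+`, lapply(matrices, contactCounts))
  ContactMatrix(tot, chrom = chromName(ref), binSize = binSize(ref),
                chromLength = chromLength(ref))
}

## ---------------------------------------------------------------------------
## ICE balancing
## ---------------------------------------------------------------------------

#' Iterative correction (ICE) of a contact matrix
#'
#' Finds multiplicative per-bin weights `w` such that the corrected matrix
#' `w_i * c_ij * w_j` has equal row sums over unmasked bins.  Bins with zero
#' marginal are always masked; additionally bins whose marginal falls below
#' the `maskQuantile` coverage quantile of the non-zero marginals are masked.
#' Convergence is declared when the relative variance of the corrected row
#' sums, `var(rowSums) / mean(rowSums)^2`, drops to `tol` or below.  The
#' gauge freedom (weights are defined up to a scalar) is fixed by setting the
#' mean unmasked weight to 1.
#'
#' @param x an unbalanced [ContactMatrix-class].
#' @param tol convergence tolerance on the relative row-sum variance.
#' @param maxIter maximal number of iterations; non-convergence is an error
#'   that reports the last variance reached.
#' @param maskQuantile coverage quantile below which bins are masked
#'   (0 disables the quantile rule; zero-marginal bins are always masked).
#' @return the input with `weights` attached and `balanced = TRUE`.
#' @export
balanceICE <- function(x, tol = 1e-5, maxIter = 200L, maskQuantile = 0.02) {
  if (tol <= 0) stop("tol must be positive")
  if (isBalanced(x)) stop("matrix is already balanced")
  C <- contactCounts(x)
  n <- nrow(C)
  marg <- rowSums(C)
  mask <- marg == 0
  if (maskQuantile > 0 && any(!mask)) {
    thr <- stats::quantile(marg[!mask], probs = maskQuantile, names = FALSE)
    mask <- mask | marg < thr
  }
  keep <- which(!mask)
  if (!length(keep)) stop("all bins masked; nothing to balance")
  Ck <- C[keep, keep, drop = FALSE]
  wk <- rep(1, length(keep))
  relvar <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    r <- wk * as.vector(Ck %*% wk)
    mu <- mean(r)
    relvar <- stats::var(r) / mu^2
    if (is.na(relvar)) relvar <- 0       # single unmasked bin
    if (relvar <= tol) { converged <- TRUE; break }
    wk <- wk / (r / mu)
  }
  if (!converged)
    stop(sprintf("ICE did not converge in %d iterations (relative variance %.3g > tol %.3g)",
                 maxIter, relvar, tol))
  wk <- wk / mean(wk)
  w <- rep(NA_real_, n)
  w[keep] <- wk
  new("ContactMatrix", chrom = x@chrom, binSize = x@binSize,
      chromLength = x@chromLength, counts = C, weights = w, balanced = TRUE)
}

## ---------------------------------------------------------------------------
## Matrix I/O (bin table + COO triplets)
## ---------------------------------------------------------------------------

#' Write a contact matrix as a bin table plus COO triplets
#'
#' The bin table is BED-like (chrom, start, end, bin_id); the COO file holds
#' `bin1_id bin2_id count` for the non-zero upper triangle (including the
#' diagonal), sorted by (bin1_id, bin2_id) — the canonical form, so that
#' write-then-read is the identity.  Balancing weights, when present, are
#' written as a fifth bin-table column (`NA` for masked bins).
#'
#' @param x a [ContactMatrix-class].
#' @param binPath path for the bin table TSV.
#' @param cooPath path for the COO triplet TSV.
#' @export
writeContactMatrix <- function(x, binPath, cooPath) {
  bt <- makeBinTable(data.frame(chrom = chromName(x), length = chromLength(x)),
                     binSize(x))
  if (length(x@weights)) bt$weight <- x@weights
  write.table(bt, binPath, sep = "\t", quote = FALSE, row.names = FALSE)
  C <- contactCounts(x)
  ut <- which(upper.tri(C, diag = TRUE) & C != 0, arr.ind = TRUE)
  coo <- data.frame(bin1_id = ut[, 1] - 1L, bin2_id = ut[, 2] - 1L,
                    count = C[ut])
  coo <- coo[order(coo$bin1_id, coo$bin2_id), ]
  write.table(coo, cooPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(binPath, cooPath))
}

#' Read a contact matrix from a bin table plus COO triplets
#'
#' Triplets may cover only the upper triangle (canonical) or both triangles;
#' the result is symmetrized either way.  Negative counts and out-of-range
#' bin ids are rejected with the offending line number.
#'
#' @param binPath bin table TSV written by [writeContactMatrix()].
#' @param cooPath COO triplet TSV.
#' @return a [ContactMatrix-class].
#' @export
readContactMatrix <- function(binPath, cooPath) {
  bt <- read.table(binPath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end", "bin_id") %in% names(bt)))
    stop("bin table needs columns chrom, start, end, bin_id")
  if (length(unique(bt$chrom)) != 1)
    stop("bin table must describe a single chromosome")
  nb <- nrow(bt)
  binSize <- max(bt$end - bt$start)
  chromLen <- max(bt$end)
  coo <- read.table(cooPath, header = TRUE, sep = "\t")
  if (!all(c("bin1_id", "bin2_id", "count") %in% names(coo)))
    stop("COO file needs columns bin1_id, bin2_id, count")
  bad <- which(coo$count < 0)
  if (length(bad))
    stop(sprintf("negative count at COO line %d", bad[1] + 1L))
  bad <- which(coo$bin1_id < 0 | coo$bin1_id >= nb |
               coo$bin2_id < 0 | coo$bin2_id >= nb)
  if (length(bad))
    stop(sprintf("bin id out of range at COO line %d", bad[1] + 1L))
  M <- as.matrix(Matrix::sparseMatrix(i = coo$bin1_id + 1L,
                                      j = coo$bin2_id + 1L,
                                      x = coo$count, dims = c(nb, nb)))
  d <- diag(M)
  M <- M + t(M)
  diag(M) <- d
  w <- if ("weight" %in% names(bt)) as.numeric(bt$weight) else numeric(0)
  ContactMatrix(M, chrom = bt$chrom[1], binSize = binSize,
                chromLength = chromLen, weights = w,
                balanced = length(w) > 0)
}
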