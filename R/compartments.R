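## A/B compartment PC1 from the observed/expected correlation matrix.

#' Compartment PC1 of a balanced contact matrix
#'
#' Standard eigenvector compartment call: observed/expected transform
#' (per-diagonal mean normalization), Pearson correlation matrix of the O/E
#' columns over unmasked bins, leading eigenvector of that correlation
#' matrix.  The sign is fixed against `orientationRef` when supplied
#' (positive correlation), otherwise the first non-zero entry is made
#' positive — compartment PC1 is defined up to sign, and without an external
#' reference (GC content, gene density) A/B identity is arbitrary.
#'
#' @param x a balanced [ContactMatrix-class] (the analysis resolution is
#'   whatever the matrix carries; 50 kb is the conventional choice).
#' @param orientationRef optional per-bin numeric track used only to set
#'   the sign.
#' @return a [CompartmentTrack-class]; `pc1` has `NA` at masked bins and
#'   unit norm over the rest, `explainedVariance` is the leading
#'   eigenvalue's share of the eigenvalue total.
#' @export
compartmentPC1 <- function(x, orientationRef = NULL) {
  B <- balancedCounts(x)
  OE <- .obsExp(B)
  n <- nrow(OE)
  valid <- which(colSums(is.finite(OE)) > 1)
  ## drop zero-variance columns: they carry no checkerboard information
  if (length(valid)) {
    sds <- apply(OE[, valid, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    valid <- valid[is.finite(sds) & sds > 0]
  }
  if (length(valid) < 20)
    stop("need at least 20 unmasked informative bins for PC1")
  M <- OE[valid, valid, drop = FALSE]
  ## empty diagonals (no counts at that distance) leave NA pixels even on
  ## unmasked bins; they carry no checkerboard signal, so set them to the
  ## neutral O/E value 1 rather than paying for pairwise-complete cor()
  M[!is.finite(M)] <- 1
  CC <- suppressWarnings(stats::cor(M))
  CC[!is.finite(CC)] <- 0
  CC <- (CC + t(CC)) / 2
  eg <- eigen(CC, symmetric = TRUE)
  if (eg$values[1] <= 0) stop("degenerate correlation matrix: no leading component")
  v <- eg$vectors[, 1]
  if (!is.null(orientationRef)) {
    r <- suppressWarnings(stats::cor(v, orientationRef[valid],
                                     use = "complete.obs"))
    if (is.finite(r) && r < 0) v <- -v
    orientation <- "reference"
  } else {
    nz <- which(abs(v) > 0)[1]
    if (!is.na(nz) && v[nz] < 0) v <- -v
    orientation <- "arbitrary-deterministic"
  }
  pc1 <- rep(NA_real_, n)
  pc1[valid] <- v
  evr <- eg$values[1] / sum(pmax(eg$values, 0))
  new("CompartmentTrack", chrom = chromName(x), binSize = binSize(x),
      pc1 = pc1, explainedVariance = evr, orientation = orientation)
}

#' Write a compartment track as bedGraph
#'
#' @param track a [CompartmentTrack-class].
#' @param path file path.
#' @export
writeCompartmentTrack <- function(track, path) {
  n <- length(track@pc1)
  start <- (seq_len(n) - 1) * track@binSize
  df <- data.frame(chrom = track@chrom, start = start,
                   end = start + track@binSize,
                   pc1 = ifelse(is.na(track@pc1), "NA",
                                format(track@pc1, digits = 8)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
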