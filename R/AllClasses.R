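#' @import methods
#' @importFrom stats var quantile rpois rexp runif sd cor median
#' @importFrom utils read.table write.table head tail
NULL

## ---------------------------------------------------------------------------
## ContactMatrix
## ---------------------------------------------------------------------------

#' ContactMatrix: one chromosome's binned symmetric contact map
#'
#' Container for a single intra-chromosomal Hi-C contact matrix binned at a
#' fixed resolution, with optional multiplicative balancing weights.  Counts
#' are stored as a full dense symmetric matrix; masked bins carry `NA`
#' weights and are excluded from all downstream statistics.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in base pairs.
#' @slot chromLength chromosome length in base pairs (the last bin may be
#'   shorter than `binSize`).
#' @slot counts symmetric non-negative numeric matrix of contact counts
#'   (or expected intensities for noise-free maps).
#' @slot weights per-bin positive balancing factors, `NA` for masked bins;
#'   length zero until [balanceICE()] has been run (or weights supplied).
#' @slot balanced logical flag: `TRUE` once weights are attached.
#'
#' @seealso [binPairs()], [balanceICE()], [balancedCounts()]
#' @export
setClass("ContactMatrix",
  representation(
    chrom       = "character",
    binSize     = "numeric",
    chromLength = "numeric",
    counts      = "matrix",
    weights     = "numeric",
    balanced    = "logical"
  ),
  prototype(weights = numeric(0), balanced = FALSE)
)

setValidity("ContactMatrix", function(object) {
  msg <- character(0)
  cnt <- object@counts
  if (nrow(cnt) != ncol(cnt)) msg <- c(msg, "counts must be square")
  if (any(!is.finite(cnt))) msg <- c(msg, "counts must be finite")
  else {
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (nrow(cnt) > 0 && max(abs(cnt - t(cnt))) > 1e-8 * max(1, max(abs(cnt))))
      msg <- c(msg, "counts must be symmetric")
  }
  if (length(object@binSize) != 1 || object@binSize <= 0)
    msg <- c(msg, "binSize must be a single positive number")
  if (length(object@chromLength) != 1 || object@chromLength <= 0)
    msg <- c(msg, "chromLength must be positive")
  w <- object@weights
  if (length(w) != 0) {
    if (length(w) != nrow(cnt)) msg <- c(msg, "weights length must equal bin count")
    if (any(!is.na(w) & w <= 0)) msg <- c(msg, "weights must be positive where defined")
  }
  if (object@balanced && length(w) == 0)
    msg <- c(msg, "balanced matrix must carry weights")
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMatrix
#'
#' @param counts symmetric non-negative numeric matrix.
#' @param chrom chromosome name.
#' @param binSize bin width (bp).
#' @param chromLength chromosome length (bp); default assumes full bins.
#' @param weights optional per-bin balancing weights (`NA` = masked).
#' @param balanced logical; set `TRUE` when `weights` are balancing weights.
#' @return A [ContactMatrix-class] object.
#' @export
ContactMatrix <- function(counts, chrom, binSize,
                          chromLength = nrow(counts) * binSize,
                          weights = numeric(0),
                          balanced = length(weights) > 0) {
  new("ContactMatrix", chrom = as.character(chrom), binSize = as.numeric(binSize),
      chromLength = as.numeric(chromLength),
      counts = unname(as.matrix(counts)), weights = as.numeric(weights),
      balanced = isTRUE(balanced))
}

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %s (%s bp), %d bins @ %s bp, %s\n",
              object@chrom, format(object@chromLength, big.mark = ","),
              nrow(object@counts), format(object@binSize, big.mark = ","),
              if (object@balanced) sprintf("balanced (%d masked bins)",
                                           sum(is.na(object@weights)))
              else "unbalanced"))
  cat(sprintf("  total counts: %s\n",
              format(sum(object@counts[upper.tri(object@counts, diag = TRUE)]),
                     digits = 6)))
})

## ---------------------------------------------------------------------------
## PsCurve
## ---------------------------------------------------------------------------

#' PsCurve: contact frequency as a function of genomic distance
#'
#' Holds both the raw per-diagonal contact frequency track (one value per
#' distance `d * binSize`) and its aggregation onto a geometric grid with a
#' fixed number of bins per decade.  The raw track is what the band
#' detector ([detectSecondDiagonal()]) localizes peaks on; the geometric
#' grid is what derivatives and shoulder metrics use.
#'
#' @slot scope `"genome"` or a chromosome name.
#' @slot binSize matrix resolution (bp) = raw diagonal spacing.
#' @slot raw data.frame with columns `s` (bp), `P` (mean balanced contact
#'   frequency per valid pair), `n` (valid pair count).
#' @slot binned data.frame with columns `s_lo`, `s_hi`, `s_mid`
#'   (geometric mean of edges), `P`, `n_pairs`.
#' @export
setClass("PsCurve",
  representation(scope = "character", binSize = "numeric",
                 raw = "data.frame", binned = "data.frame"))

setMethod("show", "PsCurve", function(object) {
  cat(sprintf("PsCurve [%s]: %d raw diagonals (s up to %s bp), %d geometric bins\n",
              object@scope, nrow(object@raw),
              format(max(object@raw$s), big.mark = ","), nrow(object@binned)))
})

## ---------------------------------------------------------------------------
## SecondDiagonalCall
## ---------------------------------------------------------------------------

#' SecondDiagonalCall: detection result for the helical-turn band
#'
#' @slot detected logical flag.
#' @slot position band center (bp); `NA` when not detected.
#' @slot prominence maximal log10 enrichment of the smoothed curve over the
#'   two-point log-log chord baseline.
#' @slot searchRange numeric(2), search window in bp (after clipping).
#' @slot theta prominence threshold used for the call.
#' @slot table per-chromosome data.frame (chrom, assessable, detected,
#'   position, prominence); empty for a single-curve call.
#' @export
setClass("SecondDiagonalCall",
  representation(detected = "logical", position = "numeric",
                 prominence = "numeric", searchRange = "numeric",
                 theta = "numeric", table = "data.frame"),
  prototype(table = data.frame()))

setMethod("show", "SecondDiagonalCall", function(object) {
  if (object@detected)
    cat(sprintf("Second diagonal DETECTED at %.2f Mb (prominence %.3f log10, theta %.2f)\n",
                object@position / 1e6, object@prominence, object@theta))
  else
    cat(sprintf("Second diagonal not detected (max prominence %.3f log10, theta %.2f)\n",
                object@prominence, object@theta))
  cat(sprintf("  search range: %.1f-%.1f Mb\n",
              object@searchRange[1] / 1e6, object@searchRange[2] / 1e6))
  if (nrow(object@table))
    cat(sprintf("  per-chromosome table: %d chromosomes, %d assessable, %d detected\n",
                nrow(object@table), sum(object@table$assessable),
                sum(object@table$detected, na.rm = TRUE)))
})

## ---------------------------------------------------------------------------
## SimulationConfig / GroundTruth
## ---------------------------------------------------------------------------

#' SimulationConfig: full generative parameter set for synthetic maps
#'
#' The expected intensity of a synthetic map factorizes per pixel as
#' `E[i,j] = D(s) * C(i,j) * Td(i,j) * H(s)` with `s = |i-j| * binSize`:
#' power-law distance decay `D(s) = (max(s, binSize)/s0)^(-alpha)`,
#' compartment checkerboard `C = 1 + c * e(i) * e(j)` with block labels
#' `e = +/-1`, TAD blocks `Td = 1 + t` inside a planted domain (plus `l`
#' at its corner pixel), and a helical-turn band
#' `H = 1 + A * exp(-(s - T)^2 / (2 sigma^2))` centered on the period
#' `T = loopSize * loopsPerTurn`.  The matrix is scaled so the expected
#' upper-triangle total equals `depth * chromLength / 150 Mb`.
#'
#' @slot genome data.frame with columns `chrom`, `length` (bp).
#' @slot binSize bin width (bp).
#' @slot alpha decay exponent (> 0).
#' @slot s0 reference distance (bp) for the power law.
#' @slot compartmentStrength checkerboard contrast `c` in `[0, 1)`.
#' @slot compartmentBlockMean mean compartment block length (bp) of the
#'   exponential block-length distribution.
#' @slot tadStrength within-TAD enrichment `t >= 0`.
#' @slot tadSpacing numeric(2): min/max TAD length (bp), drawn uniformly.
#' @slot loopStrength extra enrichment `l >= 0` at TAD corner pixels.
#' @slot loopSize loop length (bp).
#' @slot loopsPerTurn loops per helical turn.
#' @slot helixAmplitude band amplitude `A >= 0`.
#' @slot helixWidth band Gaussian width `sigma` (bp).
#' @slot depth expected total contact count for a 150 Mb chromosome;
#'   per-chromosome totals scale proportionally with length.
#' @slot seed integer seed controlling all draws (profiles and counts).
#' @export
setClass("SimulationConfig",
  representation(
    genome = "data.frame", binSize = "numeric",
    alpha = "numeric", s0 = "numeric",
    compartmentStrength = "numeric", compartmentBlockMean = "numeric",
    tadStrength = "numeric", tadSpacing = "numeric",
    loopStrength = "numeric",
    loopSize = "numeric", loopsPerTurn = "numeric",
    helixAmplitude = "numeric", helixWidth = "numeric",
    depth = "numeric", seed = "integer"
  ))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  g <- object@genome
  if (!all(c("chrom", "length") %in% names(g)))
    msg <- c(msg, "genome must have columns chrom, length")
  else {
    if (any(g$length <= 0)) msg <- c(msg, "chromosome lengths must be positive")
    if (anyDuplicated(g$chrom)) msg <- c(msg, "chromosome names must be unique")
  }
  if (object@binSize <= 0) msg <- c(msg, "binSize must be positive")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  if (object@s0 <= 0) msg <- c(msg, "s0 must be positive")
  if (object@compartmentStrength < 0 || object@compartmentStrength >= 1)
    msg <- c(msg, "compartmentStrength must lie in [0, 1)")
  if (object@tadStrength < 0) msg <- c(msg, "tadStrength must be >= 0")
  if (object@loopStrength < 0) msg <- c(msg, "loopStrength must be >= 0")
  if (object@helixAmplitude < 0) msg <- c(msg, "helixAmplitude must be >= 0")
  if (object@helixAmplitude > 0 &&
      (object@loopSize <= 0 || object@loopsPerTurn <= 0))
    msg <- c(msg, "helix period loopSize * loopsPerTurn must be positive when amplitude > 0")
  if (object@helixWidth <= 0) msg <- c(msg, "helixWidth must be positive")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d chromosome(s) @ %s bp bins, seed %d\n",
              nrow(object@genome), format(object@binSize, big.mark = ","),
              object@seed))
  cat(sprintf("  decay alpha=%.2f s0=%s; compartments c=%.2f; TADs t=%.2f loops l=%.2f\n",
              object@alpha, format(object@s0, big.mark = ","),
              object@compartmentStrength, object@tadStrength, object@loopStrength))
  cat(sprintf("  helix A=%.2f sigma=%.1f Mb, period T = %s x %s = %.1f Mb; depth %.3g / 150 Mb\n",
              object@helixAmplitude, object@helixWidth / 1e6,
              format(object@loopSize, big.mark = ","), object@loopsPerTurn,
              helixPeriod(object) / 1e6, object@depth))
})

#' GroundTruth: planted features of a simulated genome
#'
#' @slot compartments named list (per chromosome) of per-bin labels `+/-1`.
#' @slot tadBoundaries named list of boundary positions (bp, bin-aligned).
#' @slot loopAnchors named list of data.frames (`start1`, `start2`, bp) of
#'   planted corner-loop anchor pairs.
#' @slot helixPeriod named numeric: planted period `T` per chromosome (bp).
#' @export
setClass("GroundTruth",
  representation(compartments = "list", tadBoundaries = "list",
                 loopAnchors = "list", helixPeriod = "numeric"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth for %d chromosome(s): %s TAD boundaries, period %s Mb\n",
              length(object@compartments),
              sum(lengths(object@tadBoundaries)),
              paste(unique(round(object@helixPeriod / 1e6, 2)), collapse = "/")))
})

## ---------------------------------------------------------------------------
## Domain-level results
## ---------------------------------------------------------------------------

#' InsulationScore: per-bin TAD-separation score
#'
#' Mean z-scored insulation over a set of window sizes; low values mark
#' insulating positions.  `NA` within the largest window of chromosome ends.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width (bp).
#' @slot score numeric per-bin score.
#' @slot windows window sizes used (bp).
#' @export
setClass("InsulationScore",
  representation(chrom = "character", binSize = "numeric",
                 score = "numeric", windows = "numeric"))

setMethod("show", "InsulationScore", function(object) {
  cat(sprintf("InsulationScore: %s, %d bins @ %s bp, windows {%s} kb\n",
              object@chrom, length(object@score),
              format(object@binSize, big.mark = ","),
              paste(object@windows / 1e3, collapse = ", ")))
})

#' BoundarySet: called TAD boundaries
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width (bp).
#' @slot boundaries boundary positions (bp; start of the boundary bin).
#' @slot delta minimal score drop below the flank mean for a call.
#' @slot score the per-bin score the boundaries were called on.
#' @export
setClass("BoundarySet",
  representation(chrom = "character", binSize = "numeric",
                 boundaries = "numeric", delta = "numeric",
                 score = "InsulationScore"))

setMethod("show", "BoundarySet", function(object) {
  cat(sprintf("BoundarySet: %s, %d boundaries (delta %.3f)\n",
              object@chrom, length(object@boundaries), object@delta))
})

#' PileupResult: aggregate observed/expected pileup around anchor pairs
#'
#' @slot mat mean observed/expected window, `(2 f + 1)` bins square where
#'   `f = flank / binSize`.
#' @slot enrichment central enrichment: center pixel over the mean of the
#'   four corner blocks (block side `min(3, f)`).
#' @slot nAnchors anchors averaged.
#' @slot nDropped anchors dropped because their window was clipped.
#' @slot flank flank in bp.
#' @export
setClass("PileupResult",
  representation(mat = "matrix", enrichment = "numeric",
                 nAnchors = "integer", nDropped = "integer", flank = "numeric"))

setMethod("show", "PileupResult", function(object) {
  cat(sprintf("PileupResult: %d anchors (%d dropped), %dx%d window, central enrichment %.3f\n",
              object@nAnchors, object@nDropped,
              nrow(object@mat), ncol(object@mat), object@enrichment))
})

#' CompartmentTrack: A/B compartment eigenvector
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width (bp).
#' @slot pc1 per-bin leading eigenvector of the O/E correlation matrix
#'   (`NA` at masked bins; unit norm over unmasked bins).
#' @slot explainedVariance leading eigenvalue over the eigenvalue total.
#' @slot orientation `"reference"` (sign set against a supplied track) or
#'   `"arbitrary-deterministic"` (first non-zero entry positive).
#' @export
setClass("CompartmentTrack",
  representation(chrom = "character", binSize = "numeric", pc1 = "numeric",
                 explainedVariance = "numeric", orientation = "character"))

setMethod("show", "CompartmentTrack", function(object) {
  cat(sprintf("CompartmentTrack: %s, %d bins @ %s bp, EV ratio %.3f, orientation: %s\n",
              object@chrom, length(object@pc1),
              format(object@binSize, big.mark = ","),
              object@explainedVariance, object@orientation))
})

#' SCCResult: stratum-adjusted correlation between two maps
#'
#' @slot scc weighted mean of the per-stratum Pearson correlations.
#' @slot strata data.frame (distance, r, N, weight), one row per stratum.
#' @slot h smoothing half-width (bins).
#' @slot maxDist maximal distance (bp).
#' @slot resolution matrix resolution (bp).
#' @export
setClass("SCCResult",
  representation(scc = "numeric", strata = "data.frame", h = "integer",
                 maxDist = "numeric", resolution = "numeric"))

setMethod("show", "SCCResult", function(object) {
  cat(sprintf("SCC = %.4f (h = %d, max distance %.1f Mb, %d strata)\n",
              object@scc, object@h, object@maxDist / 1e6, nrow(object@strata)))
})
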