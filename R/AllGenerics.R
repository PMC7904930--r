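## Accessor generics. Bioconductor-style: slots are reached through
## accessors, never @.

#' @rdname ContactMatrix-class
#' @param x,object a helixscan object.
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("chromLength", function(x) standardGeneric("chromLength"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("balancingWeights", function(x) standardGeneric("balancingWeights"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("maskedBins", function(x) standardGeneric("maskedBins"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("balancedCounts", function(x) standardGeneric("balancedCounts"))

#' @rdname SimulationConfig-class
#' @param x a `SimulationConfig` or `GroundTruth`.
#' @export
setGeneric("helixPeriod", function(x) standardGeneric("helixPeriod"))

#' @rdname PsCurve-class
#' @param x a `PsCurve`.
#' @export
setGeneric("psRaw", function(x) standardGeneric("psRaw"))

#' @rdname PsCurve-class
#' @export
setGeneric("psBinned", function(x) standardGeneric("psBinned"))

#' @rdname BoundarySet-class
#' @param x a `BoundarySet` or `InsulationScore`.
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))

#' @rdname InsulationScore-class
#' @param x an `InsulationScore` or `BoundarySet`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

setMethod("chromName", "ContactMatrix", function(x) x@chrom)
setMethod("binSize", "ContactMatrix", function(x) x@binSize)
setMethod("chromLength", "ContactMatrix", function(x) x@chromLength)
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)
setMethod("balancingWeights", "ContactMatrix", function(x) x@weights)
setMethod("isBalanced", "ContactMatrix", function(x) x@balanced)
setMethod("nbins", "ContactMatrix", function(x) nrow(x@counts))
setMethod("maskedBins", "ContactMatrix", function(x) {
  if (length(x@weights)) which(is.na(x@weights)) else integer(0)
})

#' Balanced contact values
#'
#' Returns the matrix of balanced values `w_i * c_ij * w_j`; rows/columns of
#' masked bins are `NA`.  Errors if the matrix carries no weights.
#'
#' @param x a balanced [ContactMatrix-class].
#' @return numeric matrix with `NA` at masked bins.
#' @export
setMethod("balancedCounts", "ContactMatrix", function(x) {
  if (!x@balanced || length(x@weights) == 0)
    stop("matrix is not balanced; run balanceICE() first")
  w <- x@weights
  out <- x@counts * outer(w, w)
  out
})

setMethod("helixPeriod", "SimulationConfig", function(x) x@loopSize * x@loopsPerTurn)
setMethod("helixPeriod", "GroundTruth", function(x) x@helixPeriod)

setMethod("psRaw", "PsCurve", function(x) x@raw)
setMethod("psBinned", "PsCurve", function(x) x@binned)

setMethod("boundaries", "BoundarySet", function(x) x@boundaries)
setMethod("scores", "InsulationScore", function(x) x@score)
setMethod("scores", "BoundarySet", function(x) x@score@score)
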