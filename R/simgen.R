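## Synthetic contact-map generator.
##
## Generates the statistical structure the downstream analyses assume:
## power-law distance decay, an A/B compartment checkerboard, optional TAD
## blocks with corner loops, and a periodic long-range band at the helical
## period T = loopSize * loopsPerTurn, sampled at finite sequencing depth.
## Ground truth for every planted feature is emitted alongside.

#' Build a simulation configuration
#'
#' Defaults give an interphase-like decay exponent (`alpha = 1`), a
#' compartment checkerboard of moderate contrast, and a detectable but not
#' dominant helical-turn band; see [SimulationConfig-class] for the
#' generative model.
#'
#' @param genome data.frame with columns `chrom`, `length` (bp).
#' @param binSize bin width (bp).
#' @param alpha power-law decay exponent.
#' @param s0 reference distance (bp); defaults to `binSize`.
#' @param compartmentStrength checkerboard contrast `c` in `[0, 1)`.
#' @param compartmentBlockMean mean compartment block length (bp).
#' @param tadStrength within-TAD enrichment `t`.
#' @param tadSpacing numeric(2): min/max TAD length (bp).
#' @param loopStrength corner-loop enrichment `l`.
#' @param loopSize loop length (bp).
#' @param loopsPerTurn loops per helical turn; the band sits at
#'   `T = loopSize * loopsPerTurn`.
#' @param helixAmplitude band amplitude `A`.
#' @param helixWidth band width `sigma` (bp).
#' @param depth expected total contacts for a 150 Mb chromosome
#'   (per-chromosome totals scale with length).
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(genome, binSize = 1e5,
                             alpha = 1.0, s0 = binSize,
                             compartmentStrength = 0.3,
                             compartmentBlockMean = 3e6,
                             tadStrength = 0,
                             tadSpacing = c(4e5, 1.2e6),
                             loopStrength = 0,
                             loopSize = 2e5, loopsPerTurn = 75,
                             helixAmplitude = 0.4, helixWidth = 1.5e6,
                             depth = 1e7, seed = 1L) {
  new("SimulationConfig",
      genome = validateGenome(genome), binSize = as.numeric(binSize),
      alpha = as.numeric(alpha), s0 = as.numeric(s0),
      compartmentStrength = as.numeric(compartmentStrength),
      compartmentBlockMean = as.numeric(compartmentBlockMean),
      tadStrength = as.numeric(tadStrength),
      tadSpacing = as.numeric(tadSpacing),
      loopStrength = as.numeric(loopStrength),
      loopSize = as.numeric(loopSize),
      loopsPerTurn = as.numeric(loopsPerTurn),
      helixAmplitude = as.numeric(helixAmplitude),
      helixWidth = as.numeric(helixWidth),
      depth = as.numeric(depth), seed = as.integer(seed))
}

#' Preset configurations for the two qualitative map classes
#'
#' `"erythrocyte"`: no TADs or loops (`t = l = 0`), compartments present,
#' helical band on (`A > 0`) — condensed erythroid-like organization.
#' `"fibroblast"`: TADs with corner loops (`t, l > 0`), compartments
#' present, no band (`A = 0`) — conventional interphase organization.
#'
#' @param name `"erythrocyte"` or `"fibroblast"`.
#' @param genome data.frame with columns `chrom`, `length`.
#' @param ... overrides passed on to [simulationConfig()].
#' @return a [SimulationConfig-class].
#' @export
presetConfig <- function(name = c("erythrocyte", "fibroblast"), genome, ...) {
  name <- match.arg(name)
  base <- switch(name,
    erythrocyte = list(tadStrength = 0, loopStrength = 0,
                       helixAmplitude = 0.4),
    fibroblast  = list(tadStrength = 1.5, loopStrength = 1.5,
                       helixAmplitude = 0))
  args <- utils::modifyList(c(list(genome = genome), base), list(...))
  do.call(simulationConfig, args)
}

## Per-chromosome number of bins.
.nbinsFor <- function(config, chrom) {
  len <- config@genome$length[match(chrom, config@genome$chrom)]
  if (is.na(len)) stop("unknown chromosome: ", chrom)
  as.integer(ceiling(len / config@binSize))
}

#' Ground truth planted by a configuration
#'
#' Draws the compartment profile (alternating blocks with exponential
#' lengths), TAD boundaries (uniform spacing within `tadSpacing`; only when
#' `tadStrength > 0`) and corner-loop anchors for every chromosome, fully
#' determined by the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruth-class].
#' @export
groundTruth <- function(config) {
  g <- config@genome
  comps <- list(); tads <- list(); loops <- list(); periods <- numeric(0)
  .withSeed(config@seed, {
    for (k in seq_len(nrow(g))) {
      len <- g$length[k]
      nb <- as.integer(ceiling(len / config@binSize))
      ## compartment profile: alternating +/-1 blocks, exponential lengths
      e <- integer(0)
      lab <- sample(c(-1L, 1L), 1)
      while (length(e) < nb) {
        blk <- max(1L, as.integer(round(
          rexp(1, rate = 1 / config@compartmentBlockMean) / config@binSize)))
        e <- c(e, rep(lab, blk))
        lab <- -lab
      }
      comps[[g$chrom[k]]] <- e[seq_len(nb)]
      ## TAD boundaries at bin-aligned positions
      if (config@tadStrength > 0 || config@loopStrength > 0) {
        pos <- 0
        bnd <- numeric(0)
        repeat {
          pos <- pos + runif(1, config@tadSpacing[1], config@tadSpacing[2])
          if (pos >= len) break
          bnd <- c(bnd, round(pos / config@binSize) * config@binSize)
        }
        bnd <- unique(bnd[bnd > 0 & bnd < len])
        tads[[g$chrom[k]]] <- bnd
        edges <- c(0, bnd, floor(len / config@binSize) * config@binSize)
        loops[[g$chrom[k]]] <- data.frame(start1 = head(edges, -1),
                                          start2 = tail(edges, -1) - config@binSize)
      } else {
        tads[[g$chrom[k]]] <- numeric(0)
        loops[[g$chrom[k]]] <- data.frame(start1 = numeric(0), start2 = numeric(0))
      }
      periods[g$chrom[k]] <- config@loopSize * config@loopsPerTurn
    }
  })
  new("GroundTruth", compartments = comps, tadBoundaries = tads,
      loopAnchors = loops, helixPeriod = periods)
}

#' Expected (noise-free) contact intensity for one chromosome
#'
#' Evaluates the multiplicative model `E = D * C * Td * H` on the bin grid
#' and scales the matrix so the upper-triangle total (diagonal included)
#' equals the chromosome's expected depth.  The `s = 0` diagonal is assigned
#' the `s = binSize` decay value to avoid a singular pixel.
#'
#' @param config a [SimulationConfig-class].
#' @param chrom chromosome name (must be in the config genome).
#' @param truth optional [GroundTruth-class] (recomputed from the config
#'   when missing).
#' @return symmetric non-negative expected-intensity matrix.
#' @export
simulateExpectedMap <- function(config, chrom, truth = groundTruth(config)) {
  validObject(config)
  nb <- .nbinsFor(config, chrom)
  bs <- config@binSize
  s <- (0:(nb - 1)) * bs
  D <- (pmax(s, bs) / config@s0)^(-config@alpha)
  H <- rep(1, nb)
  if (config@helixAmplitude > 0) {
    Tp <- config@loopSize * config@loopsPerTurn
    H <- 1 + config@helixAmplitude *
      exp(-(s - Tp)^2 / (2 * config@helixWidth^2))
  }
  E <- stats::toeplitz(D * H)
  if (config@compartmentStrength > 0) {
    e <- truth@compartments[[chrom]]
    E <- E * (1 + config@compartmentStrength * outer(e, e))
  }
  if (config@tadStrength > 0 || config@loopStrength > 0) {
    bnd <- truth@tadBoundaries[[chrom]]
    edges <- unique(c(0, bnd %/% bs, nb))
    tfac <- 1 + config@tadStrength
    for (k in seq_len(length(edges) - 1)) {
      rng <- (edges[k] + 1):edges[k + 1]
      E[rng, rng] <- E[rng, rng] * tfac
      if (config@loopStrength > 0 && length(rng) > 1) {
        i0 <- rng[1]; j0 <- rng[length(rng)]
        ## corner pixel: Td = 1 + t + l there
        base <- E[i0, j0] / tfac
        E[i0, j0] <- E[i0, j0] + base * config@loopStrength
        E[j0, i0] <- E[i0, j0]
      }
    }
  }
  len <- config@genome$length[match(chrom, config@genome$chrom)]
  target <- config@depth * len / 150e6
  tot <- sum(E[upper.tri(E, diag = TRUE)])
  E * (target / tot)
}

#' Poisson-sample a contact matrix from an expected map
#'
#' Upper-triangle entries (diagonal included) are drawn independently as
#' `Poisson(E[i, j])` and mirrored.  Reproducible under a fixed seed; the
#' caller's RNG stream is left untouched.
#'
#' @param expected non-negative expected-intensity matrix.
#' @param chrom chromosome name for the result.
#' @param binSize bin width (bp).
#' @param seed integer seed.
#' @param chromLength chromosome length (bp).
#' @return a [ContactMatrix-class] of raw counts.
#' @export
sampleCounts <- function(expected, chrom, binSize, seed,
                         chromLength = nrow(expected) * binSize) {
  if (any(!is.finite(expected)) || any(expected < 0))
    stop("expected intensities must be finite and non-negative")
  n <- nrow(expected)
  ut <- upper.tri(expected, diag = TRUE)
  M <- matrix(0, n, n)
  M[ut] <- .withSeed(seed, rpois(sum(ut), expected[ut]))
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  ContactMatrix(M, chrom = chrom, binSize = binSize, chromLength = chromLength)
}

#' Simulate a full genome of contact matrices
#'
#' Convenience wrapper: expected map plus Poisson sampling for every
#' chromosome of the config genome, with per-chromosome seeds derived from
#' the config seed.
#'
#' @param config a [SimulationConfig-class].
#' @param noiseFree logical; when `TRUE` the expected intensities are
#'   returned as counts (with unit weights attached, since an expected map
#'   is already coverage-uniform up to its planted structure).
#' @return list with elements `matrices` (named list of
#'   [ContactMatrix-class]) and `truth` (a [GroundTruth-class]).
#' @export
simulateHiC <- function(config, noiseFree = FALSE) {
  validObject(config)
  truth <- groundTruth(config)
  g <- config@genome
  mats <- lapply(seq_len(nrow(g)), function(k) {
    E <- simulateExpectedMap(config, g$chrom[k], truth)
    if (noiseFree)
      ContactMatrix(E, chrom = g$chrom[k], binSize = config@binSize,
                    chromLength = g$length[k],
                    weights = rep(1, nrow(E)), balanced = TRUE)
    else
      sampleCounts(E, g$chrom[k], config@binSize,
                   seed = config@seed + 7919L * k,
                   chromLength = g$length[k])
  })
  names(mats) <- g$chrom
  list(matrices = mats, truth = truth)
}

#' BEDPE anchor table for the planted corner loops
#'
#' Convenience accessor turning the ground-truth loop anchor list into the
#' six-column BEDPE layout [apaPileup()] consumes (each anchor spans one
#' bin).
#'
#' @param truth a [GroundTruth-class].
#' @param chrom chromosome name.
#' @param binSize bin width (bp).
#' @return data.frame with columns chrom1, start1, end1, chrom2, start2,
#'   end2.
#' @export
loopAnchorsBedpe <- function(truth, chrom, binSize) {
  an <- truth@loopAnchors[[chrom]]
  if (is.null(an)) stop("no ground truth for ", chrom)
  data.frame(chrom1 = chrom, start1 = an$start1, end1 = an$start1 + binSize,
             chrom2 = chrom, start2 = an$start2, end2 = an$start2 + binSize)
}
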