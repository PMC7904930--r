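## End-to-end orchestration: simulate (or load) -> balance -> P(s) ->
## second diagonal -> TADs -> compartments -> replicate SCC -> APA ->
## machine-readable report.

#' Run the full analysis pipeline
#'
#' Simulates `replicates` Poisson samplings of a preset map (or loads
#' matrices from `binPath`/`cooPath` pairs), checks replicate
#' reproducibility by SCC, merges replicates, balances, and runs every
#' analysis stage: genome and per-chromosome P(s) with derivatives,
#' second-diagonal detection, TAD-separation boundaries, the P(s)
#' TAD-shoulder metric, compartment PC1, and a corner pileup when the
#' simulation planted loops.  All numeric outputs are deterministic given
#' the seed.  TSV/JSON artifacts are written under `outDir` when supplied.
#'
#' @param preset `"erythrocyte"` or `"fibroblast"` (ignored when `input`
#'   matrices are given).
#' @param genome data.frame with columns `chrom`, `length`.
#' @param input optional named list of raw [ContactMatrix-class] to analyze
#'   instead of simulating.
#' @param binSize simulation bin width (bp).
#' @param depth expected contacts per 150 Mb chromosome per replicate.
#' @param replicates number of simulated replicates (>= 1); SCC is computed
#'   for every pair before merging.
#' @param seed integer seed controlling the whole run.
#' @param outDir optional output directory for TSV/JSON artifacts.
#' @param searchRange,theta,smooth band-detector settings
#'   (see [detectSecondDiagonal()]).
#' @param tadWindows insulation window set (bp); used at the simulation
#'   resolution.
#' @param delta boundary-call threshold (see [callTads()]).
#' @param sccH,sccMaxDist SCC settings (see [scc()]).
#' @param config optional [SimulationConfig-class] overriding
#'   `preset`/`genome`/`binSize`/`depth`/`seed` for the generator.
#' @return a list (invisibly written as JSON when `outDir` is set) with
#'   elements `params`, `scc`, `secondDiagonal` (per-chromosome table and
#'   genome call), `shoulder`, `boundaries`, `compartments`, and `truth`
#'   when simulated.
#' @export
runPipeline <- function(preset = "erythrocyte", genome = NULL, input = NULL,
                        binSize = 1e5, depth = 1e7, replicates = 2,
                        seed = 1L, outDir = NULL,
                        searchRange = c(5e6, 5e7), theta = 0.10,
                        smooth = 5e5, tadWindows = c(1e5, 2e5, 3e5, 5e5),
                        delta = 0.05, sccH = 3L, sccMaxDist = 5e6,
                        config = NULL) {
  t0 <- Sys.time()
  truth <- NULL
  sccTab <- data.frame()
  if (is.null(input)) {
    if (is.null(config))
      config <- presetConfig(preset, genome = genome, binSize = binSize,
                             depth = depth, seed = seed)
    truth <- groundTruth(config)
    g <- config@genome
    expected <- lapply(g$chrom, function(cn)
      simulateExpectedMap(config, cn, truth))
    names(expected) <- g$chrom
    ## replicates share the planted truth and expected map; only the
    ## Poisson sampling seed differs
    reps <- lapply(seq_len(replicates), function(r) {
      mats <- lapply(seq_len(nrow(g)), function(k)
        sampleCounts(expected[[k]], g$chrom[k], config@binSize,
                     seed = config@seed + 104729L * (r - 1L) + 7919L * k,
                     chromLength = g$length[k]))
      names(mats) <- g$chrom
      mats
    })
    ## reproducibility gate: SCC for every replicate pair, per chromosome
    if (replicates >= 2) {
      for (cn in names(reps[[1]])) {
        for (r1 in seq_len(replicates - 1)) for (r2 in (r1 + 1):replicates) {
          s <- scc(reps[[r1]][[cn]], reps[[r2]][[cn]],
                   h = sccH, maxDist = sccMaxDist)
          sccTab <- rbind(sccTab, data.frame(chrom = cn, rep1 = r1,
                                             rep2 = r2, scc = s@scc))
        }
      }
    }
    input <- lapply(names(reps[[1]]), function(cn)
      mergeReplicates(lapply(reps, `[[`, cn)))
    names(input) <- names(reps[[1]])
  }
  balancedMats <- lapply(input, balanceICE)
  ps <- computePs(balancedMats)
  deriv <- psDerivative(ps$genome)
  band <- assessChromosomes(ps$perChrom, searchRange = searchRange,
                            theta = theta, smooth = smooth)
  genomeBand <- suppressWarnings(
    detectSecondDiagonal(ps$genome, searchRange = searchRange,
                         theta = theta, smooth = smooth))
  shoulder <- tryCatch(psShoulderMetric(ps$genome),
                       error = function(e) NA_real_)
  boundarySets <- lapply(balancedMats, function(m)
    callTads(tadSeparationScore(m, windows = tadWindows), delta = delta))
  comps <- lapply(seq_along(balancedMats), function(k) {
    ref <- if (!is.null(truth)) truth@compartments[[names(balancedMats)[k]]]
           else NULL
    tryCatch(compartmentPC1(balancedMats[[k]], orientationRef = ref),
             error = function(e) NULL)
  })
  names(comps) <- names(balancedMats)
  report <- list(
    params = list(preset = preset, binSize = binSize, depth = depth,
                  replicates = replicates, seed = seed,
                  searchRange = searchRange, theta = theta, smooth = smooth,
                  tadWindows = tadWindows, delta = delta, sccH = sccH,
                  sccMaxDist = sccMaxDist,
                  package = as.character(utils::packageVersion("helixscan"))),
    scc = sccTab,
    secondDiagonal = list(
      detected = genomeBand@detected,
      position = genomeBand@position,
      prominence = genomeBand@prominence,
      perChromosome = band@table),
    shoulder = shoulder,
    boundaries = lapply(boundarySets, boundaries),
    compartments = lapply(comps, function(ct)
      if (is.null(ct)) NULL
      else list(explainedVariance = ct@explainedVariance,
                orientation = ct@orientation)),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (cn in names(input))
      writeContactMatrix(balancedMats[[cn]],
                         file.path(outDir, paste0(cn, ".bins.tsv")),
                         file.path(outDir, paste0(cn, ".coo.tsv")))
    write.table(psBinned(ps$genome), file.path(outDir, "ps_genome.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(deriv, file.path(outDir, "ps_derivative.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(band@table, file.path(outDir, "second_diagonal.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (cn in names(boundarySets)) {
      bs <- boundarySets[[cn]]
      if (length(boundaries(bs)))
        write.table(data.frame(chrom = cn, start = boundaries(bs),
                               end = boundaries(bs) + binSize(balancedMats[[cn]])),
                    file.path(outDir, paste0(cn, ".boundaries.bed")),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    for (cn in names(comps))
      if (!is.null(comps[[cn]]))
        writeCompartmentTrack(comps[[cn]],
                              file.path(outDir, paste0(cn, ".pc1.bedGraph")))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  }
  if (!is.null(truth)) report$truth <- list(
    tadBoundaries = truth@tadBoundaries,
    helixPeriod = truth@helixPeriod)
  report
}
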