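test_that("perfect insulation puts the score minimum at the block junction", {
  C <- matrix(0, 20, 20)
  C[1:10, 1:10] <- 1
  C[11:20, 11:20] <- 1
  diag(C) <- 1
  m <- unitBalanced(C, binSize = 1e4)
  ins <- tadSeparationScore(m, windows = c(3e4, 5e4))
  v <- scores(ins)
  expect_true(which.min(v) %in% c(10, 11))
  # the junction-crossing diamond is empty
  expect_equal(min(v, na.rm = TRUE), v[which.min(v)])
})

test_that("a uniform matrix scores flat and yields no boundaries", {
  m <- unitBalanced(matrix(2, 30, 30), binSize = 1e4)
  ins <- tadSeparationScore(m, windows = c(3e4))
  v <- scores(ins)
  expect_true(all(v[!is.na(v)] == 0))
  expect_length(boundaries(callTads(ins)), 0)
})

test_that("the score is invariant under global matrix scaling", {
  g <- oneChromGenome(8e6)
  cfg <- presetConfig("fibroblast", g, binSize = 1e4, seed = 5)
  E <- simulateExpectedMap(cfg, "c")
  v1 <- scores(tadSeparationScore(unitBalanced(E, binSize = 1e4)))
  v2 <- scores(tadSeparationScore(unitBalanced(7 * E, binSize = 1e4)))
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("boundary calls mirror under bin-index reversal", {
  g <- oneChromGenome(8e6)
  cfg <- presetConfig("fibroblast", g, binSize = 1e4, seed = 6)
  E <- simulateExpectedMap(cfg, "c")
  n <- nrow(E)
  fwd <- callTads(tadSeparationScore(unitBalanced(E, binSize = 1e4)))
  rev <- callTads(tadSeparationScore(unitBalanced(E[n:1, n:1], binSize = 1e4)))
  mirrored <- sort((n - 1) * 1e4 - boundaries(rev))
  # sub-ulp score asymmetries can flip which bin of a flat-bottom valley
  # wins, so mirroring is exact up to one bin
  expect_equal(length(boundaries(fwd)), length(mirrored))
  expect_true(all(abs(sort(boundaries(fwd)) - mirrored) <= 1e4))
})

test_that("planted fibroblast boundaries are recovered at one-bin tolerance", {
  g <- oneChromGenome(20e6)
  cfg <- presetConfig("fibroblast", g, binSize = 1e4, depth = 1e7, seed = 1)
  sim <- simulateHiC(cfg)
  m <- balanceICE(sim$matrices$c)
  called <- boundaries(callTads(tadSeparationScore(m)))
  truthB <- sim$truth@tadBoundaries$c
  expect_gte(hitRate(truthB, called, 1e4), 0.8)
  # calls land on planted insulating features: TAD boundaries or
  # compartment sign flips (both are genuine insulation in the generator)
  planted <- c(truthB, flipPositions(sim$truth@compartments$c, 1e4))
  expect_gte(hitRate(called, planted, 1e4), 0.8)
})

test_that("without TADs, called boundaries sit at compartment flips", {
  g <- oneChromGenome(20e6)
  pooledCalled <- numeric(0)
  pooledHit <- numeric(0)
  for (sd_ in c(1, 5)) {
    cfg <- presetConfig("erythrocyte", g, binSize = 1e4, depth = 1e7,
                        seed = sd_)
    sim <- simulateHiC(cfg)
    m <- balanceICE(sim$matrices$c)
    called <- boundaries(callTads(tadSeparationScore(m)))
    flips <- flipPositions(sim$truth@compartments$c, 1e4)
    pooledCalled <- c(pooledCalled, called)
    pooledHit <- c(pooledHit, vapply(called, function(p)
      any(abs(flips - p) <= 1e4), logical(1)))
  }
  expect_gt(length(pooledCalled), 0)
  expect_gte(mean(pooledHit), 0.7)
})

test_that("the shoulder metric is zero for a pure power law", {
  s <- 10^(seq(40, 70) / 10)
  expect_equal(psShoulderMetric(psCurve(s, s^-1)), 0, tolerance = 1e-9)
})

test_that("a multiplicative bump registers its height in the shoulder metric", {
  s <- seq(1e4, 2e6, by = 1e4)
  P <- s^-1 * (1 + 0.2 * exp(-(s - 4e5)^2 / (2 * (1e5)^2)))
  expect_lt(abs(psShoulderMetric(psCurve(s, P)) - log10(1.2)), 0.02)
  expect_error(psShoulderMetric(psCurve(s[s > 5e5], P[s > 5e5])),
               "does not cover")
})

test_that("fibroblast maps shoulder; erythrocyte maps do not", {
  g <- oneChromGenome(20e6)
  for (sd_ in 1:2) {
    shoulderOf <- function(preset) {
      cfg <- presetConfig(preset, g, binSize = 1e4, depth = 1e7, seed = sd_)
      m <- balanceICE(simulateHiC(cfg)$matrices$c)
      psShoulderMetric(computePs(m)$genome)
    }
    expect_gt(shoulderOf("fibroblast"), shoulderOf("erythrocyte"))
  }
})

test_that("APA central enrichment matches factor arithmetic on expected maps", {
  g <- oneChromGenome(20e6)
  # t = 0: corner blocks sample plain background, enrichment = 1 + l exactly
  cfg <- simulationConfig(g, binSize = 1e4, tadStrength = 0,
                          loopStrength = 1, helixAmplitude = 0, seed = 4)
  sim <- simulateHiC(cfg, noiseFree = TRUE)
  bed <- loopAnchorsBedpe(sim$truth, "c", 1e4)
  pu <- apaPileup(sim$matrices$c, bed, flank = 1e5)
  expect_equal(pu@enrichment, 2, tolerance = 0.05 * 2)
  expect_equal(nrow(pu@mat), 21)
})

test_that("planted corner loops light up the pileup center on noisy maps", {
  g <- oneChromGenome(20e6)
  cfg <- presetConfig("fibroblast", g, binSize = 1e4, depth = 1e7, seed = 3)
  sim <- simulateHiC(cfg)
  m <- balanceICE(sim$matrices$c)
  bed <- loopAnchorsBedpe(sim$truth, "c", 1e4)
  pu <- apaPileup(m, bed, flank = 1e5)
  expect_gt(pu@enrichment, 1.5)
})

test_that("random anchors on a loop-free map give a flat pileup", {
  g <- oneChromGenome(20e6)
  enr <- vapply(1:3, function(sd_) {
    cfg <- presetConfig("erythrocyte", g, binSize = 1e4, depth = 1e7,
                        seed = sd_)
    m <- balanceICE(simulateHiC(cfg)$matrices$c)
    set.seed(sd_ + 100)
    s1 <- sort(sample(30:1900, 30)) * 1e4
    s2 <- s1 + sample(40:80, 30, TRUE) * 1e4
    bed <- data.frame(chrom1 = "c", start1 = s1, end1 = s1 + 1e4,
                      chrom2 = "c", start2 = s2, end2 = s2 + 1e4)
    apaPileup(m, bed, flank = 1e5)@enrichment
  }, numeric(1))
  expect_lt(abs(median(enr) - 1), 0.1)
})

test_that("APA drops clipped windows and validates its inputs", {
  m <- unitBalanced(randomCounts(50, 8) + 1, binSize = 1e4)
  bed <- data.frame(chrom1 = "toy", start1 = c(0, 2e5), end1 = c(1e4, 2.1e5),
                    chrom2 = "toy", start2 = c(1e5, 4e5), end2 = c(1.1e5, 4.1e5))
  pu <- apaPileup(m, bed, flank = 3e4)
  expect_equal(pu@nDropped, 1L)     # the window at the chromosome start
  expect_equal(pu@nAnchors, 1L)
  expect_error(apaPileup(m, bed[1, , drop = FALSE], flank = 2e5),
               "zero usable anchors")
  expect_error(apaPileup(m, bed, flank = 1.5e4), "multiple of the bin size")
  bedOff <- transform(bed, chrom1 = "other", chrom2 = "other")
  expect_error(apaPileup(m, bedOff, flank = 3e4), "no usable anchors")
})

test_that("BEDPE files round-trip", {
  bed <- data.frame(chrom1 = "c", start1 = c(0, 100), end1 = c(10, 110),
                    chrom2 = "c", start2 = c(500, 700), end2 = c(510, 710))
  f <- tempfile()
  writeBedpe(bed, f)
  expect_equal(readBedpe(f), bed)
})
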