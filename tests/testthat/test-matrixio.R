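test_that("binPairs places pairs in the right bins and conserves counts", {
  g <- data.frame(chrom = "c1", length = 200)
  p <- data.frame(chrom1 = "c1", pos1 = c(50, 50), chrom2 = "c1",
                  pos2 = c(150, 150))
  m <- binPairs(p, g, 100)
  expect_equal(contactCounts(m$c1)[1, 2], 2)
  expect_equal(contactCounts(m$c1)[2, 1], 2)

  empty <- binPairs(p[0, ], g, 100)
  expect_true(all(contactCounts(empty$c1) == 0))

  # conservation: 1,000 random pairs on one chromosome
  set.seed(42)
  g2 <- data.frame(chrom = "cX", length = 5e6)
  p2 <- data.frame(chrom1 = "cX", pos1 = runif(1000, 0, 5e6 - 1),
                   chrom2 = "cX", pos2 = runif(1000, 0, 5e6 - 1))
  m2 <- binPairs(p2, g2, 1e5)
  C <- contactCounts(m2$cX)
  expect_equal(sum(C[upper.tri(C, diag = TRUE)]), 1000)
  expect_true(isSymmetric(C))
})

test_that("binPairs rejects bad records the way the contract says", {
  g <- data.frame(chrom = "c1", length = 200)
  p <- data.frame(chrom1 = c("c1", "cZ"), pos1 = c(10, 10),
                  chrom2 = c("c1", "cZ"), pos2 = c(20, 20))
  expect_error(binPairs(p, g, 100), "unknown chromosome")

  # out-of-range positions dropped with a report, trans pairs dropped
  p2 <- data.frame(chrom1 = c("c1", "c1", "c1"), pos1 = c(10, 500, 10),
                   chrom2 = c("c1", "c1", "c2"), pos2 = c(20, 20, 20))
  g2 <- data.frame(chrom = c("c1", "c2"), length = c(200, 200))
  expect_message(m <- binPairs(p2, g2, 100), "rejected")
  expect_equal(unname(attr(m, "dropped")), c(1, 1))
  expect_equal(sum(contactCounts(m$c1)[upper.tri(contactCounts(m$c1), diag = TRUE)]), 1)
})

test_that("binning split halves then merging equals binning the whole list", {
  set.seed(7)
  g <- data.frame(chrom = "cA", length = 2e6)
  p <- data.frame(chrom1 = "cA", pos1 = runif(400, 0, 2e6 - 1),
                  chrom2 = "cA", pos2 = runif(400, 0, 2e6 - 1))
  whole <- binPairs(p, g, 1e5)$cA
  half1 <- binPairs(p[1:200, ], g, 1e5)$cA
  half2 <- binPairs(p[201:400, ], g, 1e5)$cA
  merged <- mergeReplicates(list(half1, half2))
  expect_equal(contactCounts(merged), contactCounts(whole))
})

test_that("mergeReplicates sums counts and validates shapes", {
  A <- ContactMatrix(randomCounts(6, 1), "c", 1e4)
  Z <- ContactMatrix(matrix(0, 6, 6), "c", 1e4)
  expect_equal(contactCounts(mergeReplicates(list(A, Z))), contactCounts(A))
  expect_equal(contactCounts(mergeReplicates(list(A, A))),
               2 * contactCounts(A))
  # three Poisson replicates: merged total equals sum of totals
  reps <- lapply(1:3, function(s) ContactMatrix(randomCounts(6, s), "c", 1e4))
  tot <- sum(vapply(reps, function(m) sum(contactCounts(m)), numeric(1)))
  expect_equal(sum(contactCounts(mergeReplicates(reps))), tot)

  B <- ContactMatrix(randomCounts(5, 2), "c", 1e4)
  expect_error(mergeReplicates(list(A, B)), "disagree")
  expect_error(mergeReplicates(list(A, ContactMatrix(randomCounts(6, 3), "d", 1e4))),
               "disagree")
})

test_that("ICE balancing matches a brute-force reference iteration", {
  # small hand-checkable toy
  C <- matrix(c(0, 2, 1, 2, 0, 4, 1, 4, 0), 3, 3)
  m <- balanceICE(ContactMatrix(C, "c", 1e4), tol = 1e-14, maxIter = 10000,
                  maskQuantile = 0)
  expect_equal(balancingWeights(m), bruteIce(C, tol = 1e-14),
               tolerance = 1e-6)

  # random matrices
  for (s in 1:5) {
    C2 <- randomCounts(8, s + 10) + 1    # strictly positive, well-conditioned
    m2 <- balanceICE(ContactMatrix(C2, "c", 1e4), tol = 1e-14,
                     maxIter = 10000, maskQuantile = 0)
    expect_equal(balancingWeights(m2), bruteIce(C2, tol = 1e-14),
                 tolerance = 1e-6)
    B <- balancedCounts(m2)
    expect_true(isSymmetric(B))
    rs <- rowSums(B)
    expect_lt(var(rs) / mean(rs)^2, 1e-11)
  }
})

test_that("ICE fixed point, masking, and failure modes behave", {
  # equal row sums already: all weights equal
  C <- matrix(2, 5, 5); diag(C) <- 0
  m <- balanceICE(ContactMatrix(C, "c", 1e4), maskQuantile = 0)
  expect_equal(sd(balancingWeights(m)), 0, tolerance = 1e-12)

  # zero-coverage bin is masked, the rest balances
  C2 <- randomCounts(6, 3) + 1
  C2[4, ] <- 0; C2[, 4] <- 0
  m2 <- balanceICE(ContactMatrix(C2, "c", 1e4), maskQuantile = 0)
  expect_true(is.na(balancingWeights(m2)[4]))
  expect_equal(maskedBins(m2), 4L)
  B <- balancedCounts(m2)
  rs <- rowSums(B[-4, -4])
  expect_lt(var(rs) / mean(rs)^2, 2e-5)

  # non-convergence carries the last variance
  C3 <- randomCounts(10, 4) + 1
  expect_error(balanceICE(ContactMatrix(C3, "c", 1e4), tol = 1e-12,
                          maxIter = 1L),
               "did not converge")
  expect_error(balanceICE(ContactMatrix(matrix(0, 3, 3), "c", 1e4)),
               "all bins masked")
})

test_that("balancing is invariant to global count scaling", {
  C <- randomCounts(7, 9) + 1
  w1 <- balancingWeights(balanceICE(ContactMatrix(C, "c", 1e4),
                                    maskQuantile = 0, tol = 1e-10))
  w2 <- balancingWeights(balanceICE(ContactMatrix(3 * C, "c", 1e4),
                                    maskQuantile = 0, tol = 1e-10))
  expect_equal(w1, w2, tolerance = 1e-8)
})

test_that("matrix round-trip through bin table + COO is exact", {
  set.seed(5)
  C <- randomCounts(12, 20)
  C[C < 7] <- 0                                   # sparse
  m <- ContactMatrix(C, "chrT", 2e4, chromLength = 12 * 2e4 - 5000)
  b1 <- tempfile(); c1 <- tempfile()
  writeContactMatrix(m, b1, c1)
  m2 <- readContactMatrix(b1, c1)
  expect_equal(contactCounts(m2), contactCounts(m))
  expect_equal(chromName(m2), "chrT")
  expect_equal(binSize(m2), 2e4)
  expect_equal(chromLength(m2), 12 * 2e4 - 5000)
  # write-read-write is byte identical (canonical form)
  b2 <- tempfile(); c2 <- tempfile()
  writeContactMatrix(m2, b2, c2)
  expect_identical(readLines(c1), readLines(c2))
  expect_identical(readLines(b1), readLines(b2))
})

test_that("COO reading symmetrizes the upper triangle and rejects bad input", {
  bin <- tempfile(); coo <- tempfile()
  writeLines(c("chrom\tstart\tend\tbin_id",
               "c\t0\t100\t0", "c\t100\t200\t1", "c\t200\t300\t2"), bin)
  writeLines(c("bin1_id\tbin2_id\tcount", "0\t1\t5", "1\t2\t2"), coo)
  m <- readContactMatrix(bin, coo)
  expect_equal(contactCounts(m)[2, 1], 5)
  expect_equal(contactCounts(m)[3, 2], 2)

  writeLines(c("bin1_id\tbin2_id\tcount", "0\t1\t-3"), coo)
  expect_error(readContactMatrix(bin, coo), "negative count")
  writeLines(c("bin1_id\tbin2_id\tcount", "0\t9\t3"), coo)
  expect_error(readContactMatrix(bin, coo), "out of range")
})

test_that("chrom.sizes and pair lists round-trip and validate", {
  g <- data.frame(chrom = c("chr1", "chr2"), length = c(5e6, 3e6))
  f <- tempfile()
  writeChromSizes(g, f)
  expect_equal(readChromSizes(f), g)

  p <- data.frame(chrom1 = "chr1", pos1 = c(10, 20), chrom2 = "chr1",
                  pos2 = c(30, 40))
  fp <- tempfile()
  writeContactPairs(p, fp)
  expect_equal(readContactPairs(fp), p)

  writeLines(c("chr1\t10\tchr1", "chr1\t10\tchr1\t20"), fp)
  expect_error(readContactPairs(fp), "line 1")
  writeLines(c("chr1\tten\tchr1\t20"), fp)
  expect_error(readContactPairs(fp), "non-numeric")

  expect_error(validateGenome(data.frame(chrom = c("a", "a"),
                                         length = c(1, 2))), "unique")
  expect_error(validateGenome(data.frame(chrom = "a", length = -5)),
               "positive")
})

test_that("bin tables use 0-based half-open bins with a clipped last bin", {
  g <- data.frame(chrom = "c", length = 250)
  bt <- makeBinTable(g, 100)
  expect_equal(nrow(bt), 3)
  expect_equal(bt$start, c(0, 100, 200))
  expect_equal(bt$end, c(100, 200, 250))
  expect_equal(bt$bin_id, 0:2)
})
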