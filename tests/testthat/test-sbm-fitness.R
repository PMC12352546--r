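# closed-form eigenvalues of a 2x2 symmetric matrix: independent oracle
eigen2x2 <- function(m) {
  tr <- m[1, 1] + m[2, 2]
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  disc <- sqrt(tr^2 / 4 - dt)
  c(tr / 2 + disc, tr / 2 - disc)
}

test_that("block counts match exhaustive pair enumeration on the toys", {
  part <- toyPartition()
  bc <- blockCounts(toyBinaryGraph(), part)
  expect_equal(bc@c, matrix(c(3, 1, 1, 1), 2))
  expect_equal(bc@cMax, matrix(c(3, 9, 9, 3), 2))

  bw <- blockCounts(thresholdWeighted(toyWeightedFC(), 0), part)
  expect_equal(bw@c, matrix(c(2.4, 0.2, 0.2, 0.6), 2))

  empty <- fcprom:::FcGraph(matrix(0, 6, 6), "binary")
  expect_equal(blockCounts(empty, part)@c, matrix(0, 2, 2))

  expect_error(blockCounts(toyBinaryGraph(), Partition(c(1, 1, 2))),
               "size mismatch")
})

test_that("SBM inference reproduces the hand-computed toy parameters", {
  part <- toyPartition()
  params <- inferSBM(blockCounts(toyBinaryGraph(), part), 6)
  expect_equal(blockProbs(params), c(0.5, 0.5))
  expect_equal(edgeProbMatrix(params), matrix(c(1, 1/9, 1/9, 1/3), 2))
  expect_equal(profileMatrix(params), matrix(c(3, 1/3, 1/3, 1), 2))

  pw <- inferSBM(blockCounts(thresholdWeighted(toyWeightedFC(), 0), part), 6)
  expect_equal(edgeProbMatrix(pw), matrix(c(0.8, 0.2/9, 0.2/9, 0.2), 2))
  expect_equal(profileMatrix(pw), matrix(c(2.4, 0.2/3, 0.2/3, 0.6), 2))

  # constant W collapses to an Erdos-Renyi model: PQ has rank 1
  er <- sbmFromProbabilities(c(0.3, 0.7), matrix(0.2, 2, 2), 50)
  expect_equal(qr(profileMatrix(er))$rank, 1L)
})

test_that("SNR matches the 2x2 closed-form eigen solution on the toy", {
  part <- toyPartition()
  params <- inferSBM(blockCounts(toyBinaryGraph(), part), 6)
  ev <- eigen2x2(profileMatrix(params))
  s <- snr(params)
  expect_equal(s@lambda1, ev[1], tolerance = 1e-10)
  expect_equal(s@lambda2, ev[2], tolerance = 1e-10)
  expect_equal(snrValue(s), ev[2]^2 / ev[1], tolerance = 1e-10)
  # frozen from the oracle above: 2 +/- sqrt(10)/3
  expect_equal(s@lambda1, 3.05409255338946, tolerance = 1e-10)
  expect_equal(s@lambda2, 0.945907446610540, tolerance = 1e-10)
  expect_equal(snrValue(s), 0.292964565386298, tolerance = 1e-10)
  expect_false(isWeaklyRecoverable(s))
})

test_that("symmetric two-block SBM follows the closed form (a-b)^2/(2(a+b))", {
  n <- 100
  for (ab in list(c(6, 2), c(8, 2), c(10, 3), c(4, 4), c(0.5, 3))) {
    a <- ab[1]; b <- ab[2]
    params <- sbmFromProbabilities(c(0.5, 0.5),
                                   matrix(c(a, b, b, a) / n, 2), n)
    expect_equal(snrValue(snr(params)), closedFormSNR(a, b),
                 tolerance = 1e-10)
  }
  # a=6, b=2 sits exactly on the weak-recovery boundary: PQ=[[3,1],[1,3]]
  p62 <- sbmFromProbabilities(c(0.5, 0.5), matrix(c(6, 2, 2, 6) / 100, 2), 100)
  s <- snr(p62)
  expect_equal(s@lambda1, 4, tolerance = 1e-12)
  expect_equal(s@lambda2, 2, tolerance = 1e-12)
  expect_equal(snrValue(s), 1, tolerance = 1e-12)
  # the criterion is strict: SNR of exactly 1 is not weakly recoverable
  expect_false(isWeaklyRecoverable(1.0))
  expect_true(isWeaklyRecoverable(1.8))
  expect_false(isWeaklyRecoverable(new("SNRValue", snr = 1, lambda1 = 4,
                                       lambda2 = 2,
                                       weaklyRecoverable = FALSE)))
})

test_that("ER collapse and degenerate inputs give SNR exactly 0", {
  er <- sbmFromProbabilities(c(0.25, 0.25, 0.5), matrix(0.3, 3, 3), 40)
  s <- snr(er)
  expect_equal(s@lambda2, 0, tolerance = 1e-12)
  expect_equal(snrValue(s), 0, tolerance = 1e-12)

  single <- sbmFromProbabilities(1, matrix(0.3, 1, 1), 40)
  expect_equal(snrValue(snr(single)), 0)

  emptyCounts <- blockCounts(fcprom:::FcGraph(matrix(0, 6, 6), "binary"),
                             toyPartition())
  expect_equal(snrValue(snr(inferSBM(emptyCounts, 6))), 0)
})

test_that("similarity-transform SNR agrees with a direct eigensolve of PQ", {
  for (seed in 1:60) {
    n <- withr::with_seed(seed, sample(10:60, 1))
    k <- withr::with_seed(seed + 1000, sample(2:6, 1))
    g <- thresholdBinarize(randomConnectome(n, seed), 0.4)
    part <- randomPartition(n, k, seed + 2000)
    params <- inferSBM(blockCounts(g, part), n)
    expect_equal(snrValue(snr(params)), snrDirect(params), tolerance = 1e-8)
  }
})

test_that("SNR is invariant under node permutation and community relabeling", {
  fc <- randomConnectome(30, seed = 5)
  part <- randomPartition(30, 4, seed = 6)
  g <- thresholdBinarize(fc, 0.3)
  ref <- snrValue(graphSNR(g, part))

  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(30))
    gp <- fcprom:::FcGraph(matrixValues(g)[perm, perm], "binary")
    pp <- Partition(membership(part)[perm])
    expect_equal(snrValue(graphSNR(gp, pp)), ref, tolerance = 1e-10)

    relab <- withr::with_seed(seed + 50, sample(10, 4))
    pr <- Partition(relab[membership(part)])
    expect_equal(snrValue(graphSNR(g, pr)), ref, tolerance = 1e-10)
  }
})

test_that("pair-counting conventions agree off the diagonal", {
  for (seed in 1:10) {
    n <- 30
    g <- thresholdBinarize(randomConnectome(n, seed), 0.3)
    part <- randomPartition(n, 3, seed + 100)
    wPairs <- edgeProbMatrix(inferSBM(blockCounts(g, part, cmax = "pairs"), n))
    wOuter <- edgeProbMatrix(inferSBM(blockCounts(g, part, cmax = "outer"), n))
    off <- row(wPairs) != col(wPairs)
    expect_equal(wPairs[off], wOuter[off], tolerance = 1e-12)
    # diagonals differ exactly by the self-pair factor (omega-1)/omega
    om <- communitySizes(part)
    expect_equal(diag(wOuter), diag(wPairs) * (om - 1) / om,
                 tolerance = 1e-12)
  }
})
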