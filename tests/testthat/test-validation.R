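test_that("partition shuffles preserve sizes and are seed-reproducible", {
  part <- randomPartition(40, 5, seed = 2)
  for (seed in 1:5) {
    sh <- shufflePartition(part, seed)
    expect_equal(communitySizes(sh), communitySizes(part))
    expect_identical(membership(shufflePartition(part, seed)), membership(sh))
  }
  expect_false(identical(membership(shufflePartition(part, 1)),
                         membership(shufflePartition(part, 2))))
  one <- Partition(rep(1, 10))
  expect_identical(membership(shufflePartition(one, 3)), membership(one))
})

test_that("null ensemble SNR sits below the true-partition SNR on planted graphs", {
  w <- matrix(0.02, 4, 4); diag(w) <- 0.25
  sim <- sampleSBM(rep(25, 4), w, seed = 1)  # n = 100, small-scale analogue
  fc <- ConnectomeMatrix(matrixValues(sim$graph))
  grid <- c(0, 0.5, 1)  # a binary graph is threshold-invariant on (0, 1]
  ens <- nullSNR(fc, sim$partition, grid, nShuffles = 20, seed = 0)
  trueSnr <- snrValue(graphSNR(sim$graph, sim$partition))
  expect_gte(ens@minSnr, 0)
  expect_lt(ens@maxSnr, trueSnr)
  expect_gt(trueSnr, 1)

  # ER graph: both true and null prominence are near zero
  er <- sampleSBM(rep(25, 4), matrix(0.1, 4, 4), seed = 2)
  fcEr <- ConnectomeMatrix(matrixValues(er$graph))
  ensEr <- nullSNR(fcEr, er$partition, grid, nShuffles = 5, seed = 0)
  expect_lt(snrValue(graphSNR(er$graph, er$partition)), 0.5)
  expect_lt(ensEr@maxSnr, 0.5)

  one <- nullSNR(fc, sim$partition, grid, nShuffles = 1, seed = 0)
  expect_length(one@profiles, 1)
  expect_equal(nrow(nullToTable(one)), length(grid))
})

test_that("modularity matches closed forms and igraph's implementation", {
  # two disjoint triangles split into their triangles: Q = 2 (1/2 - 1/4)
  m <- matrix(0, 6, 6)
  m[rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))] <- 1
  g <- fcprom:::FcGraph(m + t(m), "binary")
  tri <- Partition(rep(1:2, each = 3))
  expect_equal(modularityQ(g, tri), 0.5)

  # single community: Q = 0 at alpha = 1
  expect_equal(modularityQ(g, Partition(rep(1, 6))), 0)

  # singleton communities: Q = -sum((k_u / 2m)^2)
  deg <- rowSums(matrixValues(g))
  expect_equal(modularityQ(g, Partition(1:6)),
               -sum((deg / sum(deg))^2))

  # agreement with igraph on random graphs and partitions, incl. weighted
  for (seed in 1:5) {
    fc <- randomConnectome(20, seed)
    part <- randomPartition(20, 4, seed + 10)
    gb <- thresholdBinarize(fc, 0.3)
    gw <- thresholdWeighted(fc, 0.3)
    igb <- igraph::graph_from_adjacency_matrix(matrixValues(gb),
                                               mode = "undirected")
    igw <- igraph::graph_from_adjacency_matrix(matrixValues(gw),
                                               mode = "undirected",
                                               weighted = TRUE)
    expect_equal(modularityQ(gb, part),
                 igraph::modularity(igb, membership(part)), tolerance = 1e-12)
    expect_equal(modularityQ(gw, part),
                 igraph::modularity(igw, membership(part),
                                    weights = igraph::E(igw)$weight),
                 tolerance = 1e-12)
  }

  expect_error(modularityQ(fcprom:::FcGraph(matrix(0, 4, 4), "binary"),
                           Partition(rep(1, 4))), "no edges")
})

test_that("modularity is invariant to node reordering", {
  fc <- randomConnectome(15, seed = 8)
  g <- thresholdBinarize(fc, 0.2)
  part <- randomPartition(15, 3, seed = 9)
  q <- modularityQ(g, part)
  perm <- withr::with_seed(1, sample(15))
  gp <- fcprom:::FcGraph(matrixValues(g)[perm, perm], "binary")
  pp <- Partition(membership(part)[perm])
  expect_equal(modularityQ(gp, pp), q, tolerance = 1e-12)
})

test_that("modularity maximization recovers planted structure", {
  # two disjoint 5-cliques
  m <- matrix(0, 10, 10)
  m[1:5, 1:5] <- 1; m[6:10, 6:10] <- 1; diag(m) <- 0
  g <- fcprom:::FcGraph(m, "binary")
  det <- maximizeQ(g, seed = 1)
  expect_equal(ami(det, Partition(rep(1:2, each = 5))), 1)
  expect_identical(membership(maximizeQ(g, seed = 1)),
                   membership(det))  # deterministic given seed

  # complete graph: no structure; Q <= 0 but >= the singleton baseline
  km <- matrix(1, 8, 8); diag(km) <- 0
  kg <- fcprom:::FcGraph(km, "binary")
  detK <- maximizeQ(kg, seed = 1)
  expect_lte(modularityQ(kg, detK), 0)
  expect_gte(modularityQ(kg, detK), modularityQ(kg, Partition(1:8)))

  # strong planted 2-block SBM
  w <- matrix(c(0.3, 0.02, 0.02, 0.3), 2)
  sim <- sampleSBM(c(100, 100), w, seed = 3)
  det2 <- maximizeQ(sim$graph, seed = 0)
  expect_gt(ami(det2, sim$partition), 0.9)
  expect_gt(modularityQ(sim$graph, sim$partition),
            modularityQ(sim$graph, shufflePartition(sim$partition, 1)))
})

test_that("maximize_q never falls below the trivial baselines", {
  for (seed in 1:4) {
    g <- thresholdBinarize(randomConnectome(25, seed), 0.4)
    if (edgeCount(g) == 0) next
    q <- modularityQ(g, maximizeQ(g, seed = seed))
    expect_gte(q, modularityQ(g, Partition(rep(1, 25))))
    expect_gte(q, modularityQ(g, Partition(1:25)))
  }
})

test_that("AMI handles identity, relabeling, chance and symmetry", {
  p <- randomPartition(30, 4, seed = 1)
  expect_equal(ami(p, p), 1)
  relab <- Partition(c(3, 1, 4, 2)[membership(p)])
  expect_equal(ami(p, relab), 1)

  # crossed pairs: MI = 0 but E[MI] > 0, so AMI <= 0
  a <- Partition(c(1, 1, 2, 2))
  b <- Partition(c(1, 2, 1, 2))
  expect_equal(mutualInformation(a, b), 0, tolerance = 1e-12)
  expect_gt(expectedMutualInformation(c(2, 2), c(2, 2)), 0)
  expect_lte(ami(a, b), 0)

  # symmetric, bounded, invariant to label permutation
  for (seed in 2:5) {
    p1 <- randomPartition(40, 3, seed)
    p2 <- randomPartition(40, 5, seed + 20)
    expect_equal(ami(p1, p2), ami(p2, p1), tolerance = 1e-12)
    expect_gt(ami(p1, p2), -1)
    expect_lte(ami(p1, p2), 1)
  }
  expect_error(ami(a, Partition(c(1, 2, 1))), "size mismatch")
})

test_that("exact expected MI matches a small-case permutation enumeration", {
  # n = 4, margins (2,2) x (2,2): enumerate all 4! assignments directly
  perms <- matrix(c(1,2,3,4, 1,2,4,3, 1,3,2,4, 1,3,4,2, 1,4,2,3, 1,4,3,2,
                    2,1,3,4, 2,1,4,3, 2,3,1,4, 2,3,4,1, 2,4,1,3, 2,4,3,1,
                    3,1,2,4, 3,1,4,2, 3,2,1,4, 3,2,4,1, 3,4,1,2, 3,4,2,1,
                    4,1,2,3, 4,1,3,2, 4,2,1,3, 4,2,3,1, 4,3,1,2, 4,3,2,1),
                  ncol = 4, byrow = TRUE)
  base <- Partition(c(1, 1, 2, 2))
  mis <- apply(perms, 1, function(pm)
    mutualInformation(base, Partition(c(1, 1, 2, 2)[pm])))
  expect_equal(expectedMutualInformation(c(2, 2), c(2, 2)), mean(mis),
               tolerance = 1e-12)
})

test_that("AMI agrees with scikit-learn's implementation", {
  p1 <- randomPartition(60, 4, seed = 31)
  p2 <- randomPartition(60, 3, seed = 32)
  py <- sprintf(
    "from sklearn.metrics import adjusted_mutual_info_score as f; print(repr(f([%s], [%s])))",
    paste(membership(p1), collapse = ","),
    paste(membership(p2), collapse = ","))
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  skl <- as.numeric(sub("np.float64\\((.*)\\)", "\\1", tail(out, 1)))
  expect_equal(ami(p1, p2), skl, tolerance = 1e-8)
})

test_that("back-test: AMI tracks SNR while Q keeps rising, on planted input", {
  sim <- sampleCohort()  # reference study conditions
  ga <- groupAverage(sim$stack)
  bt <- backtest(ga, sim$partition, seed = 1)
  expect_named(bt, c("tau", "q_score", "ami_q", "snr"))

  snrPeak <- bt$tau[which.max(bt$snr)]
  amiPeak <- bt$tau[which.max(bt$ami_q)]
  expect_lte(abs(snrPeak - amiPeak), 0.10 + 1e-9)  # within two grid steps

  # Q does not decline past the SNR peak: its maximum is attained (and
  # plateaus) at thresholds well beyond it, so Q alone cannot single out
  # a threshold for the a priori partition
  past <- bt$q_score[bt$tau > snrPeak]
  expect_gte(max(past, na.rm = TRUE), bt$q_score[match(snrPeak, bt$tau)])
  lastQmax <- max(bt$tau[which(bt$q_score == max(bt$q_score, na.rm = TRUE))])
  expect_gte(lastQmax, snrPeak + 0.10)

  # empty-graph thresholds are NA for Q and AMI
  expect_true(all(is.na(bt$q_score[bt$tau == 1])))
  expect_true(all(is.na(bt$ami_q[bt$tau == 1])))

  # two-clique toy: detection recovers the cliques at tau = 0
  m <- matrix(0, 10, 10); m[1:5, 1:5] <- 0.9; m[6:10, 6:10] <- 0.9
  diag(m) <- 0
  btc <- backtest(ConnectomeMatrix(m), Partition(rep(1:2, each = 5)),
                  grid = c(0, 0.5), seed = 1)
  expect_equal(btc$ami_q[1], 1)
})
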