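#' Sample a planted-partition (SBM) binary graph
#'
#' Each unordered node pair {u, v} is an edge independently with
#' probability w[sigma_u, sigma_v]. Reproducible given the seed.
#'
#' @param sizes length-k vector of community sizes (each >= 1).
#' @param w k x k symmetric matrix of edge probabilities in [0, 1].
#' @param seed integer RNG seed.
#' @return list with elements `graph` (binary [FcGraph-class]) and
#'   `partition` (the planted [Partition-class]).
#' @examples
#' g <- sampleSBM(c(50, 50), matrix(c(0.3, 0.02, 0.02, 0.3), 2), seed = 1)
#' graphSNR(g$graph, g$partition)
#' @export
sampleSBM <- function(sizes, w, seed) {
  w <- as.matrix(w)
  if (any(w < 0 | w > 1)) stop("edge probabilities must lie in [0, 1]")
  if (any(sizes < 1)) stop("community sizes must be >= 1")
  k <- length(sizes)
  stopifnot(nrow(w) == k, ncol(w) == k)
  sigma <- rep(seq_len(k), times = sizes)
  n <- sum(sizes)
  probs <- w[sigma, sigma, drop = FALSE]
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- withr::with_seed(as.integer(seed),
                            (stats::runif(sum(ut)) < probs[ut]) * 1)
  a <- a + t(a)
  list(graph = FcGraph(a, "binary"), partition = Partition(sigma))
}

#' Sample a connectome-like matrix with planted block structure
#'
#' Off-diagonal entries are drawn independently per unordered pair from
#' a normal distribution whose mean is `muWithin` for pairs inside one
#' block and `muBetween` for pairs across blocks, with common standard
#' deviation `sd`, then clipped to [-0.999, 0.999] (avoiding |r| = 1
#' degeneracies). This emulates a functional connectome with a planted
#' functional-network partition and analytically controlled contrast; it
#' does not emulate the dependence structure a latent-time-series
#' pipeline would induce.
#'
#' @param sizes length-k vector of block sizes.
#' @param muWithin mean within-block association.
#' @param muBetween mean between-block association.
#' @param sd entry-level noise standard deviation.
#' @param seed integer RNG seed.
#' @param label identifier for the resulting matrix.
#' @return list with elements `fc` ([ConnectomeMatrix-class]) and
#'   `partition` ([Partition-class]).
#' @export
sampleFC <- function(sizes, muWithin = 0.6, muBetween = 0.1, sd = 0.02,
                     seed = 0, label = "synthetic") {
  if (any(sizes < 1)) stop("block sizes must be >= 1")
  sigma <- rep(seq_along(sizes), times = sizes)
  fc <- withr::with_seed(as.integer(seed),
                         .sampleFCBody(sigma, muWithin, muBetween, sd))
  list(fc = ConnectomeMatrix(fc, label = label, tol = 1e-8),
       partition = Partition(sigma))
}

.sampleFCBody <- function(sigma, muWithin, muBetween, sd) {
  n <- length(sigma)
  mu <- matrix(muBetween, n, n)
  same <- outer(sigma, sigma, `==`)
  mu[same] <- muWithin
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- mu[ut] + if (sd > 0) stats::rnorm(sum(ut), 0, sd) else 0
  a <- pmin(pmax(a, -0.999), 0.999)
  a <- a + t(a)
  diag(a) <- 0
  a
}

#' Sample a cohort of connectome-like matrices
#'
#' Per subject, the block means are jittered by independent
#' normal(0, subjectSd) draws (a crude model of trait-level differences
#' in functional-coupling strength) before entry-level sampling as in
#' [sampleFC()]. Subject s uses the derived seed `seed + s` for
#' auditability.
#'
#' Defaults encode the package's reference study conditions: 4 planted
#' blocks of 30 nodes, within/between contrast 0.6 vs 0.1, entry noise
#' sd 0.02 (the order of the sampling error of a Pearson correlation
#' estimated from roughly a thousand time points), subject jitter 0.1,
#' and a cohort of 20 subjects.
#'
#' @param gamma number of subjects (>= 1).
#' @param sizes length-k vector of block sizes.
#' @param muWithin,muBetween,sd population-level parameters, see
#'   [sampleFC()].
#' @param subjectSd standard deviation of the per-subject jitter applied
#'   to both block means.
#' @param seed base integer seed.
#' @return list with elements `stack` ([CohortStack-class]) and
#'   `partition` (the planted [Partition-class]).
#' @export
sampleCohort <- function(gamma = 20, sizes = c(30, 30, 30, 30),
                         muWithin = 0.6, muBetween = 0.1, sd = 0.02,
                         subjectSd = 0.1, seed = 7) {
  stopifnot(gamma >= 1)
  sigma <- rep(seq_along(sizes), times = sizes)
  mats <- lapply(seq_len(gamma), function(s) {
    vals <- withr::with_seed(as.integer(seed + s), {
      jw <- stats::rnorm(1, 0, subjectSd)
      jb <- stats::rnorm(1, 0, subjectSd)
      .sampleFCBody(sigma, muWithin + jw, muBetween + jb, sd)
    })
    ConnectomeMatrix(vals, label = sprintf("subject_%03d", s), tol = 1e-8)
  })
  list(stack = CohortStack(mats), partition = Partition(sigma))
}

#' Closed-form SNR of the symmetric two-block SBM
#'
#' For two equal blocks with p = (1/2, 1/2) and W = (1/n) [[a, b], [b,
#' a]], the community profile matrix is PQ = (1/2) [[a, b], [b, a]] with
#' eigenvalues (a + b)/2 and (a - b)/2, so SNR = (a - b)^2 / (2 (a + b))
#' exactly. The Kesten-Stigum weak-recovery boundary is SNR = 1, i.e.
#' (a - b)^2 = 2 (a + b). Used as an analytic oracle for the inference +
#' eigen pipeline.
#'
#' @param a expected within-block degree parameter (>= 0).
#' @param b expected between-block degree parameter (>= 0), a + b > 0.
#' @return scalar SNR.
#' @examples
#' closedFormSNR(6, 2)  # exactly 1: on the weak-recovery boundary
#' @export
closedFormSNR <- function(a, b) {
  stopifnot(a >= 0, b >= 0)
  if (a + b == 0) stop("a + b must be positive")
  (a - b)^2 / (2 * (a + b))
}
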