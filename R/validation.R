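#' Size-preserving partition shuffle
#'
#' Uniformly random permutation of the node-to-community assignment: the
#' community sizes omega are preserved exactly, only which node carries
#' which label changes. Reproducible given the seed.
#'
#' @param part a [Partition-class].
#' @param seed integer RNG seed.
#' @return A [Partition-class] with identical omega.
#' @export
shufflePartition <- function(part, seed) {
  sigma <- withr::with_seed(as.integer(seed),
                            part@sigma[sample.int(length(part@sigma))])
  new("Partition", sigma = sigma, k = part@k, omega = part@omega)
}

#' Null SNR ensemble under partition shuffles
#'
#' Repeats [sweepSNR()] with independently shuffled partitions
#' (shuffle s uses seed + s - 1), recording the ensemble of profiles and
#' the overall maximum and minimum SNR across shuffles and thresholds.
#' Used to check that the prominence of the a priori partition is not an
#' artifact of the graph's density or degree profile: for a genuinely
#' structured partition the whole null ensemble should sit below the
#' weak-recovery threshold SNR = 1, giving the ordering
#' 0 <= SNR_null < SNR(true partition).
#'
#' @param fc a [ConnectomeMatrix-class].
#' @param part the a priori [Partition-class] (its sizes define the null).
#' @param grid ascending thresholds (default [tauGrid()]).
#' @param nShuffles number of shuffles (default 100).
#' @param seed base seed (default 0).
#' @param mode "binary" or "weighted".
#' @param cmax pair-counting convention, see [blockCounts()].
#' @return A [NullEnsemble-class].
#' @export
nullSNR <- function(fc, part, grid = tauGrid(), nShuffles = 100, seed = 0,
                    mode = c("binary", "weighted"), cmax = "pairs") {
  mode <- match.arg(mode)
  stopifnot(nShuffles >= 1)
  profiles <- lapply(seq_len(nShuffles), function(s) {
    shuf <- shufflePartition(part, seed + s - 1)
    sweepSNR(fc, shuf, grid, mode = mode, cmax = cmax)
  })
  allSnr <- unlist(lapply(profiles, function(p) p@snrs))
  new("NullEnsemble", nShuffles = as.integer(nShuffles),
      seed = as.integer(seed), profiles = profiles,
      maxSnr = max(allSnr), minSnr = min(allSnr))
}

#' Convert a null ensemble to a long table
#'
#' @param ens a [NullEnsemble-class].
#' @return data.frame with columns shuffle_id, tau, snr.
#' @export
nullToTable <- function(ens) {
  do.call(rbind, lapply(seq_along(ens@profiles), function(s) {
    p <- ens@profiles[[s]]
    data.frame(shuffle_id = s, tau = p@taus, snr = p@snrs)
  }))
}

#' Newman modularity score
#'
#' Q = (1/2m) * sum_{u,v} (A_uv - alpha * k_u k_v / (2m)) * delta(sigma_u,
#' sigma_v), summed over ordered node pairs, with the configuration-model
#' null and tuning parameter alpha (default 1). For weighted graphs, k
#' are weighted degrees (strengths) and 2m is the total weight; the 2m
#' normalization makes Q comparable across graph sizes.
#'
#' @param g an [FcGraph-class] with at least one edge.
#' @param part a [Partition-class].
#' @param alpha resolution/tuning parameter (default 1).
#' @return scalar Q; 0 for the single-community partition at alpha = 1.
#' @export
modularityQ <- function(g, part, alpha = 1) {
  if (g@m == 0L) stop("no edges: modularity is undefined on an empty graph")
  if (nrow(g@values) != length(part@sigma)) stop("size mismatch")
  a <- g@values
  twoM <- sum(a)
  deg <- rowSums(a)
  q <- 0
  for (i in seq_len(part@k)) {
    idx <- part@sigma == i
    q <- q + sum(a[idx, idx]) / twoM - alpha * (sum(deg[idx]) / twoM)^2
  }
  q
}

#' Greedy modularity maximization
#'
#' Multi-level (Louvain-style) local-move + aggregation heuristic for
#' maximizing [modularityQ()] at alpha = 1, applied to binary or weighted
#' graphs. The node order is shuffled once by the seed, making the
#' result deterministic given (graph, seed). A single pass is performed
#' (no consensus clustering).
#'
#' @param g an [FcGraph-class] with at least one edge.
#' @param seed integer seed (default 0).
#' @return A [Partition-class] (labels in order of first appearance over
#'   nodes). Isolated nodes end up in their own communities.
#' @export
maximizeQ <- function(g, seed = 0) {
  if (g@m == 0L) stop("no edges: nothing to cluster")
  n <- nrow(g@values)
  withr::with_seed(as.integer(seed), {
    perm <- sample.int(n)
    ig <- .asIgraph(FcGraph(g@values[perm, perm], g@mode))
    comm <- igraph::cluster_louvain(ig)
  })
  lab <- integer(n)
  lab[perm] <- igraph::membership(comm)
  Partition(lab)
}

.entropyNats <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Mutual information between two partitions (nats)
#'
#' @param p1,p2 [Partition-class] objects on the same node set.
#' @return scalar MI in nats.
#' @export
mutualInformation <- function(p1, p2) {
  if (length(p1@sigma) != length(p2@sigma)) stop("size mismatch")
  n <- length(p1@sigma)
  tab <- table(p1@sigma, p2@sigma)
  a <- rowSums(tab)
  b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
  }
  unname(mi)
}

#' Exact expected mutual information under the hypergeometric model
#'
#' E[MI] over random contingency tables with the observed margins fixed
#' (permutation model); the exact finite sum, not a Monte-Carlo estimate.
#'
#' @param a,b integer margin vectors (cluster sizes of the two
#'   partitions), with equal sums n.
#' @return scalar expected MI in nats.
#' @export
expectedMutualInformation <- function(a, b) {
  n <- sum(a)
  stopifnot(sum(b) == n)
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (lo > hi) next
    nij <- lo:hi
    logp <- lchoose(ai, nij) + lchoose(n - ai, bj - nij) - lchoose(n, bj)
    emi <- emi + sum((nij / n) * log(n * nij / (ai * bj)) * exp(logp))
  }
  emi
}

#' Adjusted mutual information
#'
#' AMI = (MI - E[MI]) / (mean(H1, H2) - E[MI]) with the exact
#' hypergeometric expectation over contingency tables with fixed margins
#' and entropies in nats. Equals 1 for identical partitions (up to any
#' relabeling), is symmetric in its arguments, and is <= 0 for
#' partitions that agree no better than chance.
#'
#' @param p1,p2 [Partition-class] objects on the same node set.
#' @return scalar AMI in (-1, 1].
#' @export
ami <- function(p1, p2) {
  if (length(p1@sigma) != length(p2@sigma)) stop("size mismatch")
  h1 <- .entropyNats(p1@omega)
  h2 <- .entropyNats(p2@omega)
  if (h1 == 0 && h2 == 0) return(1)   # both trivial single-community
  mi <- mutualInformation(p1, p2)
  emi <- expectedMutualInformation(p1@omega, p2@omega)
  denom <- (h1 + h2) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (mi - emi) / denom
}

#' Normalized mutual information
#'
#' NMI = MI / mean(H1, H2), without the chance adjustment; offered as an
#' alternative agreement score.
#'
#' @inheritParams ami
#' @return scalar NMI in [0, 1].
#' @export
nmi <- function(p1, p2) {
  h1 <- .entropyNats(p1@omega)
  h2 <- .entropyNats(p2@omega)
  if (h1 == 0 && h2 == 0) return(1)
  mutualInformation(p1, p2) / ((h1 + h2) / 2)
}

#' Back-test of SNR against modularity-based community detection
#'
#' Per threshold: threshold the connectome, run greedy modularity
#' maximization, record the detected partition's Q score, its adjusted
#' mutual information with the a priori partition, and the SNR of the
#' a priori partition on the same graph. Thresholds at which the graph
#' is empty yield NA for Q and AMI (SNR is 0 there).
#'
#' A prominent partition should make the SNR-vs-tau and AMI-vs-tau peaks
#' agree, while Q keeps rising with tau (fragmentation inflates Q), which
#' is why Q alone cannot pick a threshold for an a priori partition.
#'
#' @param fc a [ConnectomeMatrix-class].
#' @param part the a priori [Partition-class].
#' @param grid ascending thresholds (default [tauGrid()]).
#' @param mode "binary" (default: detection on the masked graph) or
#'   "weighted".
#' @param seed seed for the detection heuristic.
#' @param cmax pair-counting convention, see [blockCounts()].
#' @param score "ami" (default) or "nmi".
#' @return data.frame with columns tau, q_score, ami_q, snr.
#' @export
backtest <- function(fc, part, grid = tauGrid(), mode = c("binary", "weighted"),
                     seed = 0, cmax = "pairs", score = c("ami", "nmi")) {
  mode <- match.arg(mode)
  score <- match.arg(score)
  agree <- if (score == "ami") ami else nmi
  thr <- if (mode == "binary") thresholdBinarize else thresholdWeighted
  rows <- lapply(grid, function(tau) {
    g <- thr(fc, tau)
    s <- graphSNR(g, part, cmax = cmax)@snr
    if (g@m == 0L) {
      return(data.frame(tau = tau, q_score = NA_real_, ami_q = NA_real_,
                        snr = s))
    }
    det <- maximizeQ(g, seed = seed)
    data.frame(tau = tau, q_score = modularityQ(g, det),
               ami_q = agree(det, part), snr = s)
  })
  do.call(rbind, rows)
}
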