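#' Per-block edge statistics for a graph + partition
#'
#' Computes the statistical summary C of the graph's edges with respect
#' to the a priori partition: in binary mode, the number of edges whose
#' endpoints lie in block pair (i, j); in weighted mode, the sum of
#' absolute edge weights per block pair. cMax holds the number of node
#' pairs available to each block pair.
#'
#' Two pair-counting conventions are supported. The default,
#' `cmax = "pairs"`, counts unordered node pairs with self-pairs
#' excluded: cMax_ij = omega_i * omega_j for i != j and
#' omega_i (omega_i - 1) / 2 on the diagonal, with C counted the same way
#' — the correct convention for simple graphs. `cmax = "outer"` uses the
#' literal outer product omega %*% t(omega) (diagonal omega_i^2, which
#' includes self-pairs) with C counted over ordered pairs; the two
#' conventions give identical W = C / cMax off the diagonal and differ on
#' the diagonal only by the O(1/omega_i) self-pair term.
#'
#' @param g an [FcGraph-class].
#' @param part a [Partition-class] on the same node set.
#' @param cmax `"pairs"` (default) or `"outer"`.
#' @return A [BlockCounts-class].
#' @export
blockCounts <- function(g, part, cmax = c("pairs", "outer")) {
  cmax <- match.arg(cmax)
  n <- nrow(g@values)
  if (n != length(part@sigma)) {
    stop("size mismatch: graph has ", n, " nodes, partition ",
         length(part@sigma))
  }
  k <- part@k
  z <- matrix(0, n, k)
  z[cbind(seq_len(n), part@sigma)] <- 1
  cOrd <- t(z) %*% g@values %*% z   # ordered-pair sums; diagonal doubled
  om <- as.numeric(part@omega)
  if (cmax == "pairs") {
    cc <- cOrd
    diag(cc) <- diag(cOrd) / 2
    cm <- om %o% om
    diag(cm) <- om * (om - 1) / 2
  } else {
    cc <- cOrd                      # diagonal keeps both endpoint orders
    cm <- om %o% om
  }
  new("BlockCounts", c = unname(cc), cMax = unname(cm),
      omega = part@omega, mode = g@mode)
}

#' Infer stochastic block model parameters from block counts
#'
#' Maximum-likelihood inference given that both the graph and the
#' partition are observed: p = omega / n (law of large numbers),
#' W = C / Cmax elementwise (the Bernoulli edge probability per block
#' pair in binary mode; the mean absolute weight per node pair in
#' weighted mode), Q = nW (expected degrees, degree-scaling factor fixed
#' at 1), and the community profile matrix PQ = n diag(p) W.
#'
#' Block pairs with no available node pairs (cMax = 0, i.e. a singleton
#' community's diagonal) get W = 0.
#'
#' @param counts a [BlockCounts-class].
#' @param n total node count.
#' @return An [SBMParams-class].
#' @export
inferSBM <- function(counts, n) {
  om <- counts@omega
  if (any(om < 1L)) stop("degenerate partition: empty community")
  p <- as.numeric(om) / n
  w <- counts@c / counts@cMax
  w[counts@cMax == 0] <- 0
  w <- (w + t(w)) / 2   # kill last-bit asymmetry from BLAS
  q <- n * w
  pq <- n * diag(p, nrow = length(p)) %*% w
  new("SBMParams", p = p, w = unname(w), q = unname(q), pq = unname(pq),
      mode = counts@mode, n = as.integer(n), st = 1)
}

#' Build SBMParams directly from exact block probabilities
#'
#' Bypasses counting: useful for analytic oracles and for evaluating the
#' SNR of a model specified by its exact parameters rather than inferred
#' from a sampled graph.
#'
#' @param p length-k community probability vector (must sum to 1).
#' @param w k x k symmetric nonnegative matrix W.
#' @param n node count.
#' @param mode "binary" or "weighted".
#' @return An [SBMParams-class].
#' @export
sbmFromProbabilities <- function(p, w, n, mode = "binary") {
  p <- as.numeric(p)
  w <- as.matrix(w)
  pq <- n * diag(p, nrow = length(p)) %*% w
  new("SBMParams", p = p, w = unname(w), q = unname(n * w),
      pq = unname(pq), mode = mode, n = as.integer(n), st = 1)
}

#' SNR prominence statistic of an SBM
#'
#' The signal-to-noise ratio SNR = lambda2^2 / lambda1 of the community
#' profile matrix PQ = n diag(p) W, with eigenvalues ordered by
#' descending absolute value. PQ is similar to the symmetric matrix
#' S = n P^(1/2) W P^(1/2), so its spectrum is real; eigenvalues are
#' computed on S with a symmetric solver, which avoids nonsymmetric-
#' solver noise. lambda1 is nonnegative (Perron-Frobenius on a
#' nonnegative matrix); lambda2 may be negative, and squaring makes the
#' statistic sign-free.
#'
#' Degenerate cases (a single community, or lambda1 below 1e-12 as for an
#' empty graph) return SNR = 0 rather than erroring, so that threshold
#' sweeps over a full grid never abort.
#'
#' @param x an [SBMParams-class].
#' @return An [SNRValue-class]; `weaklyRecoverable` is the strict
#'   criterion SNR > 1 under which weak recovery of the partition is
#'   efficiently solvable (Kesten-Stigum regime).
#' @examples
#' params <- sbmFromProbabilities(c(0.5, 0.5), matrix(c(6, 2, 2, 6)/100, 2), 100)
#' snr(params)  # SNR exactly 1: the weak-recovery boundary
#' @export
setGeneric("snr", function(x) standardGeneric("snr"))

#' @rdname snr
#' @export
setMethod("snr", "SBMParams", function(x) {
  k <- length(x@p)
  if (k == 1L) {
    return(new("SNRValue", snr = 0, lambda1 = x@pq[1, 1], lambda2 = 0,
               weaklyRecoverable = FALSE))
  }
  sp <- sqrt(x@p)
  s <- x@n * (sp %o% sp) * x@w       # similar to PQ, symmetric
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[order(abs(ev), decreasing = TRUE)]
  l1 <- ev[1]
  l2 <- ev[2]
  if (l1 <= 1e-12) {
    return(new("SNRValue", snr = 0, lambda1 = l1, lambda2 = l2,
               weaklyRecoverable = FALSE))
  }
  val <- l2^2 / l1
  new("SNRValue", snr = val, lambda1 = l1, lambda2 = l2,
      weaklyRecoverable = val > 1)
})

#' Weak-recovery criterion
#'
#' Strict test SNR > 1: above this hard threshold an efficient algorithm
#' can recover a partition correlated with the ground truth better than
#' chance.
#'
#' @param x an [SNRValue-class] or a numeric SNR.
#' @return logical.
#' @export
isWeaklyRecoverable <- function(x) {
  if (is(x, "SNRValue")) x@snr > 1 else as.numeric(x) > 1
}

#' One-call SNR of a graph + partition
#'
#' Convenience wrapper: [blockCounts()] then [inferSBM()] then [snr()].
#'
#' @inheritParams blockCounts
#' @return An [SNRValue-class].
#' @export
graphSNR <- function(g, part, cmax = "pairs") {
  snr(inferSBM(blockCounts(g, part, cmax = cmax), nrow(g@values)))
}
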