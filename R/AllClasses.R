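#' @import methods
NULL

.SYM_TOL <- 1e-8

#' ConnectomeMatrix: a weighted functional connectome
#'
#' An n x n symmetric matrix of pairwise association strengths between
#' nodes (brain regions), typically Pearson correlations, with zero
#' diagonal (self-association carries no information and is excluded from
#' every edge sum downstream). Off-diagonal entries must lie in [-1, 1];
#' negative couplings are retained at this stage and handled by magnitude
#' at thresholding time.
#'
#' @slot values numeric matrix, n x n, symmetric, zero diagonal.
#' @slot label free-text identifier (subject id, condition, "GA", ...).
#'
#' @seealso [readConnectome()], [thresholdBinarize()], [groupAverage()]
#' @export
setClass("ConnectomeMatrix",
  representation(values = "matrix", label = "character"),
  prototype(label = "")
)

setValidity("ConnectomeMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) != ncol(v)) return("values must be square")
  if (any(!is.finite(v))) return("values must be finite")
  if (max(abs(v - t(v))) > .SYM_TOL) {
    return(sprintf("values must be symmetric within %g", .SYM_TOL))
  }
  if (any(diag(v) != 0)) return("diagonal must be exactly zero")
  off <- abs(v[row(v) != col(v)])
  if (length(off) && max(off) > 1) {
    return("off-diagonal entries must lie in [-1, 1]")
  }
  if (length(object@label) != 1L) return("label must be length 1")
  TRUE
})

#' Construct a ConnectomeMatrix
#'
#' Symmetrizes as (A + t(A))/2 when the asymmetry is within `tol`
#' (errors otherwise), forces the diagonal to zero, and range-checks the
#' off-diagonal entries against [-1 - tol, 1 + tol] before clamping the
#' retained values to [-1, 1].
#'
#' @param values square numeric matrix.
#' @param label identifier string.
#' @param tol asymmetry / range tolerance for raw input (default 1e-6,
#'   sized for round-tripping through decimal text).
#' @return A [ConnectomeMatrix-class] object.
#' @export
ConnectomeMatrix <- function(values, label = "", tol = 1e-6) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("shape error: matrix is ", nrow(values), " x ", ncol(values))
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("range error: non-numeric or non-finite entries")
  }
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("symmetry error: max asymmetry %.3g exceeds %g", asym, tol))
  }
  values <- (values + t(values)) / 2
  if (any(diag(values) != 0)) {
    warning("nonzero diagonal coerced to 0 (self-loops are excluded)")
    diag(values) <- 0
  }
  off <- values[row(values) != col(values)]
  if (length(off) && max(abs(off)) > 1 + tol) {
    stop(sprintf("range error: |entry| = %.6g exceeds 1", max(abs(off))))
  }
  values[values > 1] <- 1
  values[values < -1] <- -1
  dimnames(values) <- NULL
  new("ConnectomeMatrix", values = values, label = as.character(label))
}

#' Partition: an a priori community assignment
#'
#' A length-n vector sigma of community labels in 1..k, together with the
#' number of communities k and the community-size vector omega. Labels are
#' always contiguous (every label in 1..k occurs at least once); the
#' constructor relabels arbitrary input labels to 1..k in order of first
#' appearance.
#'
#' @slot sigma integer vector, node -> community.
#' @slot k number of communities.
#' @slot omega integer vector of community sizes, sum(omega) = n.
#'
#' @seealso [readPartition()], [shufflePartition()]
#' @export
setClass("Partition",
  representation(sigma = "integer", k = "integer", omega = "integer")
)

setValidity("Partition", function(object) {
  s <- object@sigma
  k <- object@k
  if (length(k) != 1L || k < 1L) return("k must be a positive scalar")
  if (length(s) < 1L) return("sigma must be non-empty")
  if (any(s < 1L) || any(s > k)) return("labels must lie in 1..k")
  om <- tabulate(s, nbins = k)
  if (any(om == 0L)) return("every label in 1..k must occur (no empty community)")
  if (!identical(as.integer(om), object@omega)) {
    return("omega must equal the tabulated community sizes")
  }
  TRUE
})

#' Construct a Partition from arbitrary labels
#'
#' @param labels vector of community labels (any atomic type); relabeled
#'   to 1..k by order of first appearance.
#' @return A [Partition-class] object.
#' @export
Partition <- function(labels) {
  if (length(labels) < 1L) stop("empty partition")
  if (any(is.na(labels))) stop("missing community labels")
  f <- factor(as.character(labels), levels = unique(as.character(labels)))
  sigma <- as.integer(f)
  k <- nlevels(f)
  new("Partition",
    sigma = sigma, k = as.integer(k),
    omega = as.integer(tabulate(sigma, nbins = k))
  )
}

#' CohortStack: an ordered cohort of connectomes
#'
#' Gamma subject-level [ConnectomeMatrix-class] objects sharing one
#' parcellation (equal n).
#'
#' @slot matrices list of ConnectomeMatrix, all with identical n.
#' @export
setClass("CohortStack", representation(matrices = "list"))

setValidity("CohortStack", function(object) {
  m <- object@matrices
  if (length(m) < 1L) return("cohort must contain at least one matrix")
  if (!all(vapply(m, is, logical(1), "ConnectomeMatrix"))) {
    return("all members must be ConnectomeMatrix objects")
  }
  ns <- vapply(m, function(x) nrow(x@values), integer(1))
  if (length(unique(ns)) != 1L) {
    return("cohort shape error: members differ in node count")
  }
  TRUE
})

#' @rdname CohortStack-class
#' @param matrices list of [ConnectomeMatrix-class] objects.
#' @export
CohortStack <- function(matrices) new("CohortStack", matrices = matrices)

#' FcGraph: a thresholded (binarized or weighted) graph
#'
#' The graph obtained from a connectome by thresholding: in binary mode
#' entries are 0/1 adjacency; in weighted mode retained entries carry the
#' absolute weight |a_uv|. Symmetric, zero diagonal; m is the number of
#' unordered node pairs with a nonzero entry.
#'
#' @slot values n x n nonnegative matrix.
#' @slot mode "binary" or "weighted".
#' @slot m edge count (unordered pairs with nonzero entry).
#' @export
setClass("FcGraph",
  representation(values = "matrix", mode = "character", m = "integer")
)

setValidity("FcGraph", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (max(abs(v - t(v))) > .SYM_TOL) return("values must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  if (any(v < 0)) return("entries must be nonnegative")
  if (!object@mode %in% c("binary", "weighted")) {
    return('mode must be "binary" or "weighted"')
  }
  if (object@mode == "binary" && !all(v %in% c(0, 1))) {
    return("binary mode requires entries in {0, 1}")
  }
  if (object@m != sum(v[upper.tri(v)] != 0)) {
    return("m must equal the number of nonzero unordered pairs")
  }
  TRUE
})

FcGraph <- function(values, mode) {
  dimnames(values) <- NULL
  new("FcGraph",
    values = values, mode = mode,
    m = as.integer(sum(values[upper.tri(values)] != 0))
  )
}

#' BlockCounts: per-block edge statistics
#'
#' The statistical summary C of a graph's edges with respect to a
#' partition: in binary mode the edge count per unordered block pair, in
#' weighted mode the sum of absolute edge weights; cMax holds the maximal
#' number of node pairs per block pair under the chosen convention (see
#' [blockCounts()]).
#'
#' @slot c k x k symmetric nonnegative matrix.
#' @slot cMax k x k positive matrix of pair counts.
#' @slot omega community sizes.
#' @slot mode "binary" or "weighted".
#' @export
setClass("BlockCounts",
  representation(c = "matrix", cMax = "matrix", omega = "integer",
                 mode = "character")
)

setValidity("BlockCounts", function(object) {
  if (max(abs(object@c - t(object@c))) > .SYM_TOL) return("c must be symmetric")
  if (any(object@c < 0)) return("c must be nonnegative")
  if (object@mode == "binary" && any(object@c > object@cMax + .SYM_TOL)) {
    return("binary counts cannot exceed cMax")
  }
  TRUE
})

#' SBMParams: inferred stochastic block model parameters
#'
#' For one graph + partition pair in one mode: the community membership
#' probabilities p = omega/n, the edge-probability (or mean-absolute-
#' weight) matrix W = C / Cmax, the expected-degree matrix Q = nW, and the
#' community profile matrix PQ = n diag(p) W whose (i, j) entry is the
#' expected number of community-j neighbours of a node in community i.
#' The degree-scaling factor is fixed at 1 (weak-recovery regime).
#'
#' @slot p length-k probability vector (sums to 1).
#' @slot w k x k symmetric nonnegative matrix.
#' @slot q k x k matrix, nW.
#' @slot pq k x k community profile matrix.
#' @slot mode "binary" or "weighted".
#' @slot n node count.
#' @slot st degree-scaling factor, always 1.
#' @export
setClass("SBMParams",
  representation(p = "numeric", w = "matrix", q = "matrix", pq = "matrix",
                 mode = "character", n = "integer", st = "numeric"),
  prototype(st = 1)
)

setValidity("SBMParams", function(object) {
  if (abs(sum(object@p) - 1) > 1e-9) return("p must sum to 1")
  if (any(object@p <= 0)) return("p entries must be positive")
  if (max(abs(object@w - t(object@w))) > .SYM_TOL) return("w must be symmetric")
  if (any(object@w < 0)) return("w entries must be nonnegative")
  if (object@mode == "binary" && any(object@w > 1 + 1e-9)) {
    return("binary-mode w entries must be probabilities")
  }
  if (object@st != 1) return("st must be 1 (weak-recovery regime)")
  pq <- object@n * diag(object@p, nrow = length(object@p)) %*% object@w
  if (max(abs(pq - object@pq)) > 1e-9 * max(1, max(abs(pq)))) {
    return("pq must equal n * diag(p) * w")
  }
  TRUE
})

#' SNRValue: the prominence statistic for one graph + partition
#'
#' snr = lambda2^2 / lambda1 where lambda_i are the eigenvalues of the
#' community profile matrix PQ ordered by descending absolute value;
#' weaklyRecoverable is the strict Kesten-Stigum criterion snr > 1.
#'
#' @slot snr nonnegative real.
#' @slot lambda1 leading eigenvalue (nonnegative).
#' @slot lambda2 second eigenvalue by absolute value (may be negative).
#' @slot weaklyRecoverable logical, snr > 1.
#' @export
setClass("SNRValue",
  representation(snr = "numeric", lambda1 = "numeric", lambda2 = "numeric",
                 weaklyRecoverable = "logical")
)

#' SNRProfile: SNR as a function of threshold
#'
#' @slot taus strictly ascending threshold grid in [0, 1].
#' @slot snrs matching nonnegative SNR values.
#' @slot mode "binary" or "weighted".
#' @slot label matrix identifier.
#' @export
setClass("SNRProfile",
  representation(taus = "numeric", snrs = "numeric", mode = "character",
                 label = "character")
)

setValidity("SNRProfile", function(object) {
  if (length(object@taus) != length(object@snrs)) {
    return("taus and snrs must have equal length")
  }
  if (any(diff(object@taus) <= 0)) return("taus must be strictly ascending")
  if (any(object@taus < 0 | object@taus > 1)) return("taus must lie in [0, 1]")
  if (any(object@snrs < -1e-12)) return("snrs must be nonnegative")
  TRUE
})

#' RecoverabilityInterval: the weak-recoverability threshold sub-interval
#'
#' The longest contiguous run of grid thresholds at which the binarized
#' group-average graph satisfies SNR > 1; empty when no grid point does.
#'
#' @slot aW lower endpoint (NA when empty).
#' @slot bW upper endpoint (NA when empty).
#' @slot empty logical.
#' @slot mask logical vector, SNR > 1 per grid point (full transparency
#'   when the super-threshold set is not contiguous).
#' @export
setClass("RecoverabilityInterval",
  representation(aW = "numeric", bW = "numeric", empty = "logical",
                 mask = "logical")
)

#' CohortReport: full output of the threshold-optimization pipeline
#'
#' @slot subjects data.frame with columns label, tauOpt, maxSnr,
#'   inInterval (one row per subject).
#' @slot tauOptGA group-average optimal threshold.
#' @slot maxSnrGA SNR at tauOptGA on the group-average connectome.
#' @slot gaInInterval logical, tauOptGA inside the vetting interval.
#' @slot interval [RecoverabilityInterval-class] from the binary vetting
#'   sweep on the group average.
#' @slot grid the threshold grid used.
#' @slot gaBinaryProfile binary-mode group-average [SNRProfile-class].
#' @slot gaWeightedProfile weighted-mode group-average profile.
#' @slot subjectProfiles list of per-subject weighted profiles.
#' @export
setClass("CohortReport",
  representation(subjects = "data.frame", tauOptGA = "numeric",
                 maxSnrGA = "numeric", gaInInterval = "logical",
                 interval = "RecoverabilityInterval", grid = "numeric",
                 gaBinaryProfile = "SNRProfile",
                 gaWeightedProfile = "SNRProfile",
                 subjectProfiles = "list")
)

#' NullEnsemble: SNR profiles under size-preserving partition shuffles
#'
#' @slot nShuffles number of shuffles.
#' @slot seed base RNG seed (shuffle s uses seed + s - 1).
#' @slot profiles list of [SNRProfile-class], one per shuffle.
#' @slot maxSnr ensemble maximum over all shuffles and thresholds.
#' @slot minSnr ensemble minimum.
#' @export
setClass("NullEnsemble",
  representation(nShuffles = "integer", seed = "integer", profiles = "list",
                 maxSnr = "numeric", minSnr = "numeric")
)
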