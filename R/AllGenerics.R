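#' Number of nodes
#'
#' @param x a ConnectomeMatrix, FcGraph, Partition or CohortStack.
#' @return integer node count n.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "ConnectomeMatrix", function(x) nrow(x@values))
#' @rdname nNodes
#' @export
setMethod("nNodes", "FcGraph", function(x) nrow(x@values))
#' @rdname nNodes
#' @export
setMethod("nNodes", "Partition", function(x) length(x@sigma))
#' @rdname nNodes
#' @export
setMethod("nNodes", "CohortStack", function(x) nrow(x@matrices[[1]]@values))

#' Dense matrix of values
#'
#' @param x a ConnectomeMatrix or FcGraph.
#' @return the underlying n x n numeric matrix.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))
#' @rdname matrixValues
#' @export
setMethod("matrixValues", "ConnectomeMatrix", function(x) x@values)
#' @rdname matrixValues
#' @export
setMethod("matrixValues", "FcGraph", function(x) x@values)

#' Accessors for partitions
#'
#' `membership()` returns the node-to-community vector sigma,
#' `nCommunities()` the number of communities k, and `communitySizes()`
#' the size vector omega.
#'
#' @param x a [Partition-class].
#' @return integer vector or scalar.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname membership
#' @export
setMethod("membership", "Partition", function(x) x@sigma)
#' @rdname membership
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))
#' @rdname membership
#' @export
setMethod("nCommunities", "Partition", function(x) x@k)
#' @rdname membership
#' @export
setGeneric("communitySizes", function(x) standardGeneric("communitySizes"))
#' @rdname membership
#' @export
setMethod("communitySizes", "Partition", function(x) x@omega)

#' Cohort size accessor
#'
#' @param x a [CohortStack-class].
#' @return Gamma, the number of subject matrices.
#' @export
setGeneric("cohortSize", function(x) standardGeneric("cohortSize"))
#' @rdname cohortSize
#' @export
setMethod("cohortSize", "CohortStack", function(x) length(x@matrices))

#' Connectome label accessor
#' @param x a [ConnectomeMatrix-class].
#' @return character label.
#' @export
setGeneric("connLabel", function(x) standardGeneric("connLabel"))
#' @rdname connLabel
#' @export
setMethod("connLabel", "ConnectomeMatrix", function(x) x@label)

#' Edge count accessor
#' @param x an [FcGraph-class].
#' @return m, the number of unordered node pairs with a nonzero entry.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname edgeCount
#' @export
setMethod("edgeCount", "FcGraph", function(x) x@m)

#' Graph mode accessor
#' @param x an [FcGraph-class], [BlockCounts-class] or [SBMParams-class].
#' @return "binary" or "weighted".
#' @export
setGeneric("graphMode", function(x) standardGeneric("graphMode"))
#' @rdname graphMode
#' @export
setMethod("graphMode", "FcGraph", function(x) x@mode)
#' @rdname graphMode
#' @export
setMethod("graphMode", "BlockCounts", function(x) x@mode)
#' @rdname graphMode
#' @export
setMethod("graphMode", "SBMParams", function(x) x@mode)

#' SBM parameter accessors
#'
#' `blockProbs()` returns p, `edgeProbMatrix()` W, and `profileMatrix()`
#' the community profile matrix PQ = n diag(p) W.
#'
#' @param x an [SBMParams-class].
#' @return numeric vector or k x k matrix.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @rdname profileMatrix
#' @export
setMethod("profileMatrix", "SBMParams", function(x) x@pq)
#' @rdname profileMatrix
#' @export
setGeneric("edgeProbMatrix", function(x) standardGeneric("edgeProbMatrix"))
#' @rdname profileMatrix
#' @export
setMethod("edgeProbMatrix", "SBMParams", function(x) x@w)
#' @rdname profileMatrix
#' @export
setGeneric("blockProbs", function(x) standardGeneric("blockProbs"))
#' @rdname profileMatrix
#' @export
setMethod("blockProbs", "SBMParams", function(x) x@p)

#' SNR accessors
#'
#' @param x an [SNRValue-class] or [SNRProfile-class].
#' @return `snrValue()` the scalar SNR; `snrValues()` the per-threshold
#'   vector; `thresholds()` the grid.
#' @export
setGeneric("snrValue", function(x) standardGeneric("snrValue"))
#' @rdname snrValue
#' @export
setMethod("snrValue", "SNRValue", function(x) x@snr)
#' @rdname snrValue
#' @export
setGeneric("snrValues", function(x) standardGeneric("snrValues"))
#' @rdname snrValue
#' @export
setMethod("snrValues", "SNRProfile", function(x) x@snrs)
#' @rdname snrValue
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))
#' @rdname snrValue
#' @export
setMethod("thresholds", "SNRProfile", function(x) x@taus)

#' Interval accessors
#' @param x a [RecoverabilityInterval-class].
#' @return numeric endpoints (NA when empty) or logical emptiness flag.
#' @export
setGeneric("intervalBounds", function(x) standardGeneric("intervalBounds"))
#' @rdname intervalBounds
#' @export
setMethod("intervalBounds", "RecoverabilityInterval",
          function(x) c(aW = x@aW, bW = x@bW))
#' @rdname intervalBounds
#' @export
setGeneric("isEmptyInterval", function(x) standardGeneric("isEmptyInterval"))
#' @rdname intervalBounds
#' @export
setMethod("isEmptyInterval", "RecoverabilityInterval", function(x) x@empty)

setMethod("show", "ConnectomeMatrix", function(object) {
  cat(sprintf("ConnectomeMatrix '%s': %d nodes, off-diagonal range [%.3f, %.3f]\n",
              object@label, nrow(object@values),
              min(object@values[row(object@values) != col(object@values)]),
              max(object@values[row(object@values) != col(object@values)])))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: n = %d, k = %d, sizes = %s\n",
              length(object@sigma), object@k,
              paste(object@omega, collapse = ", ")))
})

setMethod("show", "CohortStack", function(object) {
  cat(sprintf("CohortStack: Gamma = %d subjects, n = %d nodes\n",
              length(object@matrices), nrow(object@matrices[[1]]@values)))
})

setMethod("show", "FcGraph", function(object) {
  n <- nrow(object@values)
  cat(sprintf("FcGraph (%s): n = %d, m = %d edges, density %.4f\n",
              object@mode, n, object@m,
              if (n > 1) object@m / (n * (n - 1) / 2) else NA_real_))
})

setMethod("show", "SBMParams", function(object) {
  cat(sprintf("SBMParams (%s): n = %d, k = %d communities\n",
              object@mode, object@n, length(object@p)))
  cat("community profile matrix PQ:\n")
  print(round(object@pq, 4))
})

setMethod("show", "SNRValue", function(object) {
  cat(sprintf("SNR = %.6g (lambda1 = %.6g, lambda2 = %.6g); weak recovery: %s\n",
              object@snr, object@lambda1, object@lambda2,
              ifelse(object@weaklyRecoverable, "yes (SNR > 1)", "no")))
})

setMethod("show", "SNRProfile", function(object) {
  cat(sprintf("SNRProfile '%s' (%s): %d thresholds in [%g, %g], max SNR %.4g\n",
              object@label, object@mode, length(object@taus),
              min(object@taus), max(object@taus), max(object@snrs)))
})

setMethod("show", "RecoverabilityInterval", function(object) {
  if (object@empty) {
    cat("RecoverabilityInterval: empty (no threshold with SNR > 1)\n")
  } else {
    cat(sprintf("RecoverabilityInterval: [%g, %g]\n", object@aW, object@bW))
  }
})

setMethod("show", "CohortReport", function(object) {
  cat(sprintf("CohortReport: %d subjects, grid of %d thresholds\n",
              nrow(object@subjects), length(object@grid)))
  show(object@interval)
  cat(sprintf("tauOpt(GA) = %g (max SNR %.4g, in interval: %s)\n",
              object@tauOptGA, object@maxSnrGA, object@gaInInterval))
  cat(sprintf("mean subject tauOpt = %g\n", mean(object@subjects$tauOpt)))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble: %d shuffles (seed %d), SNR range [%.4g, %.4g]\n",
              object@nShuffles, object@seed, object@minSnr, object@maxSnr))
})
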