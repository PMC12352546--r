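#' Group-average connectome
#'
#' Entrywise arithmetic mean of the subject matrices; the standard way to
#' obtain a cohort-level representative connectome before thresholding.
#'
#' @param x a [CohortStack-class].
#' @return A [ConnectomeMatrix-class] labeled "GA".
#' @export
setGeneric("groupAverage", function(x) standardGeneric("groupAverage"))

#' @rdname groupAverage
#' @export
setMethod("groupAverage", "CohortStack", function(x) {
  acc <- Reduce(`+`, lapply(x@matrices, function(m) m@values))
  ConnectomeMatrix(acc / length(x@matrices), label = "GA", tol = 1e-8)
})

.checkTau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau > 1) {
    stop("tau must be a single value in [0, 1]")
  }
}

#' Threshold a connectome into a binary graph
#'
#' An edge u-v is retained iff |a_uv| >= tau (>= so that grid endpoints
#' are reproducible; exact zeros are never edges). Thresholding is on the
#' magnitude by default, matching the absolute-weight convention used in
#' the weighted block sums; set `signed = TRUE` to retain only entries
#' with a_uv >= tau (positive couplings only).
#'
#' @param fc a [ConnectomeMatrix-class].
#' @param tau threshold in [0, 1].
#' @param signed logical; threshold on signed values instead of |a_uv|.
#' @return An [FcGraph-class] in binary mode.
#' @export
thresholdBinarize <- function(fc, tau, signed = FALSE) {
  .checkTau(tau)
  v <- if (signed) fc@values else abs(fc@values)
  a <- (v >= tau & v != 0) * 1
  diag(a) <- 0
  FcGraph(a, "binary")
}

#' Threshold a connectome into a weighted graph
#'
#' Retained entries carry the absolute weight |a_uv| where |a_uv| >= tau;
#' all other entries are 0. See [thresholdBinarize()] for the magnitude
#' convention and the `signed` escape hatch.
#'
#' @inheritParams thresholdBinarize
#' @return An [FcGraph-class] in weighted mode.
#' @export
thresholdWeighted <- function(fc, tau, signed = FALSE) {
  .checkTau(tau)
  v <- if (signed) fc@values else abs(fc@values)
  w <- abs(fc@values) * (v >= tau & v != 0)
  diag(w) <- 0
  FcGraph(w, "weighted")
}

#' Edge density of a graph
#'
#' @param x an [FcGraph-class] with at least 2 nodes.
#' @return m / (n(n-1)/2), in [0, 1].
#' @export
setGeneric("edgeDensity", function(x) standardGeneric("edgeDensity"))

#' @rdname edgeDensity
#' @export
setMethod("edgeDensity", "FcGraph", function(x) {
  n <- nrow(x@values)
  stopifnot(n >= 2)
  x@m / (n * (n - 1) / 2)
})

#' Number of connected components
#'
#' Isolated nodes count as components; an edgeless graph on n nodes has
#' n components.
#'
#' @param x an [FcGraph-class].
#' @return positive integer.
#' @export
setGeneric("countComponents", function(x) standardGeneric("countComponents"))

#' @rdname countComponents
#' @export
setMethod("countComponents", "FcGraph", function(x) {
  g <- igraph::graph_from_adjacency_matrix(x@values != 0, mode = "undirected")
  igraph::components(g)$no
})

.asIgraph <- function(g) {
  if (g@mode == "weighted") {
    igraph::graph_from_adjacency_matrix(g@values, mode = "undirected",
                                        weighted = TRUE)
  } else {
    igraph::graph_from_adjacency_matrix(g@values, mode = "undirected")
  }
}
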