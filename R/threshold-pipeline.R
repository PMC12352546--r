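#' Default threshold grid
#'
#' Thresholds 0 to 1 inclusive in increments of 0.05 (21 points), the
#' discretized line search used throughout the pipeline. Values are
#' computed as integer multiples of the step so grid points are exactly
#' reproducible.
#'
#' @param from,to grid endpoints in [0, 1].
#' @param by increment.
#' @return ascending numeric vector.
#' @export
tauGrid <- function(from = 0, to = 1, by = 0.05) {
  if (is.na(from) || is.na(to) || is.na(by) ||
      from < 0 || to > 1 || by <= 0 || from > to) {
    stop("invalid grid: need 0 <= from <= to <= 1 and by > 0")
  }
  g <- from + by * seq.int(0L, floor((to - from) / by + 1e-9))
  round(g, 12)
}

#' SNR threshold sweep for one connectome
#'
#' For each grid threshold tau: threshold the connectome (binary or
#' weighted mode), compute block counts against the a priori partition,
#' infer the SBM parameters, and evaluate the SNR prominence statistic.
#' Degenerate thresholds (e.g. an empty graph at high tau) yield SNR 0.
#'
#' @param fc a [ConnectomeMatrix-class].
#' @param part a [Partition-class].
#' @param grid ascending thresholds in [0, 1] (default [tauGrid()]).
#' @param mode "binary" or "weighted".
#' @param signed threshold on signed values instead of magnitudes.
#' @param cmax pair-counting convention, see [blockCounts()].
#' @return An [SNRProfile-class].
#' @export
sweepSNR <- function(fc, part, grid = tauGrid(),
                     mode = c("weighted", "binary"),
                     signed = FALSE, cmax = "pairs") {
  mode <- match.arg(mode)
  stopifnot(all(diff(grid) > 0), all(grid >= 0 & grid <= 1))
  thr <- if (mode == "binary") thresholdBinarize else thresholdWeighted
  snrs <- vapply(grid, function(tau) {
    g <- thr(fc, tau, signed = signed)
    graphSNR(g, part, cmax = cmax)@snr
  }, numeric(1))
  new("SNRProfile", taus = as.numeric(grid), snrs = snrs, mode = mode,
      label = fc@label)
}

#' Weak-recoverability sub-interval of a sweep
#'
#' The longest contiguous run of grid thresholds with SNR > 1 (strict);
#' on ties the earliest run wins; empty when no grid point exceeds 1.
#' The full per-grid-point boolean mask is kept on the result so a
#' non-contiguous super-threshold set remains visible.
#'
#' Vetting is defined on the binarized group-average sweep; a profile in
#' weighted mode is accepted with a warning.
#'
#' @param profile an [SNRProfile-class].
#' @return A [RecoverabilityInterval-class].
#' @export
vettingInterval <- function(profile) {
  if (profile@mode != "binary") {
    warning("vetting interval is defined on a binary-mode profile; ",
            "got mode '", profile@mode, "'")
  }
  mask <- profile@snrs > 1
  if (!any(mask)) {
    return(new("RecoverabilityInterval", aW = NA_real_, bW = NA_real_,
               empty = TRUE, mask = mask))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]   # which.max takes the earliest tie
  new("RecoverabilityInterval",
      aW = profile@taus[starts[best]], bW = profile@taus[ends[best]],
      empty = FALSE, mask = mask)
}

#' Optimal threshold of a sweep
#'
#' The grid threshold maximizing SNR; ties resolve to the smallest tau
#' (mildest pruning).
#'
#' @param profile an [SNRProfile-class].
#' @return scalar tau.
#' @export
optimalThreshold <- function(profile) {
  stopifnot(length(profile@taus) > 0)
  profile@taus[which.max(profile@snrs)]
}

#' Threshold-optimization pipeline for a cohort
#'
#' The four-step fitness assessment:
#' \enumerate{
#'   \item compute the group-average connectome GA;
#'   \item vetting: binary-mode SNR sweep on GA, and its
#'     weak-recoverability sub-interval \eqn{[a_w, b_w]};
#'   \item weighted-mode SNR sweep per subject, giving each subject's
#'     individualized optimal threshold;
#'   \item weighted-mode sweep on GA, giving the cohort-level optimal
#'     threshold; every optimal threshold is checked for membership in
#'     \eqn{[a_w, b_w]}.
#' }
#' If the vetting interval is empty the report is still produced, with
#' all membership flags FALSE and a prominent warning.
#'
#' @param stack a [CohortStack-class].
#' @param part a [Partition-class] on the same node set.
#' @param grid ascending thresholds (default [tauGrid()]).
#' @param mode mode for the optimization sweeps (default "weighted", the
#'   prominence measure on thresholded connectomes; the vetting sweep is
#'   always binary).
#' @param cmax pair-counting convention, see [blockCounts()].
#' @return A [CohortReport-class].
#' @export
runCohort <- function(stack, part, grid = tauGrid(),
                      mode = c("weighted", "binary"), cmax = "pairs") {
  mode <- match.arg(mode)
  if (nNodes(stack) != length(part@sigma)) {
    stop("size mismatch: cohort has ", nNodes(stack), " nodes, partition ",
         length(part@sigma))
  }
  ga <- groupAverage(stack)
  gaBin <- sweepSNR(ga, part, grid, mode = "binary", cmax = cmax)
  interval <- vettingInterval(gaBin)
  if (interval@empty) {
    warning("weak-recoverability interval is empty: no threshold puts the ",
            "binarized group average above SNR = 1; optimal thresholds ",
            "are reported but not vetted")
  }
  inInt <- function(tau) {
    !interval@empty & tau >= interval@aW & tau <= interval@bW
  }
  profs <- lapply(stack@matrices, sweepSNR, part = part, grid = grid,
                  mode = mode, cmax = cmax)
  tauOpt <- vapply(profs, optimalThreshold, numeric(1))
  maxSnr <- vapply(profs, function(p) max(p@snrs), numeric(1))
  labels <- vapply(stack@matrices, connLabel, character(1))
  labels[!nzchar(labels)] <- sprintf("subject_%03d", which(!nzchar(labels)))
  gaW <- sweepSNR(ga, part, grid, mode = mode, cmax = cmax)
  tauGA <- optimalThreshold(gaW)
  new("CohortReport",
      subjects = data.frame(label = labels, tauOpt = tauOpt,
                            maxSnr = maxSnr, inInterval = inInt(tauOpt),
                            stringsAsFactors = FALSE),
      tauOptGA = tauGA, maxSnrGA = max(gaW@snrs),
      gaInInterval = inInt(tauGA), interval = interval,
      grid = as.numeric(grid), gaBinaryProfile = gaBin,
      gaWeightedProfile = gaW, subjectProfiles = profs)
}

#' Serialize a cohort report to a JSON run summary
#'
#' @param report a [CohortReport-class].
#' @param path output path; NULL returns the JSON string.
#' @param extra named list merged into the summary (seeds, input paths...).
#' @return path (invisibly) or JSON string.
#' @export
reportToJSON <- function(report, path = NULL, extra = list()) {
  obj <- c(list(
    grid = report@grid,
    interval = list(a_w = report@interval@aW, b_w = report@interval@bW,
                    empty = report@interval@empty,
                    mask = report@interval@mask),
    tau_opt_ga = report@tauOptGA,
    max_snr_ga = report@maxSnrGA,
    ga_in_interval = report@gaInInterval,
    subjects = report@subjects
  ), extra)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
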