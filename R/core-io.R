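#' Read a dense connectome matrix from delimited text
#'
#' Reads an n x n numeric matrix (whitespace- or comma-delimited, no
#' header), symmetrizes it as (A + t(A))/2 provided the asymmetry is at
#' most 1e-6, forces the diagonal to zero (raw Pearson connectomes carry
#' a diagonal of 1; self-loops are excluded from every edge sum in this
#' package), and checks that off-diagonal entries lie in [-1, 1].
#'
#' Node indices are 1-based both in files and internally.
#'
#' @param path path to the matrix file.
#' @param delimiter field separator; `""` (default) splits on any
#'   whitespace, `","` reads comma-separated values.
#' @param label identifier stored on the object (defaults to the file
#'   base name).
#' @return A [ConnectomeMatrix-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("0 0.3", "0.3 0"), f)
#' readConnectome(f)
#' @export
readConnectome <- function(path, delimiter = "", label = basename(path)) {
  rows <- utils::read.table(path, sep = delimiter, header = FALSE,
                            colClasses = "numeric")
  m <- as.matrix(rows)
  if (nrow(m) != ncol(m)) {
    stop("shape error: ", path, " is ", nrow(m), " x ", ncol(m))
  }
  ConnectomeMatrix(m, label = label)
}

#' Write a connectome matrix to delimited text
#'
#' @param fc a [ConnectomeMatrix-class].
#' @param path output path.
#' @param delimiter field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(fc, path, delimiter = "\t") {
  utils::write.table(format(fc@values, digits = 10, trim = TRUE,
                            scientific = FALSE),
                     path, sep = delimiter, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an a priori partition from two-column text
#'
#' Expects rows of (node_index, community_label) with node indices
#' forming the contiguous range 1..n (any order). Labels may be arbitrary
#' strings (e.g. "VIS", "DMN"); they are relabeled to contiguous integers
#' 1..k in order of first appearance after sorting rows by node index,
#' which makes the result invariant to any injective renaming of the
#' input labels.
#'
#' @param path path to the partition file.
#' @param delimiter field separator; `""` splits on whitespace.
#' @return A [Partition-class].
#' @export
readPartition <- function(path, delimiter = "") {
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = c("integer", "character"))
  idx <- tab[[1]]
  n <- length(idx)
  if (anyDuplicated(idx)) {
    stop("duplicate error: node index ", idx[duplicated(idx)][1],
         " appears more than once")
  }
  if (!setequal(idx, seq_len(n))) {
    missing <- setdiff(seq_len(max(idx, n)), idx)
    stop("coverage error: node index ", missing[1], " missing")
  }
  Partition(tab[[2]][order(idx)])
}

#' Write a partition to two-column text
#'
#' @param part a [Partition-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(part, path) {
  utils::write.table(
    data.frame(node = seq_along(part@sigma), community = part@sigma),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort of connectomes from a manifest
#'
#' The manifest lists one matrix path per line (relative paths are
#' resolved against the manifest's directory). All matrices must share
#' the same node count.
#'
#' @param manifest path to the manifest file.
#' @param delimiter field separator passed to [readConnectome()].
#' @return A [CohortStack-class].
#' @export
readCohort <- function(manifest, delimiter = "") {
  paths <- readLines(manifest)
  paths <- trimws(paths)
  paths <- paths[nzchar(paths)]
  if (length(paths) == 0L) stop("empty manifest: ", manifest)
  base <- dirname(manifest)
  paths <- ifelse(file.exists(paths), paths, file.path(base, paths))
  mats <- lapply(paths, readConnectome, delimiter = delimiter)
  ns <- vapply(mats, nNodes, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("cohort shape error: node counts ",
         paste(unique(ns), collapse = ", "), " across manifest")
  }
  CohortStack(mats)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; numeric columns are written at 10
#' significant digits so that a read-back reproduces the values within
#' 1e-9 relative error. Row order is preserved as given (callers are
#' expected to pass deterministically ordered records).
#'
#' @param rows a data.frame of result records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 10, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Convert an SNR profile to a data.frame
#'
#' @param profile an [SNRProfile-class].
#' @return data.frame with columns tau, snr, mode, label.
#' @export
profileToTable <- function(profile) {
  data.frame(tau = profile@taus, snr = profile@snrs,
             mode = profile@mode, label = profile@label,
             stringsAsFactors = FALSE)
}
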