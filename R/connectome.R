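#' Average voxel time series within parcels
#'
#' Per-frame arithmetic mean over each parcel's voxels; WM and CSF voxels are
#' excluded. Column order follows the parcellation's node order.
#'
#' @param voxelTs frames x voxels matrix.
#' @param voxelLabels per-voxel labels (parcel/thalamus names, \code{"WM"},
#'   \code{"CSF"}).
#' @param parcellation a \code{\linkS4class{Parcellation}}.
#' @return frames x n_node matrix of ROI time series.
#' @export
roiAverage <- function(voxelTs, voxelLabels, parcellation) {
  stopifnot(is.matrix(voxelTs), length(voxelLabels) == ncol(voxelTs))
  nodes <- nodeNames(parcellation)
  counts <- vapply(nodes, function(nm) sum(voxelLabels == nm), integer(1))
  if (any(counts == 0))
    stop("parcel(s) with zero voxels: ",
         paste(nodes[counts == 0], collapse = ", "))
  out <- vapply(nodes, function(nm)
    rowMeans(voxelTs[, voxelLabels == nm, drop = FALSE]),
    numeric(nrow(voxelTs)))
  colnames(out) <- nodes
  out
}

#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlation of the cleaned ROI time series computed over
#' valid (non-rejected, hence non-interpolated) frames only; the diagonal is
#' set to 1. A zero-variance ROI gets zero correlations and a warning.
#'
#' @param clean a \code{\linkS4class{CleanRoiTimeSeries}} (or a plain
#'   frames x n matrix, in which case all frames are used).
#' @param subjectId,gaWeeks metadata carried into the result.
#' @return a \code{\linkS4class{ConnectivityMatrix}}.
#' @export
computeFC <- function(clean, subjectId = NA_character_, gaWeeks = NA_real_) {
  if (is(clean, "CleanRoiTimeSeries")) {
    keep <- validFrames(clean)
    ts <- clean@ts[keep, , drop = FALSE]
  } else {
    stopifnot(is.matrix(clean))
    ts <- clean
  }
  if (nrow(ts) < 8)
    stop("at least 8 valid frames required for connectivity")
  sds <- apply(ts, 2, stats::sd)
  flat <- sds < 1e-12
  if (any(flat))
    warning("zero-variance ROI(s) set to zero correlation: ",
            paste(colnames(ts)[flat], collapse = ", "))
  C <- suppressWarnings(stats::cor(ts))
  C[flat, ] <- 0
  C[, flat] <- 0
  C[is.na(C)] <- 0
  C <- (C + t(C)) / 2
  diag(C) <- 1
  new("ConnectivityMatrix", mat = C,
      subjectId = as.character(subjectId), gaWeeks = as.numeric(gaWeeks))
}

#' Thresholded nodal degree
#'
#' Zeroes negative and weak connections (entries below \code{tau}) and sums
#' the retained edge weights per node (weighted degree; \code{binary = TRUE}
#' counts retained edges instead). The diagonal never contributes.
#'
#' @param M a \code{\linkS4class{ConnectivityMatrix}} or plain symmetric
#'   matrix.
#' @param tau threshold; entries strictly below \code{tau} are removed
#'   (default 0.1). Must be nonnegative, so negative connections are always
#'   removed.
#' @param binary count edges instead of summing weights (default
#'   \code{FALSE}).
#' @return named numeric vector of nodal degrees.
#' @export
thresholdedDegree <- function(M, tau = 0.1, binary = FALSE) {
  if (is(M, "ConnectivityMatrix")) M <- M@mat
  stopifnotSymmetric(M)
  if (tau < 0) stop("tau must be nonnegative")
  A <- M
  diag(A) <- 0
  A[A < tau] <- 0
  if (binary) A <- (A > 0) * 1
  rowSums(A)
}
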