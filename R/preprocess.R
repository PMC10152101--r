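#' Detect outlier volumes from voxel time series
#'
#' Flags voxels whose temporal first difference is extreme (robust z via
#' median/MAD of each voxel's own differences, threshold \code{spikeZ}) and
#' rejects every volume in which the fraction of outlier voxels is strictly
#' greater than \code{volumeFraction}. An isolated intensity spike makes both
#' the difference into and out of the spiked frame large, so a voxel is
#' attributed to frame \code{t} when the smaller of the two adjacent
#' difference z-scores exceeds the threshold (a single difference is used at
#' the series edges).
#'
#' @param voxelTs frames x voxels matrix.
#' @param spikeZ robust z threshold for an outlier voxel (default 5).
#' @param volumeFraction volume rejection threshold on the outlier-voxel
#'   fraction; strictly-greater rule, so a frame with exactly this fraction is
#'   kept (default 0.05).
#' @return a \code{\linkS4class{CensorMask}} (nothing interpolated yet).
#' @export
detectOutlierVolumes <- function(voxelTs, spikeZ = 5, volumeFraction = 0.05) {
  stopifnot(is.matrix(voxelTs))
  nf <- nrow(voxelTs)
  if (nf < 3) stop("at least 3 frames required")
  if (!is.finite(volumeFraction) || volumeFraction < 0 || volumeFraction > 1)
    stop("volumeFraction must lie in [0, 1]")
  D <- diff(voxelTs)                       # (nf-1) x voxels
  med <- apply(D, 2, stats::median)
  madv <- apply(D, 2, stats::mad)
  madv[madv < 1e-12] <- 1e-12
  Z <- abs(sweep(sweep(D, 2, med, "-"), 2, madv, "/"))
  frac <- numeric(nf)
  frac[1] <- mean(Z[1, ] > spikeZ)
  frac[nf] <- mean(Z[nf - 1, ] > spikeZ)
  if (nf > 2) {
    for (t in 2:(nf - 1))
      frac[t] <- mean(pmin(Z[t - 1, ], Z[t, ]) > spikeZ)
  }
  rejected <- frac > volumeFraction
  new("CensorMask", rejected = rejected,
      interpolated = rep(FALSE, nf))
}

#' aCompCor nuisance design
#'
#' Extracts the top principal components of the white-matter and CSF voxel
#' pools (per-voxel mean-centred and variance-normalized, computed on valid
#' frames only), ordered by explained variance.
#'
#' @param voxelTs frames x voxels matrix.
#' @param voxelLabels per-voxel labels; \code{"WM"} and \code{"CSF"} mark the
#'   tissue pools.
#' @param nWm,nCsf number of components per tissue (default 5 each).
#' @param censor optional \code{\linkS4class{CensorMask}}; rejected frames are
#'   excluded from the decomposition and get zero regressor values.
#' @return a \code{\linkS4class{NuisanceDesign}}.
#' @export
computeACompCor <- function(voxelTs, voxelLabels, nWm = 5, nCsf = 5,
                            censor = NULL) {
  stopifnot(is.matrix(voxelTs), length(voxelLabels) == ncol(voxelTs))
  nf <- nrow(voxelTs)
  valid <- if (is.null(censor)) rep(TRUE, nf) else !censor@rejected
  design <- matrix(0, nf, 0)
  labels <- character()
  for (tissue in c("WM", "CSF")) {
    k <- if (tissue == "WM") nWm else nCsf
    if (k == 0) next
    cols <- which(voxelLabels == tissue)
    if (length(cols) <= max(nWm, nCsf))
      stop("insufficient ", tissue, " voxels (", length(cols),
           ") for ", max(nWm, nCsf), " components")
    B <- voxelTs[valid, cols, drop = FALSE]
    B <- scale(B)
    B[, attr(B, "scaled:scale") < 1e-12] <- 0
    pc <- stats::prcomp(B, center = FALSE, scale. = FALSE)
    k <- min(k, ncol(pc$x))
    sc <- matrix(0, nf, k)
    sc[valid, ] <- pc$x[, seq_len(k), drop = FALSE]
    design <- cbind(design, sc)
    labels <- c(labels, sprintf("%s-PC%d", tissue, seq_len(k)))
  }
  colnames(design) <- labels
  new("NuisanceDesign", design = design, labels = labels)
}

## Discrete-cosine high-pass basis: all DCT-II columns with frequency
## strictly below cutoffHz. Column k has frequency k / (2 * N * tr).
dctHighpassBasis <- function(frames, tr, cutoffHz) {
  kmax <- floor(2 * frames * tr * cutoffHz - 1e-12)
  if (kmax < 1) return(matrix(0, frames, 0))
  t <- seq_len(frames)
  B <- vapply(seq_len(kmax),
              function(k) cos(pi * k * (2 * t - 1) / (2 * frames)),
              numeric(frames))
  colnames(B) <- sprintf("DCT%d", seq_len(kmax))
  B
}

#' Simultaneous temporal filtering and nuisance regression
#'
#' Removes the nuisance regressors and a discrete-cosine high-pass basis
#' (every DCT column with frequency below \code{highpassHz}) in a single
#' least-squares projection fitted on valid frames only, then fills rejected
#' frames with a cubic-spline interpolation of the residual series (nearest
#' valid value at the series edges) and flags them as interpolated.
#'
#' @param roiTs frames x n_roi matrix of ROI time series.
#' @param design a \code{\linkS4class{NuisanceDesign}} (may have 0 columns).
#' @param highpassHz high-pass cutoff in Hz (default 0.008); must be below
#'   the Nyquist frequency \code{1/(2 tr)}.
#' @param tr repetition time in seconds.
#' @param censor optional \code{\linkS4class{CensorMask}}.
#' @return a \code{\linkS4class{CleanRoiTimeSeries}}.
#' @export
cleanTimeseries <- function(roiTs, design = NULL, highpassHz = 0.008, tr = 3,
                            censor = NULL) {
  stopifnot(is.matrix(roiTs))
  nf <- nrow(roiTs)
  if (!is.null(design) && nrow(design@design) != nf)
    stop("design rows must equal the number of frames")
  if (highpassHz >= 1 / (2 * tr))
    stop("highpassHz must be below the Nyquist frequency 1/(2 tr)")
  valid <- if (is.null(censor)) rep(TRUE, nf) else !censor@rejected
  if (sum(valid) < 8)
    stop("fewer than 8 valid frames remain; subject must be flagged")

  dct <- dctHighpassBasis(nf, tr, highpassHz)
  nd <- if (is.null(design)) matrix(0, nf, 0) else design@design
  X <- cbind(`(Intercept)` = 1, dct, nd)
  Xv <- X[valid, , drop = FALSE]
  q <- qr(Xv)
  if (q$rank < ncol(Xv)) {
    bad <- colnames(Xv)[q$pivot[(q$rank + 1):ncol(Xv)]]
    stop("rank-deficient cleaning design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(q, roiTs[valid, , drop = FALSE])
  res <- matrix(NA_real_, nf, ncol(roiTs), dimnames = dimnames(roiTs))
  res[valid, ] <- roiTs[valid, , drop = FALSE] - Xv %*% beta

  if (any(!valid)) {
    vIdx <- which(valid); rIdx <- which(!valid)
    for (j in seq_len(ncol(res))) {
      f <- stats::splinefun(vIdx, res[vIdx, j], method = "natural")
      inside <- rIdx >= min(vIdx) & rIdx <= max(vIdx)
      res[rIdx[inside], j] <- f(rIdx[inside])
      if (any(!inside)) {
        lo <- rIdx[!inside & rIdx < min(vIdx)]
        hi <- rIdx[!inside & rIdx > max(vIdx)]
        if (length(lo)) res[lo, j] <- res[min(vIdx), j]
        if (length(hi)) res[hi, j] <- res[max(vIdx), j]
      }
    }
  }
  cm <- new("CensorMask", rejected = !valid, interpolated = !valid)
  new("CleanRoiTimeSeries", ts = res, censor = cm, tr = tr)
}

#' @rdname validFrames
#' @export
validFrames <- function(x) {
  if (is(x, "CleanRoiTimeSeries")) x <- x@censor
  !x@rejected
}

#' Frame bookkeeping helpers
#'
#' @param x a \code{\linkS4class{CensorMask}} or
#'   \code{\linkS4class{CleanRoiTimeSeries}}.
#' @return \code{validFrames}: logical per frame (not rejected);
#'   \code{nValidFrames}: their count.
#' @name validFrames
#' @export
nValidFrames <- function(x) sum(validFrames(x))

setMethod("show", "CensorMask", function(object) {
  cat(sprintf("CensorMask: %d frames, %d rejected (%d interpolated)\n",
              length(object@rejected), sum(object@rejected),
              sum(object@interpolated)))
})

setMethod("show", "CleanRoiTimeSeries", function(object) {
  cat(sprintf("CleanRoiTimeSeries: %d frames x %d ROIs (TR %gs), %d rejected frame(s)\n",
              nrow(object@ts), ncol(object@ts), object@tr,
              sum(object@censor@rejected)))
})
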