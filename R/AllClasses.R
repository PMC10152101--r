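#' @import methods
NULL

## ------------------------------------------------------------------ ##
##  Parcellation                                                      ##
## ------------------------------------------------------------------ ##

#' Parcellation of the fetal cortex
#'
#' Holds the cortical parcel labels (left/right homolog pairs), their lobe
#' assignment, the homolog (mirror-twin) index permutation, and optional
#' thalamus node(s) appended after the cortical parcels.
#'
#' @slot parcels character vector of cortical parcel names.
#' @slot hemisphere \code{"L"}/\code{"R"} per cortical parcel.
#' @slot lobe lobe name per cortical parcel (frontal, parietal, temporal,
#'   occipital, insular, limbic).
#' @slot homolog integer permutation mapping each cortical parcel to its
#'   contralateral twin; an involution with no fixed points.
#' @slot thalamus character vector of thalamus node names (possibly empty).
#' @export
setClass("Parcellation", representation(
  parcels = "character",
  hemisphere = "character",
  lobe = "character",
  homolog = "integer",
  thalamus = "character"
))

setValidity("Parcellation", function(object) {
  n <- length(object@parcels)
  msg <- character()
  if (length(object@hemisphere) != n || length(object@lobe) != n ||
      length(object@homolog) != n)
    msg <- c(msg, "parcels, hemisphere, lobe, homolog must have equal length")
  if (!all(object@hemisphere %in% c("L", "R")))
    msg <- c(msg, "hemisphere labels must be 'L' or 'R'")
  nl <- sum(object@hemisphere == "L"); nr <- sum(object@hemisphere == "R")
  if (nl != nr)
    msg <- c(msg, "unequal number of left and right parcels")
  h <- object@homolog
  if (length(h) == n && n > 0) {
    if (any(h < 1L | h > n) || any(h[h] != seq_len(n)))
      msg <- c(msg, "homolog must be an involution on the parcel indices")
    if (any(h == seq_len(n)))
      msg <- c(msg, "homolog must have no fixed points")
    if (any(object@lobe != object@lobe[h]))
      msg <- c(msg, "homolog pairs must share a lobe")
    if (any(object@hemisphere == object@hemisphere[h]))
      msg <- c(msg, "homolog pairs must lie in opposite hemispheres")
  }
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------ ##
##  GroundTruth                                                       ##
## ------------------------------------------------------------------ ##

#' Generating parameters of a synthetic fetal cohort
#'
#' Stores every symbol the synthetic-BOLD forward model uses: per-edge sigmoid
#' trajectory parameters, the mirror-asymmetry (homolog-similarity decay)
#' component, the laterality effect, the noise/motion/nuisance model, and the
#' seed the random structure was drawn with. Serializable to JSON via
#' \code{\link{writeGroundTruth}}.
#'
#' @slot parcellation a \code{\linkS4class{Parcellation}}.
#' @slot beta1,beta2,beta3,beta4 node x node matrices of per-edge sigmoid
#'   parameters (span, baseline, inflection week, growth-rate scale).
#' @slot structMatrix static mirror-symmetric low-rank "topography"
#'   component (positive semidefinite) giving connectivity profiles stable,
#'   age-independent spatial heterogeneity.
#' @slot homologDecay per-week blend weight towards the independent
#'   correlation structure (0 = homolog similarity constant in age).
#' @slot asymMatrix fixed random correlation matrix (positive definite, not
#'   mirror-symmetric); the truth matrix at age \code{ga} is the convex blend
#'   \code{(1-w) M_sym + w asymMatrix} with
#'   \code{w = homologDecay * (ga - 19)}, so homolog similarity decays with
#'   age without any eigenvalue clipping.
#' @slot lateralityOffset,lateralitySlope laterality effect (LI offset at the
#'   reference age and LI change per week) applied to \code{lateralityParcels}.
#' @slot lateralityParcels base names (no hemisphere suffix) of lateralized
#'   parcels.
#' @slot gaRef reference gestational age (weeks) for age-centred effects.
#' @slot noiseSd per-voxel noise standard deviation in grey-matter voxels.
#' @slot tissueNoiseSd per-voxel noise in WM/CSF voxels on top of the rank-5
#'   latent components.
#' @slot spikeProb per-frame probability of a motion-corrupted frame.
#' @slot spikeAmp intensity-spike amplitude (signal SD units).
#' @slot spikeVoxelFrac fraction of voxels hit by an intensity spike in a
#'   corrupted frame.
#' @slot nWm,nCsf number of latent white-matter / CSF nuisance components.
#' @slot wmLeak,csfLeak mixing weight of the nuisance components into
#'   grey-matter voxels.
#' @slot voxelsPerParcel grey-matter voxels per parcel.
#' @slot nWmVoxels,nCsfVoxels voxels in the WM / CSF pools.
#' @slot ar lag-1 autocorrelation of the latent BOLD signals (0 = white).
#' @slot seed seed used to draw the random structure (asymmetry direction).
#' @export
setClass("GroundTruth", representation(
  parcellation = "Parcellation",
  beta1 = "matrix", beta2 = "matrix", beta3 = "matrix", beta4 = "matrix",
  structMatrix = "matrix",
  homologDecay = "numeric",
  asymMatrix = "matrix",
  lateralityOffset = "numeric",
  lateralitySlope = "numeric",
  lateralityParcels = "character",
  gaRef = "numeric",
  noiseSd = "numeric",
  tissueNoiseSd = "numeric",
  spikeProb = "numeric",
  spikeAmp = "numeric",
  spikeVoxelFrac = "numeric",
  nWm = "integer", nCsf = "integer",
  wmLeak = "numeric", csfLeak = "numeric",
  voxelsPerParcel = "integer",
  nWmVoxels = "integer", nCsfVoxels = "integer",
  ar = "numeric",
  seed = "integer"
))

setValidity("GroundTruth", function(object) {
  n <- nNodes(object@parcellation)
  msg <- character()
  for (nm in c("beta1", "beta2", "beta3", "beta4", "asymMatrix",
               "structMatrix")) {
    M <- slot(object, nm)
    if (!all(dim(M) == c(n, n)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, n, n))
    else if (max(abs(M - t(M))) > 1e-12)
      msg <- c(msg, sprintf("%s must be symmetric", nm))
  }
  off <- upper.tri(object@beta4)
  if (all(dim(object@beta4) == c(n, n)) && any(object@beta4[off] == 0))
    msg <- c(msg, "beta4 must be nonzero on every edge")
  if (!all(is.finite(c(object@homologDecay, object@lateralityOffset,
                       object@lateralitySlope, object@noiseSd,
                       object@spikeProb, object@spikeAmp))))
    msg <- c(msg, "scalar rates must be finite")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------ ##
##  SubjectRecord                                                     ##
## ------------------------------------------------------------------ ##

#' One simulated fetus
#'
#' @slot subjectId character id.
#' @slot gaWeeks gestational age in decimal weeks.
#' @slot voxelTs frames x voxels BOLD matrix.
#' @slot voxelLabels per-voxel label: a parcel/thalamus name, \code{"WM"} or
#'   \code{"CSF"}.
#' @slot motionTrace frames x 6 rigid-body parameters (3 translations in mm,
#'   3 rotations in radians).
#' @slot corruptedFrames integer indices of frames with injected spikes.
#' @slot truthFc the noiseless generating connectivity matrix at this age.
#' @slot tr repetition time in seconds.
#' @export
setClass("SubjectRecord", representation(
  subjectId = "character",
  gaWeeks = "numeric",
  voxelTs = "matrix",
  voxelLabels = "character",
  motionTrace = "matrix",
  corruptedFrames = "integer",
  truthFc = "matrix",
  tr = "numeric"
))

setValidity("SubjectRecord", function(object) {
  msg <- character()
  nf <- nrow(object@voxelTs)
  if (nf < 2) msg <- c(msg, "at least 2 frames required")
  if (length(object@voxelLabels) != ncol(object@voxelTs))
    msg <- c(msg, "one label per voxel required")
  if (!all(dim(object@motionTrace) == c(nf, 6)))
    msg <- c(msg, "motionTrace must be frames x 6")
  if (length(object@corruptedFrames) &&
      (min(object@corruptedFrames) < 1 || max(object@corruptedFrames) > nf))
    msg <- c(msg, "corruptedFrames out of range")
  if (length(msg)) msg else TRUE
})

## ------------------------------------------------------------------ ##
##  CensorMask / NuisanceDesign / CleanRoiTimeSeries                  ##
## ------------------------------------------------------------------ ##

#' Per-frame censoring state
#'
#' @slot rejected logical per frame: volume rejected by outlier detection.
#' @slot interpolated logical per frame: value replaced by interpolation
#'   (a subset of \code{rejected}).
#' @export
setClass("CensorMask", representation(
  rejected = "logical",
  interpolated = "logical"
))

setValidity("CensorMask", function(object) {
  msg <- character()
  if (length(object@rejected) != length(object@interpolated))
    msg <- c(msg, "rejected and interpolated must have equal length")
  else if (any(object@interpolated & !object@rejected))
    msg <- c(msg, "interpolated frames must be a subset of rejected frames")
  if (length(msg)) msg else TRUE
})

#' Nuisance regression design
#'
#' Frames x k matrix of mean-centred nuisance regressors (aCompCor principal
#' components and discrete-cosine high-pass columns) with provenance labels.
#'
#' @slot design frames x k numeric matrix.
#' @slot labels character column provenance (e.g. \code{"WM-PC1"},
#'   \code{"DCT1"}).
#' @export
setClass("NuisanceDesign", representation(
  design = "matrix",
  labels = "character"
))

setValidity("NuisanceDesign", function(object) {
  if (ncol(object@design) != length(object@labels))
    "one label per design column required" else TRUE
})

#' Cleaned ROI time series
#'
#' Residual ROI signals after joint high-pass filtering and nuisance
#' regression; rejected frames are filled by interpolation but flagged so that
#' downstream correlation analysis can skip them.
#'
#' @slot ts frames x n_roi numeric matrix.
#' @slot censor a \code{\linkS4class{CensorMask}}.
#' @slot tr repetition time (seconds).
#' @export
setClass("CleanRoiTimeSeries", representation(
  ts = "matrix",
  censor = "CensorMask",
  tr = "numeric"
))

## ------------------------------------------------------------------ ##
##  ConnectivityMatrix / MotionSummary / SigmoidFit / QCReport        ##
## ------------------------------------------------------------------ ##

#' Subject-level functional connectivity matrix
#'
#' Symmetric Pearson correlation matrix over ROIs (unit diagonal), with the
#' subject id and gestational age it belongs to.
#'
#' @slot mat n x n numeric matrix, parcel order fixed by the parcellation.
#' @slot subjectId character.
#' @slot gaWeeks numeric, decimal weeks.
#' @export
setClass("ConnectivityMatrix", representation(
  mat = "matrix",
  subjectId = "character",
  gaWeeks = "numeric"
))

setValidity("ConnectivityMatrix", function(object) {
  M <- object@mat
  msg <- character()
  if (nrow(M) != ncol(M)) msg <- c(msg, "matrix must be square")
  else {
    if (max(abs(M - t(M))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(diag(M) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (max(abs(M)) > 1 + 1e-8) msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Motion summary
#'
#' Framewise displacement trace plus its mean and maximum.
#'
#' @slot fd per-frame framewise displacement (mm); \code{fd[1] = 0}.
#' @slot meanFd,maxFd scalars.
#' @export
setClass("MotionSummary", representation(
  fd = "numeric", meanFd = "numeric", maxFd = "numeric"
))

setValidity("MotionSummary", function(object) {
  if (length(object@fd) && (object@fd[1] != 0 || any(object@fd < 0)))
    "fd must be nonnegative with fd[1] = 0" else TRUE
})

#' Sigmoid growth-curve fit
#'
#' @slot beta named numeric of length 4 (\code{beta1} span, \code{beta2}
#'   baseline, \code{beta3} inflection week, \code{beta4} growth-rate scale).
#' @slot adjR2,aic,bic goodness of fit (4 fitted mean parameters + error
#'   variance).
#' @slot rss residual sum of squares.
#' @slot converged logical: did the nonlinear polish converge.
#' @slot degenerate logical: |beta4| exceeds the observed GA span (near-linear
#'   regime).
#' @slot nObs number of observations.
#' @export
setClass("SigmoidFit", representation(
  beta = "numeric",
  adjR2 = "numeric", aic = "numeric", bic = "numeric",
  rss = "numeric",
  converged = "logical",
  degenerate = "logical",
  nObs = "integer"
))

setValidity("SigmoidFit", function(object) {
  msg <- character()
  if (length(object@beta) != 4)
    msg <- c(msg, "beta must have length 4")
  if (length(object@adjR2) == 1 && is.finite(object@adjR2) &&
      object@adjR2 > 1 + 1e-12)
    msg <- c(msg, "adjusted R-squared cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' Group-level quality-control report
#'
#' Result of the iterative tangent-space age-consistency filter (and,
#' optionally, per-subject dynamic-FC/motion statistics).
#'
#' @slot subjectIds character.
#' @slot kept logical per subject.
#' @slot ageConsistency per-subject GA-distance/FC-distance correlation, taken
#'   at the iteration where the subject was last evaluated.
#' @slot removedAt iteration number at which a subject was removed (NA if
#'   kept).
#' @slot iterations list of per-iteration data frames (subject, correlation,
#'   removed).
#' @slot dfcFd per-subject dynamic-FC/FD association statistic (NA if not
#'   computed).
#' @export
setClass("QCReport", representation(
  subjectIds = "character",
  kept = "logical",
  ageConsistency = "numeric",
  removedAt = "numeric",
  iterations = "list",
  dfcFd = "numeric"
))

setValidity("QCReport", function(object) {
  n <- length(object@subjectIds)
  if (length(object@kept) != n || length(object@ageConsistency) != n)
    return("per-subject slots must share length")
  bad <- !object@kept & !(object@ageConsistency < 0)
  if (any(bad[!is.na(bad)]))
    return("removed subjects must have negative age consistency")
  TRUE
})
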