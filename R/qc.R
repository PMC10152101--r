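#' Framewise displacement
#'
#' Standard scalar head-motion summary per frame:
#' \code{FD(t) = sum |delta translations| + r * sum |delta rotations|},
#' with rotations (radians) converted to arc length on a sphere of radius
#' \code{headRadiusMm}. The first frame has FD 0.
#'
#' @param motionTrace frames x 6 matrix: 3 translations (mm) then 3 rotations
#'   (radians).
#' @param headRadiusMm head radius in mm (default 50).
#' @return a \code{\linkS4class{MotionSummary}}.
#' @export
framewiseDisplacement <- function(motionTrace, headRadiusMm = 50) {
  stopifnot(is.matrix(motionTrace), ncol(motionTrace) == 6)
  if (nrow(motionTrace) < 2) stop("at least 2 frames required")
  if (!all(is.finite(motionTrace)))
    stop("non-finite motion parameters")
  d <- abs(diff(motionTrace))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            headRadiusMm * rowSums(d[, 4:6, drop = FALSE]))
  new("MotionSummary", fd = fd, meanFd = mean(fd), maxFd = max(fd))
}

#' Association between dynamic FC and framewise displacement
#'
#' Sliding-window subject-level quality statistic: per window the
#' upper-triangle FC vector is computed; the dynamic-FC change series is the
#' mean absolute difference between consecutive window FC vectors; the
#' statistic is the Pearson correlation between that change series and the
#' mean FD over the frames by which the two windows differ (the frames
#' entering and leaving the window -- the motion events that can drive the
#' observed FC change). Constant FD yields a statistic of 0 with a
#' degenerate flag.
#'
#' @param clean a \code{\linkS4class{CleanRoiTimeSeries}} or frames x n
#'   matrix.
#' @param fd per-frame framewise displacement (numeric) or a
#'   \code{\linkS4class{MotionSummary}}.
#' @param windowFrames window length in frames (default 10, minimum 5).
#' @param step window step in frames (default 1).
#' @return list with \code{statistic}, \code{degenerate}, \code{nWindows}.
#' @export
dfcFdAssociation <- function(clean, fd, windowFrames = 10, step = 1) {
  ts <- if (is(clean, "CleanRoiTimeSeries")) clean@ts else clean
  if (is(fd, "MotionSummary")) fd <- fd@fd
  nf <- nrow(ts)
  stopifnot(length(fd) == nf)
  if (windowFrames < 5) stop("windowFrames must be at least 5")
  if (windowFrames > nf) stop("windowFrames exceeds the number of frames")
  starts <- seq(1, nf - windowFrames + 1, by = step)
  ut <- upper.tri(matrix(0, ncol(ts), ncol(ts)))
  vecs <- lapply(starts, function(s) {
    w <- s:(s + windowFrames - 1)
    C <- suppressWarnings(stats::cor(ts[w, , drop = FALSE]))
    C[is.na(C)] <- 0
    C[ut]
  })
  if (length(starts) < 3)
    stop("too few windows; decrease windowFrames or step")
  dfc <- vapply(seq_len(length(vecs) - 1),
                function(j) mean(abs(vecs[[j + 1]] - vecs[[j]])), numeric(1))
  wfd <- vapply(seq_len(length(starts) - 1), function(j) {
    w1 <- starts[j]:(starts[j] + windowFrames - 1)
    w2 <- starts[j + 1]:(starts[j + 1] + windowFrames - 1)
    changed <- c(setdiff(w1, w2), setdiff(w2, w1))
    mean(fd[changed])
  }, numeric(1))
  if (stats::sd(wfd) < 1e-12 || stats::sd(dfc) < 1e-12)
    return(list(statistic = 0, degenerate = TRUE, nWindows = length(starts)))
  list(statistic = stats::cor(dfc, wfd), degenerate = FALSE,
       nWindows = length(starts))
}

#' Affine-invariant geometry on SPD matrices
#'
#' \code{spdGeometricMean} computes the affine-invariant (Karcher) mean of a
#' list of SPD matrices by the standard fixed-point iteration
#' \code{G <- G^{1/2} expm(mean_i logm(G^{-1/2} M_i G^{-1/2})) G^{1/2}};
#' \code{spdDistance} is the affine-invariant distance
#' \code{||logm(A^{-1/2} B A^{-1/2})||_F}; \code{spdSqrt}/\code{spdLog} are
#' the eigendecomposition-based matrix square root and logarithm.
#'
#' @param matrices list of SPD matrices.
#' @param tol convergence tolerance on the Frobenius norm of the mean tangent
#'   step (default 1e-8).
#' @param maxIter maximum fixed-point iterations (default 50).
#' @param A,B,M SPD matrices.
#' @return \code{spdGeometricMean}: the mean SPD matrix;
#'   \code{spdDistance}: a nonnegative scalar.
#' @export
spdGeometricMean <- function(matrices, tol = 1e-8, maxIter = 50) {
  stopifnot(length(matrices) >= 1)
  for (M in matrices) stopifnotSymmetric(M, label = "input matrix")
  G <- Reduce(`+`, matrices) / length(matrices)
  for (it in seq_len(maxIter)) {
    Gs <- spdSqrt(G)
    Gis <- spdInvSqrt(G)
    Tbar <- Reduce(`+`, lapply(matrices, function(M)
      spdLog(Gis %*% M %*% Gis))) / length(matrices)
    G <- Gs %*% spdExp(Tbar) %*% Gs
    G <- (G + t(G)) / 2
    if (sqrt(sum(Tbar^2)) < tol) return(G)
  }
  stop("geometric-mean fixed-point iteration did not converge in ",
       maxIter, " iterations")
}

#' @rdname spdGeometricMean
#' @export
spdDistance <- function(A, B) {
  Ais <- spdInvSqrt(A)
  sqrt(sum(spdLog(Ais %*% B %*% Ais)^2))
}

#' Tangent-space embedding of connectivity matrices
#'
#' Regularizes each matrix to SPD via shrinkage towards the identity,
#' computes the affine-invariant geometric mean as reference, and projects
#' every matrix to the tangent space at the reference:
#' \code{T_i = logm(ref^{-1/2} M_i ref^{-1/2})}.
#'
#' @param matrices list of \code{\linkS4class{ConnectivityMatrix}} or plain
#'   symmetric matrices.
#' @param shrinkage shrinkage weight in (0, 1]:
#'   \code{(1 - s) M + s I} (default 0.1).
#' @param tol,maxIter passed to \code{\link{spdGeometricMean}}.
#' @return list with \code{reference} (SPD matrix) and \code{tangent}
#'   (list of symmetric tangent matrices).
#' @export
tangentEmbed <- function(matrices, shrinkage = 0.1, tol = 1e-8,
                         maxIter = 50) {
  if (length(matrices) < 2) stop("at least 2 matrices required")
  if (shrinkage <= 0 || shrinkage > 1)
    stop("shrinkage must lie in (0, 1]")
  mats <- lapply(matrices, function(M) {
    if (is(M, "ConnectivityMatrix")) M <- M@mat
    stopifnotSymmetric(M, label = "connectivity matrix")
    (1 - shrinkage) * M + shrinkage * diag(nrow(M))
  })
  ref <- spdGeometricMean(mats, tol = tol, maxIter = maxIter)
  Ris <- spdInvSqrt(ref)
  tangent <- lapply(mats, function(M) spdLog(Ris %*% M %*% Ris))
  list(reference = ref, tangent = tangent)
}

## Pairwise Euclidean distances between tangent maps at a common reference.
tangentDistances <- function(tangent) {
  n <- length(tangent)
  V <- vapply(tangent, as.numeric, numeric(length(tangent[[1]])))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- sqrt(sum((V[, i] - V[, j])^2))
  D
}

#' Iterative age-consistency quality filter
#'
#' Group-level quality control built on the premise that, in a homogeneous
#' developing cohort, the distance between two subjects' connectivity
#' matrices grows with the distance between their gestational ages. Each
#' iteration embeds the currently kept matrices in the tangent space at their
#' geometric mean, computes for every subject the Pearson correlation between
#' its gestational-age gaps and its tangent-space distances to all other kept
#' subjects, removes every subject with a negative correlation, and
#' re-embeds; iteration stops when no correlation is negative or only
#' \code{minKeep} subjects remain (the most negative are removed first when
#' the last removal would overshoot).
#'
#' @param matrices list of \code{\linkS4class{ConnectivityMatrix}} or plain
#'   symmetric matrices.
#' @param gaWeeks gestational ages (taken from the matrices when omitted).
#' @param minKeep minimum number of subjects to retain (default 3).
#' @param shrinkage tangent-embedding shrinkage (default 0.1).
#' @param subjectIds ids (taken from the matrices when omitted).
#' @return a \code{\linkS4class{QCReport}}.
#' @export
iterativeAgeConsistencyFilter <- function(matrices, gaWeeks = NULL,
                                          minKeep = 3, shrinkage = 0.1,
                                          subjectIds = NULL) {
  n <- length(matrices)
  if (n < 3) stop("at least 3 subjects required")
  if (minKeep < 3 || minKeep > n)
    stop("minKeep must satisfy 3 <= minKeep <= n")
  if (is.null(gaWeeks) && all(vapply(matrices, is, logical(1),
                                     "ConnectivityMatrix")))
    gaWeeks <- vapply(matrices, function(m) m@gaWeeks, numeric(1))
  if (is.null(subjectIds)) {
    subjectIds <- if (all(vapply(matrices, is, logical(1),
                                 "ConnectivityMatrix")))
      vapply(matrices, subjectId, character(1))
    else sprintf("S%03d", seq_len(n))
  }
  stopifnot(length(gaWeeks) == n)

  kept <- rep(TRUE, n)
  consistency <- rep(NA_real_, n)
  removedAt <- rep(NA_real_, n)
  iterations <- list()
  if (n == minKeep) {
    warning("cohort already at minKeep; nothing removed")
  }
  it <- 0
  repeat {
    it <- it + 1
    idx <- which(kept)
    emb <- tangentEmbed(matrices[idx], shrinkage = shrinkage)
    D <- tangentDistances(emb$tangent)
    r <- vapply(seq_along(idx), function(i) {
      gaGap <- abs(gaWeeks[idx][i] - gaWeeks[idx][-i])
      d <- D[i, -i]
      if (stats::sd(gaGap) < 1e-12 || stats::sd(d) < 1e-12) return(0)
      stats::cor(gaGap, d)
    }, numeric(1))
    consistency[idx] <- r
    neg <- which(r < 0)
    removeNow <- integer()
    if (length(neg) && length(idx) > minKeep) {
      if (length(idx) - length(neg) < minKeep)
        neg <- neg[order(r[neg])][seq_len(length(idx) - minKeep)]
      removeNow <- idx[neg]
    }
    iterations[[it]] <- data.frame(
      iteration = it, subject_id = subjectIds[idx],
      age_consistency = r,
      removed = idx %in% removeNow, stringsAsFactors = FALSE)
    if (!length(removeNow)) break
    kept[removeNow] <- FALSE
    removedAt[removeNow] <- it
    if (sum(kept) <= minKeep) break
  }
  new("QCReport", subjectIds = subjectIds, kept = kept,
      ageConsistency = consistency, removedAt = removedAt,
      iterations = iterations, dfcFd = rep(NA_real_, n))
}

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d subjects, %d kept, %d removed over %d iteration(s)\n",
              length(object@kept), sum(object@kept), sum(!object@kept),
              length(object@iterations)))
})

setMethod("show", "MotionSummary", function(object) {
  cat(sprintf("MotionSummary: %d frames, mean FD %.3f mm, max FD %.3f mm\n",
              length(object@fd), object@meanFd, object@maxFd))
})
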