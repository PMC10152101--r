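## Sigmoid trajectory parameters planted on thalamus--visual-cortex edges.
## Values follow the reported left-hemisphere developmental fits for the
## middle/superior occipital gyri, calcarine, cuneus, lingual and fusiform
## regions (initial plateau beta2, span beta1, inflection beta3, rate beta4).
## The same parameters are used for both hemispheres so that, with the
## asymmetry components switched off, the generating matrix is exactly
## mirror-symmetric.
.thalamoVisualBeta <- list(
  MOG  = c(beta1 = 0.3587, beta2 = -0.0133, beta3 = 29.3857, beta4 = 0.4614),
  SOG  = c(beta1 = 0.3389, beta2 = -0.0535, beta3 = 29.5098, beta4 = 1.2673),
  CAL  = c(beta1 = 0.0173, beta2 = 0.3681, beta3 = 28.8726, beta4 = -0.6535),
  CUN  = c(beta1 = 0.4203, beta2 = 0.0057, beta3 = 31.0579, beta4 = 0.4492),
  LING = c(beta1 = 0.1593, beta2 = 0.0614, beta3 = 26.9146, beta4 = 114.9882),
  FFG  = c(beta1 = 0.027, beta2 = 0.12, beta3 = 30.46, beta4 = 43.44)
)

## Default GA range of the emulated cohort: 19+5 to 39+2 weeks.
.gaMinDefault <- 19 + 5 / 7
.gaMaxDefault <- 39 + 2 / 7

#' Generate a synthetic cohort table
#'
#' Draws \code{nSubjects} gestational ages uniformly on
#' \code{[gaMin, gaMax]} (the emulated study window is 19+5 to 39+2 weeks)
#' and assigns subject ids. Deterministic given \code{seed}.
#'
#' @param nSubjects number of fetuses (default 48).
#' @param gaMin,gaMax gestational-age range in decimal weeks.
#' @param seed integer seed.
#' @return \code{data.frame} with columns \code{subject_id}, \code{ga_weeks}.
#' @examples
#' head(generateCohort(48, seed = 7))
#' @export
generateCohort <- function(nSubjects = 48, gaMin = .gaMinDefault,
                           gaMax = .gaMaxDefault, seed = 1) {
  if (length(nSubjects) != 1 || is.na(nSubjects) || nSubjects < 1)
    stop("nSubjects must be a positive integer")
  if (!is.finite(gaMin) || !is.finite(gaMax) || gaMin >= gaMax)
    stop("gaMin must be strictly smaller than gaMax")
  ga <- withSeed(seed, stats::runif(nSubjects, gaMin, gaMax))
  data.frame(subject_id = sprintf("S%03d", seq_len(nSubjects)),
             ga_weeks = ga, stringsAsFactors = FALSE)
}

#' Build the generating ground truth of a synthetic cohort
#'
#' Assembles per-edge sigmoid trajectory parameters and the asymmetry, noise,
#' motion and nuisance models that define a synthetic fetal cohort. The base
#' connectivity structure is mirror-symmetric: a weak global increase on all
#' edges, stronger within-lobe coupling with lobe-specific inflection weeks,
#' strong homolog-pair coupling, and thalamus--visual edges following the
#' planted occipital trajectories. Age-dependent hemispheric differences enter
#' through two switchable components: an age-growing convex blend towards a
#' random independent correlation structure (homolog-similarity decay) and a
#' multiplicative laterality effect on temporal parcels.
#'
#' @param parcellation a \code{\linkS4class{Parcellation}} (default
#'   \code{\link{defaultParcellation}()}).
#' @param config named list overriding defaults; recognised entries:
#'   \describe{
#'     \item{homologDecay}{per-week blend weight towards the independent
#'       correlation structure (default 0.02; 0 disables the
#'       homolog-similarity decay).}
#'     \item{structSd, structRank}{target entry spread and rank of the
#'       static mirror-symmetric topography component (defaults 0.15 and
#'       10) that gives connectivity profiles stable spatial heterogeneity;
#'       built from mirrored factor loadings so it is positive semidefinite
#'       and exactly mirror-symmetric.}
#'     \item{asymRank}{rank of the random independent correlation structure
#'       the symmetric part is blended towards as gestation advances
#'       (default 12; lower rank means coarser, stronger asymmetry).}
#'     \item{lateralityOffset, lateralitySlope}{laterality effect at the
#'       reference age and its per-week slope (defaults 0.03 and 0.025;
#'       both 0 disables).}
#'     \item{lateralityParcels}{base names of lateralized parcels (default
#'       \code{c("STG", "MTG", "ITG")}, the superior/middle/inferior temporal
#'       regions).}
#'     \item{growth}{logical; \code{FALSE} freezes every edge at its value at
#'       the reference age (stationary cohort, the statistical null for
#'       age-trend calibration).}
#'     \item{noiseSd, tissueNoiseSd, spikeProb, spikeAmp, spikeVoxelFrac,
#'       nWm, nCsf, wmLeak, csfLeak, voxelsPerParcel, nWmVoxels, nCsfVoxels,
#'       ar, gaRef}{forward-model scalars, see
#'       \code{\linkS4class{GroundTruth}}.}
#'   }
#' @param seed integer seed for the random asymmetry direction.
#' @return a \code{\linkS4class{GroundTruth}}.
#' @export
buildGroundTruth <- function(parcellation = defaultParcellation(),
                             config = list(), seed = 1) {
  defaults <- list(
    homologDecay = 0.02,
    asymRank = 12L,
    structSd = 0.15,
    structRank = 10L,
    lateralityOffset = 0.03,
    lateralitySlope = 0.025,
    lateralityParcels = c("STG", "MTG", "ITG"),
    growth = TRUE,
    gaRef = 29,
    noiseSd = 0.5,
    tissueNoiseSd = 0.2,
    spikeProb = 0.06,
    spikeAmp = 8,
    spikeVoxelFrac = 0.3,
    nWm = 5L, nCsf = 5L,
    wmLeak = 0.15, csfLeak = 0.15,
    voxelsPerParcel = 10L,
    nWmVoxels = 50L, nCsfVoxels = 50L,
    ar = 0.4
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown ground-truth config entries: ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!all(is.finite(unlist(cfg[c("homologDecay", "lateralityOffset",
                                  "lateralitySlope", "noiseSd", "spikeProb",
                                  "spikeAmp")]))))
    stop("ground-truth rates must be finite")

  p <- parcellation
  n <- nNodes(p)
  nodes <- nodeNames(p)
  hemi <- c(hemisphereOf(p), rep("M", length(p@thalamus)))
  lobe <- c(lobeOf(p), rep("thalamus", length(p@thalamus)))
  hmap <- homologMap(p)

  b1 <- matrix(0, n, n); b2 <- matrix(0, n, n)
  b3 <- matrix(30, n, n); b4 <- matrix(3, n, n)

  setEdge <- function(i, j, beta) {
    b1[i, j] <<- b1[j, i] <<- beta[["beta1"]]
    b2[i, j] <<- b2[j, i] <<- beta[["beta2"]]
    b3[i, j] <<- b3[j, i] <<- beta[["beta3"]]
    b4[i, j] <<- b4[j, i] <<- beta[["beta4"]]
  }

  ## global weak increase
  b2[] <- 0.18; b1[] <- 0.12; b3[] <- 30; b4[] <- 3

  ## within-lobe coupling, lobe-specific inflection weeks
  lobeInflection <- c(frontal = 31, parietal = 29.5, temporal = 30,
                      occipital = 29, insular = 30, limbic = 30.5,
                      thalamus = 30)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (lobe[i] == lobe[j] && lobe[i] != "thalamus")
      setEdge(i, j, c(beta1 = 0.12, beta2 = 0.28,
                      beta3 = unname(lobeInflection[lobe[i]]), beta4 = 2))
  }

  ## homolog pairs
  for (i in seq_len(nParcels(p))) {
    j <- hmap[i]
    if (j > i)
      setEdge(i, j, c(beta1 = 0.12, beta2 = 0.38, beta3 = 29, beta4 = 2))
  }

  ## thalamocortical edges
  if (length(p@thalamus)) {
    thal <- which(nodes %in% p@thalamus)
    for (tn in thal) for (i in seq_len(nParcels(p))) {
      base <- sub("\\.[LR]$", "", nodes[i])
      if (base %in% names(.thalamoVisualBeta))
        setEdge(tn, i, .thalamoVisualBeta[[base]])
      else
        setEdge(tn, i, c(beta1 = 0.12, beta2 = 0.12, beta3 = 31, beta4 = 3))
    }
  }

  if (any(b4[upper.tri(b4)] == 0))
    stop("beta4 must be nonzero on every edge")

  if (!cfg$growth) {
    ## freeze at the reference age: flat trajectories with the same level
    b2 <- b2 + b1 / (1 + exp(-(cfg$gaRef - b3) / b4))
    b1[] <- 0
  }

  ## random components: static mirror-symmetric topography (low-rank PSD
  ## with mirrored loadings) and the mirror-antisymmetric decay direction
  rnd <- withSeed(seed, {
    k <- cfg$structRank
    s <- sqrt(cfg$structSd / sqrt(k))
    L <- matrix(0, n, k)
    left <- which(hemi == "L")
    L[left, ] <- stats::rnorm(length(left) * k, sd = s)
    L[hmap[left], ] <- L[left, ]
    mid <- which(!(hemi %in% c("L", "R")))
    if (length(mid)) L[mid, ] <- stats::rnorm(length(mid) * k, sd = s)
    G <- matrix(stats::rnorm(n * cfg$asymRank), n, cfg$asymRank)
    list(B = L %*% t(L),
         A = stats::cov2cor(G %*% t(G) + 0.5 * diag(n)))
  })
  asym <- rnd$A

  latPar <- cfg$lateralityParcels
  if (length(latPar)) regionIndices(p, latPar, "L")  # validate names

  new("GroundTruth",
      parcellation = p,
      beta1 = b1, beta2 = b2, beta3 = b3, beta4 = b4,
      structMatrix = rnd$B,
      homologDecay = cfg$homologDecay,
      asymMatrix = asym,
      lateralityOffset = cfg$lateralityOffset,
      lateralitySlope = cfg$lateralitySlope,
      lateralityParcels = as.character(latPar),
      gaRef = cfg$gaRef,
      noiseSd = cfg$noiseSd,
      tissueNoiseSd = cfg$tissueNoiseSd,
      spikeProb = cfg$spikeProb,
      spikeAmp = cfg$spikeAmp,
      spikeVoxelFrac = cfg$spikeVoxelFrac,
      nWm = as.integer(cfg$nWm), nCsf = as.integer(cfg$nCsf),
      wmLeak = cfg$wmLeak, csfLeak = cfg$csfLeak,
      voxelsPerParcel = as.integer(cfg$voxelsPerParcel),
      nWmVoxels = as.integer(cfg$nWmVoxels),
      nCsfVoxels = as.integer(cfg$nCsfVoxels),
      ar = cfg$ar,
      seed = as.integer(seed))
}

#' Generating connectivity matrix at a gestational age
#'
#' Evaluates the planted sigmoid trajectory of every edge at age \code{ga},
#' applies the laterality scaling and the age-growing mirror-asymmetric
#' perturbation, and projects the result onto the correlation-matrix cone
#' (negative eigenvalues clipped, then renormalized to unit diagonal).
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param ga gestational age in decimal weeks.
#' @return n x n correlation matrix with node names.
#' @export
truthMatrix <- function(truth, ga) {
  stopifnot(is.finite(ga))
  S <- truth@beta2 + truth@beta1 / (1 + exp(-(ga - truth@beta3) / truth@beta4))
  p <- truth@parcellation
  n <- nNodes(p)
  diag(S) <- 1
  S <- stats::cov2cor(S + truth@structMatrix)
  if (truth@homologDecay != 0) {
    w <- min(max(truth@homologDecay * (ga - 19), 0), 0.9)
    S <- (1 - w) * S + w * truth@asymMatrix
  }
  if (length(truth@lateralityParcels) &&
      (truth@lateralityOffset != 0 || truth@lateralitySlope != 0)) {
    g <- truth@lateralityOffset + truth@lateralitySlope * (ga - truth@gaRef)
    g <- max(min(g, 0.9), -0.9)
    d <- rep(1, n)
    d[regionIndices(p, truth@lateralityParcels, "L")] <- 1 + g
    d[regionIndices(p, truth@lateralityParcels, "R")] <- 1 - g
    S <- S * outer(d, d)
  }
  S[S > 0.99] <- 0.99
  S[S < -0.99] <- -0.99
  diag(S) <- 1
  M <- nearestCorrelation(S)
  dimnames(M) <- list(nodeNames(p), nodeNames(p))
  M
}

## Stationary unit-variance AR(1) noise, frames x k.
.arNoise <- function(frames, k, phi) {
  Z <- matrix(stats::rnorm(frames * k), frames, k)
  if (phi != 0) {
    for (t in 2:frames)
      Z[t, ] <- phi * Z[t - 1, ] + sqrt(1 - phi^2) * Z[t, ]
  }
  Z
}

#' Simulate one fetus at the voxel level
#'
#' Forward model: latent parcel signals with correlation structure equal to
#' \code{truthMatrix(truth, ga)} (independent AR(1) noise mixed through the
#' symmetric matrix square root), grey-matter voxels as parcel signal plus
#' voxel noise plus a leak of the latent WM/CSF nuisance components, WM/CSF
#' pools spanned by rank-\code{nWm}/\code{nCsf} latent components, and
#' motion-corrupted frames receiving simultaneous intensity spikes and
#' motion-trace spikes.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param ga gestational age (decimal weeks).
#' @param frames number of volumes (default 96).
#' @param tr repetition time, seconds (default 3).
#' @param seed integer seed; identical \code{(ga, seed)} give bit-identical
#'   records.
#' @param subjectId id string.
#' @return a \code{\linkS4class{SubjectRecord}}.
#' @export
simulateSubject <- function(truth, ga, frames = 96, tr = 3.0, seed = 1,
                            subjectId = "S001") {
  if (frames < 8) stop("frames must be at least 8")
  p <- truth@parcellation
  n <- nNodes(p)
  M <- truthMatrix(truth, ga)
  R <- spdSqrt(M)
  vpp <- truth@voxelsPerParcel
  nGm <- n * vpp
  nVox <- nGm + truth@nWmVoxels + truth@nCsfVoxels
  labels <- c(rep(nodeNames(p), each = vpp),
              rep("WM", truth@nWmVoxels), rep("CSF", truth@nCsfVoxels))

  rec <- withSeed(seed, {
    X <- .arNoise(frames, n, truth@ar) %*% R    # latent parcel signals
    W <- .arNoise(frames, truth@nWm, truth@ar)  # latent WM components
    Cc <- .arNoise(frames, truth@nCsf, truth@ar)

    V <- matrix(0, frames, nVox)
    gmIdx <- rep(seq_len(n), each = vpp)
    V[, seq_len(nGm)] <- X[, gmIdx] +
      truth@noiseSd * matrix(stats::rnorm(frames * nGm), frames, nGm)
    if (truth@wmLeak != 0)
      V[, seq_len(nGm)] <- V[, seq_len(nGm)] +
        truth@wmLeak * (W %*% matrix(stats::rnorm(truth@nWm * nGm),
                                     truth@nWm, nGm))
    if (truth@csfLeak != 0)
      V[, seq_len(nGm)] <- V[, seq_len(nGm)] +
        truth@csfLeak * (Cc %*% matrix(stats::rnorm(truth@nCsf * nGm),
                                       truth@nCsf, nGm))
    wmCols <- nGm + seq_len(truth@nWmVoxels)
    csfCols <- nGm + truth@nWmVoxels + seq_len(truth@nCsfVoxels)
    V[, wmCols] <- W %*% matrix(stats::rnorm(truth@nWm * truth@nWmVoxels),
                                truth@nWm, truth@nWmVoxels)
    V[, csfCols] <- Cc %*% matrix(stats::rnorm(truth@nCsf * truth@nCsfVoxels),
                                  truth@nCsf, truth@nCsfVoxels)
    if (truth@tissueNoiseSd != 0) {
      k <- truth@nWmVoxels + truth@nCsfVoxels
      V[, c(wmCols, csfCols)] <- V[, c(wmCols, csfCols)] +
        truth@tissueNoiseSd * matrix(stats::rnorm(frames * k), frames, k)
    }

    motion <- matrix(0, frames, 6)
    spikes <- integer()
    if (truth@spikeProb > 0) {
      spikes <- which(stats::runif(frames) < truth@spikeProb)
      for (t in spikes) {
        hit <- sample.int(nVox, max(1L, round(truth@spikeVoxelFrac * nVox)))
        V[t, hit] <- V[t, hit] +
          truth@spikeAmp * sample(c(-1, 1), length(hit), replace = TRUE)
        motion[t, 1:3] <- stats::rnorm(3, sd = 1.5)   # mm
        motion[t, 4:6] <- stats::rnorm(3, sd = 0.02)  # rad
      }
    }
    list(V = V, motion = motion, spikes = as.integer(spikes))
  })

  colnames(rec$V) <- sprintf("V%04d", seq_len(nVox))
  new("SubjectRecord",
      subjectId = subjectId, gaWeeks = ga,
      voxelTs = rec$V, voxelLabels = labels,
      motionTrace = rec$motion, corruptedFrames = rec$spikes,
      truthFc = M, tr = tr)
}

#' Simulate a subject's FC matrix at the parcel level
#'
#' Fast forward path that skips the voxel, motion and nuisance layers:
#' latent parcel signals with the ground-truth correlation structure plus
#' ROI-level noise (\code{noiseSd / sqrt(voxelsPerParcel)}, the residual noise
#' that voxel averaging would leave), correlated into a
#' \code{\linkS4class{ConnectivityMatrix}}. Used for cohort-scale simulation
#' studies of the downstream statistics.
#'
#' @inheritParams simulateSubject
#' @param ar override the ground-truth lag-1 autocorrelation (default: use
#'   \code{truth@ar}).
#' @return a \code{\linkS4class{ConnectivityMatrix}}.
#' @export
simulateFcMatrix <- function(truth, ga, frames = 96, seed = 1,
                             subjectId = "S001", ar = truth@ar) {
  if (frames < 8) stop("frames must be at least 8")
  M <- truthMatrix(truth, ga)
  n <- nrow(M)
  R <- spdSqrt(M)
  roiNoise <- truth@noiseSd / sqrt(truth@voxelsPerParcel)
  roi <- withSeed(seed, {
    X <- .arNoise(frames, n, ar) %*% R
    if (roiNoise > 0)
      X <- X + roiNoise * matrix(stats::rnorm(frames * n), frames, n)
    X
  })
  C <- stats::cor(roi)
  diag(C) <- 1
  dimnames(C) <- dimnames(M)
  new("ConnectivityMatrix", mat = C, subjectId = subjectId, gaWeeks = ga)
}

#' Simulate a cohort of FC matrices with optional planted inconsistency
#'
#' Generates one parcel-level FC matrix per cohort row. When \code{nPlanted}
#' is positive, that many subjects are drawn from the outer thirds of the
#' labelled age range and generated at a random age in the opposite outer
#' third, so their matrices are strongly inconsistent with their recorded
#' age -- the anomaly the group-level quality-control filter is designed to
#' catch.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param cohort cohort table from \code{\link{generateCohort}}.
#' @param frames frames per acquisition.
#' @param seed master seed (per-subject seeds are derived from it).
#' @param nPlanted number of GA-inconsistent subjects to plant (default 0).
#' @return list with \code{fc} (list of \code{ConnectivityMatrix}),
#'   \code{gaWeeks} (labelled ages), \code{planted} (indices).
#' @export
simulateCohortFc <- function(truth, cohort, frames = 96, seed = 1,
                             nPlanted = 0) {
  n <- nrow(cohort)
  ga <- cohort$ga_weeks
  gaEff <- ga
  planted <- integer()
  if (nPlanted > 0) {
    if (nPlanted >= n) stop("nPlanted must be smaller than the cohort size")
    gaMin <- min(ga); gaMax <- max(ga)
    third <- (gaMax - gaMin) / 3
    plant <- withSeed(seed + 1L, {
      cand <- which(ga < gaMin + third | ga > gaMax - third)
      if (length(cand) < nPlanted)
        cand <- order(pmin(ga - gaMin, gaMax - ga))[seq_len(nPlanted)]
      idx <- sort(sample(cand, nPlanted))
      eff <- vapply(idx, function(i) {
        if (ga[i] < (gaMin + gaMax) / 2)
          stats::runif(1, gaMax - third, gaMax)
        else stats::runif(1, gaMin, gaMin + third)
      }, numeric(1))
      list(idx = idx, eff = eff)
    })
    planted <- plant$idx
    gaEff[planted] <- plant$eff
  }
  seeds <- childSeeds(seed, n)
  fc <- vector("list", n)
  for (i in seq_len(n)) {
    fc[[i]] <- simulateFcMatrix(truth, gaEff[i], frames = frames,
                                seed = seeds[i],
                                subjectId = cohort$subject_id[i])
    fc[[i]]@gaWeeks <- ga[i]  # labelled (possibly inconsistent) age
  }
  list(fc = fc, gaWeeks = ga, planted = planted)
}

setMethod("show", "GroundTruth", function(object) {
  p <- object@parcellation
  cat("GroundTruth for", nNodes(p), "nodes\n")
  cat(sprintf("  homolog decay %.4g/wk, laterality offset %.4g slope %.4g/wk (%s)\n",
              object@homologDecay, object@lateralityOffset,
              object@lateralitySlope,
              paste(object@lateralityParcels, collapse = ",")))
  cat(sprintf("  noiseSd %.3g, spikeProb %.3g, ar %.2g, %d+%d nuisance comps\n",
              object@noiseSd, object@spikeProb, object@ar,
              object@nWm, object@nCsf))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s: GA %.2f wk, %d frames x %d voxels (TR %gs), %d corrupted frame(s)\n",
              object@subjectId, object@gaWeeks, nrow(object@voxelTs),
              ncol(object@voxelTs), object@tr,
              length(object@corruptedFrames)))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(sprintf("ConnectivityMatrix %s (GA %.2f wk): %d x %d\n",
              object@subjectId, object@gaWeeks,
              nrow(object@mat), ncol(object@mat)))
})

#' @rdname fcMatrix
#' @export
fcMatrix <- function(x) x@mat

#' Accessors for connectivity matrices
#'
#' @param x a \code{\linkS4class{ConnectivityMatrix}}.
#' @return \code{fcMatrix}: the numeric matrix; \code{gaWeeks}: the
#'   gestational age; \code{subjectId}: the id.
#' @name fcMatrix
#' @export
gaWeeks <- function(x) x@gaWeeks

#' @rdname fcMatrix
#' @export
subjectId <- function(x) x@subjectId
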