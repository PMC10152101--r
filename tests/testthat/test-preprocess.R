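test_that("outlier-volume detection follows the strict 5% rule", {
  nf <- 60; nv <- 200
  clean <- withSeed(1, matrix(rnorm(nf * nv), nf, nv))
  expect_equal(sum(detectOutlierVolumes(clean, spikeZ = 5)@rejected), 0)

  ## spike 10% of voxels at frame 20 -> rejected
  spiked <- clean
  hit <- seq_len(0.10 * nv)
  spiked[20, hit] <- spiked[20, hit] + 12 * rep(c(-1, 1), length.out = length(hit))
  cm <- detectOutlierVolumes(spiked, spikeZ = 5, volumeFraction = 0.05)
  expect_true(cm@rejected[20])
  expect_equal(sum(cm@rejected), 1)   # the spiked frame only

  ## exactly 5.0% outlier voxels -> kept (strictly-greater rule)
  border <- clean
  hit <- seq_len(0.05 * nv)
  border[20, hit] <- border[20, hit] + 12 * rep(c(-1, 1), length.out = length(hit))
  cmB <- detectOutlierVolumes(border, spikeZ = 5, volumeFraction = 0.05)
  expect_false(cmB@rejected[20])

  expect_error(detectOutlierVolumes(clean, volumeFraction = 1.5), "\\[0, 1\\]")
  expect_error(detectOutlierVolumes(clean[1:2, ]), "3 frames")
})

test_that("aCompCor recovers a planted rank-5 nuisance subspace exactly when noiseless", {
  gt0 <- buildGroundTruth(fullParc, list(tissueNoiseSd = 0, spikeProb = 0),
                          seed = 2)
  rec <- simulateSubject(gt0, 28, seed = 3)
  nd <- computeACompCor(rec@voxelTs, rec@voxelLabels, nWm = 5, nCsf = 5)
  expect_identical(nd@labels,
                   c(paste0("WM-PC", 1:5), paste0("CSF-PC", 1:5)))
  for (tissue in c("WM", "CSF")) {
    block <- rec@voxelTs[, rec@voxelLabels == tissue, drop = FALSE]
    oracle <- qr.Q(qr(svd(scale(block, scale = FALSE))$u[, 1:5]))
    pcs <- qr.Q(qr(nd@design[, grepl(tissue, nd@labels), drop = FALSE]))
    angles <- acos(pmin(svd(crossprod(oracle, pcs))$d, 1))
    expect_lt(max(angles), 1e-6)
  }
  ## PC columns mutually orthogonal within tissue, mean-centred
  wm <- nd@design[, 1:5]
  expect_lt(max(abs(crossprod(wm) - diag(diag(crossprod(wm))))), 1e-8)
  expect_lt(max(abs(colMeans(nd@design))), 1e-10)
})

test_that("aCompCor respects component counts and tissue-pool preconditions", {
  ts <- withSeed(4, matrix(rnorm(40 * 30), 40, 30))
  labels <- c(rep("WM", 12), rep("CSF", 12), rep("P1.L", 6))
  nd0 <- computeACompCor(ts, labels, nWm = 0, nCsf = 0)
  expect_equal(ncol(nd0@design), 0)
  expect_error(computeACompCor(ts, labels, nWm = 15, nCsf = 5),
               "insufficient WM")
})

test_that("joint cleaning removes slow drift and regressors in one projection", {
  nf <- 96; tr <- 3
  tt <- seq_len(nf) * tr
  drift <- sin(2 * pi * 0.002 * tt)
  sig <- withSeed(5, matrix(rnorm(nf * 3), nf, 3))
  nuis <- withSeed(6, matrix(rnorm(nf * 2), nf, 2))
  colnames(nuis) <- c("N1", "N2")
  design <- new("NuisanceDesign", design = scale(nuis, scale = FALSE),
                labels = colnames(nuis))
  y <- sig + drift + nuis %*% rbind(c(0.5, 0, 1), c(0, -0.8, 0.3))
  colnames(y) <- paste0("R", 1:3)
  cl <- cleanTimeseries(y, design, highpassHz = 0.008, tr = tr)
  ## residuals orthogonal to every design column
  X <- cbind(1, fetoconn:::dctHighpassBasis(nf, tr, 0.008), design@design)
  expect_lt(max(abs(crossprod(X, cl@ts))), 1e-8)
  ## > 99% of pure-drift power removed
  clDrift <- cleanTimeseries(matrix(drift, ncol = 1), NULL, 0.008, tr)
  expect_lt(sum(clDrift@ts^2) / sum(drift^2), 0.01)
  ## idempotence on already-clean data
  cl2 <- cleanTimeseries(cl@ts, design, highpassHz = 0.008, tr = tr)
  expect_lt(max(abs(cl2@ts - cl@ts)), 1e-8 * max(abs(cl@ts)))
})

test_that("cleaning reports collinear design columns and Nyquist violations", {
  nf <- 48
  bad <- matrix(rnorm(nf), nf, 2)   # duplicated column
  colnames(bad) <- c("N1", "N1dup")
  design <- new("NuisanceDesign", design = bad, labels = colnames(bad))
  y <- matrix(rnorm(nf), ncol = 1)
  expect_error(cleanTimeseries(y, design, 0.008, 3), "collinear")
  expect_error(cleanTimeseries(y, NULL, highpassHz = 0.5, tr = 3), "Nyquist")
})

test_that("rejected frames are interpolated, flagged and excluded downstream", {
  nf <- 50
  y <- withSeed(7, matrix(rnorm(nf * 4), nf, 4))
  colnames(y) <- paste0("R", 1:4)
  rej <- rep(FALSE, nf); rej[c(1, 17, 18, 50)] <- TRUE
  censor <- new("CensorMask", rejected = rej,
                interpolated = rep(FALSE, nf))
  cl <- cleanTimeseries(y, NULL, 0.008, 3, censor = censor)
  expect_true(all(is.finite(cl@ts)))
  expect_equal(which(cl@censor@interpolated), c(1, 17, 18, 50))
  expect_equal(validFrames(cl), !rej)
  ## FC ignores interpolated frames entirely
  fcA <- computeFC(cl)
  clB <- cl
  clB@ts[rej, ] <- 1e6   # arbitrary perturbation of interpolated frames
  fcB <- computeFC(clB)
  expect_identical(fcMatrix(fcA), fcMatrix(fcB))
})

test_that("planted spikes are censored with high sensitivity and low false-positive rate", {
  sens <- c(); fpr <- c()
  for (s in 1:10) {
    rec <- simulateSubject(defaultTruth, 28, seed = 600 + s)
    cm <- detectOutlierVolumes(rec@voxelTs, spikeZ = 5)
    det <- which(cm@rejected)
    planted <- rec@corruptedFrames
    if (length(planted)) sens <- c(sens, mean(planted %in% det))
    fpr <- c(fpr, length(setdiff(det, planted)) /
               (nrow(rec@voxelTs) - length(planted)))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.05)
})
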