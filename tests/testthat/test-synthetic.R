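test_that("cohort generation is seeded, bounded and validates arguments", {
  co <- generateCohort(48, 19.71, 39.29, seed = 7)
  expect_equal(nrow(co), 48)
  expect_true(all(co$ga_weeks >= 19.71 & co$ga_weeks <= 39.29))
  expect_false(anyDuplicated(co$subject_id) > 0)
  expect_identical(co, generateCohort(48, 19.71, 39.29, seed = 7))
  expect_identical(generateCohort(1, 20, 21, seed = 0),
                   generateCohort(1, 20, 21, seed = 0))
  expect_error(generateCohort(0, 19, 39, seed = 0), "positive")
  expect_error(generateCohort(10, 30, 20), "smaller")
})

test_that("ground truth plants the reported visual-edge trajectory parameters", {
  gt <- defaultTruth
  thal <- which(nodeNames(fullParc) == "THA")
  mog <- which(nodeNames(fullParc) == "MOG.L")
  expect_equal(gt@beta1[thal, mog], 0.3587)
  expect_equal(gt@beta2[thal, mog], -0.0133)
  expect_equal(gt@beta3[thal, mog], 29.3857)
  expect_equal(gt@beta4[thal, mog], 0.4614)
  ## same parameters on the contralateral twin (mirror-symmetric base)
  mogR <- which(nodeNames(fullParc) == "MOG.R")
  expect_equal(gt@beta3[thal, mogR], 29.3857)
  expect_error(buildGroundTruth(fullParc, list(bogus = 1)), "unknown")
  expect_error(buildGroundTruth(fullParc, list(noiseSd = NaN)), "finite")
})

test_that("truth matrices are mirror-symmetric correlation matrices when asymmetry is off", {
  p <- fullParc
  h <- homologMap(p)
  P <- diag(nNodes(p))[h, ]
  for (ga in c(20, 25, 38)) {
    M <- truthMatrix(symTruth, ga)
    expect_equal(M, P %*% M %*% t(P), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(diag(M), rep(1, nNodes(p)), ignore_attr = TRUE)
    expect_equal(M, t(M))
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_lte(max(abs(M)), 1)
  }
})

test_that("planted visual edge increases strictly and monotonically with age", {
  thal <- which(nodeNames(fullParc) == "THA")
  mog <- which(nodeNames(fullParc) == "MOG.L")
  gas <- seq(20, 39, by = 0.5)
  vals <- vapply(gas, function(g) truthMatrix(symTruth, g)[thal, mog],
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("homolog similarity of the truth is age-invariant without decay and decays with it", {
  s20 <- mean(homologSimilarities(truthMatrix(symTruth, 20), fullParc))
  s38 <- mean(homologSimilarities(truthMatrix(symTruth, 38), fullParc))
  expect_equal(s20, s38, tolerance = 1e-10)
  expect_equal(s20, 1, tolerance = 1e-10)  # perfect mirror symmetry
  d20 <- mean(homologSimilarities(truthMatrix(defaultTruth, 20), fullParc))
  d38 <- mean(homologSimilarities(truthMatrix(defaultTruth, 38), fullParc))
  expect_lt(d38, d20 - 0.2)
})

test_that("subject simulation is bit-reproducible and respects the motion switch", {
  a <- simulateSubject(defaultTruth, 28, seed = 11)
  b <- simulateSubject(defaultTruth, 28, seed = 11)
  expect_identical(a@voxelTs, b@voxelTs)
  expect_identical(a@motionTrace, b@motionTrace)
  expect_identical(a@corruptedFrames, b@corruptedFrames)
  quiet <- buildGroundTruth(fullParc, list(spikeProb = 0), seed = 1)
  rec <- simulateSubject(quiet, 28, seed = 3)
  expect_length(rec@corruptedFrames, 0)
  expect_true(all(rec@motionTrace == 0))
  expect_error(simulateSubject(defaultTruth, 28, frames = 4), "frames")
})

test_that("long noiseless simulations reproduce the generating connectivity", {
  gtE <- buildGroundTruth(fullParc,
                          list(noiseSd = 0, spikeProb = 0, ar = 0,
                               wmLeak = 0, csfLeak = 0), seed = 4)
  fc <- simulateFcMatrix(gtE, 30, frames = 5000, seed = 5, ar = 0)
  expect_lt(max(abs(fcMatrix(fc) - truthMatrix(gtE, 30))), 0.05)
})

test_that("voxel averaging of a noiseless subject equals the latent parcel signals", {
  gtE <- buildGroundTruth(fullParc,
                          list(noiseSd = 0, spikeProb = 0,
                               wmLeak = 0, csfLeak = 0), seed = 6)
  rec <- simulateSubject(gtE, 27, seed = 8)
  expect_length(rec@corruptedFrames, 0)
  roi <- roiAverage(rec@voxelTs, rec@voxelLabels, fullParc)
  ## every voxel of a parcel is an identical copy of the latent signal
  mog <- rec@voxelTs[, rec@voxelLabels == "MOG.L", drop = FALSE]
  expect_equal(roi[, "MOG.L"], mog[, 1], ignore_attr = TRUE)
  ## pipeline FC equals the Pearson oracle on the latent signals
  fc <- computeFC(roi)
  expect_equal(fcMatrix(fc), stats::cor(roi), tolerance = 1e-12,
               ignore_attr = TRUE)
})
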