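test_that("mirrored profiles follow the homolog permutation and are involutive", {
  p <- tinyParc
  n <- nNodes(p)
  M <- randomSpd(n, seed = 1); M <- stats::cov2cor(M)
  dimnames(M) <- list(nodeNames(p), nodeNames(p))
  h <- homologMap(p)
  for (q in c(1, 3, 6)) {
    expect_equal(mirrorProfile(M, q, p), M[q, h], ignore_attr = TRUE)
    ## applying the mirror twice restores the original profile
    expect_equal(mirrorProfile(M, q, p)[h], M[q, ], ignore_attr = TRUE)
  }
  ## brute-force oracle with an explicit index swap
  q <- 2
  oracle <- vapply(seq_len(n), function(k) M[q, h[k]], numeric(1))
  expect_equal(mirrorProfile(M, q, p), oracle, ignore_attr = TRUE)
})

test_that("similarity map is symmetric with unit diagonal and honours mirror structure", {
  M <- truthMatrix(symTruth, 28)
  sim <- similarityMap(M, fullParc, tau = 0.1)
  expect_equal(sim, t(sim))
  expect_equal(diag(sim), rep(1, nNodes(fullParc)), ignore_attr = TRUE)
  expect_true(all(abs(sim) <= 1 + 1e-12))
  ## mirror-symmetric matrix: homolog similarity is maximal (= 1)
  h <- homologMap(fullParc)
  homologSims <- vapply(seq_len(39), function(q) sim[q, h[q]], numeric(1))
  expect_equal(homologSims, rep(1, 39), tolerance = 1e-8, ignore_attr = TRUE)
  ## and exceeds every non-homolog similarity
  others <- sim[1, setdiff(seq_len(78), c(1, h[1]))]
  expect_true(all(others < 1 - 1e-6))
  ## identical rows give similarity 1 in the plain (same-hemisphere) case
  p2 <- tinyParc
  M2 <- stats::cov2cor(randomSpd(nNodes(p2), seed = 2))
  M2[2, ] <- M2[1, ]; M2[, 2] <- M2[, 1]; diag(M2) <- 1
  sim2 <- similarityMap(M2, p2, tau = 0)
  expect_gt(sim2[1, 2], 0.999)
})

test_that("homolog similarities match the full map and decay with the planted asymmetry", {
  M <- truthMatrix(defaultTruth, 30)
  sim <- similarityMap(M, fullParc, tau = 0.1)
  fast <- homologSimilarities(M, fullParc, tau = 0.1)
  h <- homologMap(fullParc)
  expect_equal(unname(fast),
               vapply(seq_len(39), function(q) sim[q, h[q]], numeric(1)),
               tolerance = 1e-12)
  sims <- vapply(c(21, 27, 33, 39), function(g)
    mean(homologSimilarities(truthMatrix(defaultTruth, g), fullParc)),
    numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("homolog similarity test detects planted excess and is calibrated on exchangeable input", {
  p <- toyParcellation(8)
  n <- nNodes(p)
  h <- homologMap(p)
  ## deterministic construction: parcel 1's similarities to the 14
  ## non-homolog parcels have known mean and sd; its homolog similarity is
  ## planted exactly 3 sd above that mean, so t = 3 on 13 df
  sim <- matrix(0.2, n, n); diag(sim) <- 1
  others <- setdiff(seq_len(16), c(1, h[1]))
  vals <- rep(c(0.15, 0.25), length.out = length(others))
  sim[1, others] <- sim[others, 1] <- vals
  s3 <- stats::sd(vals)
  sim[1, h[1]] <- sim[h[1], 1] <- 0.2 + 3 * s3
  attr(sim, "degenerate") <- matrix(FALSE, n, n)  # already a similarity map
  out <- homologSimilarityTest(sim, p)
  expect_equal(out$t[1], 3, tolerance = 1e-12)
  expect_equal(out$p[1], stats::pt(3, df = 13, lower.tail = FALSE))
  expect_lt(out$p[1], 0.01)
  ## mirror-symmetric truth: maximal statistic everywhere
  M <- truthMatrix(symTruth, 28)
  outM <- homologSimilarityTest(similarityMap(M, fullParc, 0.1), fullParc)
  expect_true(all(outM$sHomolog >= outM$meanOthers))
  expect_true(all(outM$p < 0.01))
  ## exchangeable similarities: rejection near the nominal level
  rej <- vapply(1:60, function(s) {
    simN <- withSeed(4000 + s, {
      A <- matrix(rnorm(n * n, 0.2, 0.1), n)
      (A + t(A)) / 2
    })
    diag(simN) <- 1
    mean(homologSimilarityTest(simN, p)$p[1:8] < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(rej), 0.15)
})

test_that("laterality index follows its definition, sign convention and antisymmetry", {
  p <- fullParc
  M <- truthMatrix(symTruth, 28)
  ## mirror-symmetric matrix: LI exactly 0 for every region
  for (r in list("STG", "MTG", "ITG", c("STG", "MTG", "ITG")))
    expect_equal(lateralityIndex(M, p, r, tau = 0.1), 0)
  ## constructed Left = 3, Right = 1 -> LI = 0.5
  n <- nNodes(p)
  C <- diag(n); dimnames(C) <- list(nodeNames(p), nodeNames(p))
  iL <- regionIndices(p, "ITG", "L"); iR <- regionIndices(p, "ITG", "R")
  thal <- n
  C[iL, thal] <- C[thal, iL] <- 1       # weighted degree 3 via three edges
  C[iL, 1] <- C[1, iL] <- 1
  C[iL, 2] <- C[2, iL] <- 1
  C[iR, thal] <- C[thal, iR] <- 1       # degree 1
  expect_equal(lateralityIndex(C, p, "ITG", tau = 0.1), 0.5)
  ## right-heavy construction gives negative LI
  Crev <- swapHemispheres(C, p)
  expect_equal(lateralityIndex(Crev, p, "ITG", tau = 0.1), -0.5)
  ## antisymmetry on an arbitrary lateralized matrix
  ML <- truthMatrix(defaultTruth, 35)
  li <- lateralityIndex(ML, p, "ITG", tau = 0.1)
  expect_gt(abs(li), 0)
  expect_equal(lateralityIndex(swapHemispheres(ML, p), p, "ITG", 0.1), -li)
  ## empty degrees -> undefined, not zero
  Z <- diag(n); dimnames(Z) <- dimnames(C)
  expect_true(is.na(lateralityIndex(Z, p, "ITG", tau = 0.1)))
  expect_error(lateralityIndex(C, p, "NOPE", 0.1), "unknown parcel")
})

test_that("LI-age regression recovers the planted developmental slope", {
  co <- generateCohort(48, seed = 9)
  seeds <- childSeeds(9, 48)
  li <- vapply(seq_len(48), function(i)
    lateralityIndex(simulateFcMatrix(defaultTruth, co$ga_weeks[i],
                                     seed = seeds[i]),
                    fullParc, "ITG", tau = 0.1), numeric(1))
  reg <- liAgeRegression(li, co$ga_weeks)
  expect_lt(abs(reg$slope - 0.025), 0.01)
  expect_lt(reg$p, 0.05)
  ## constant LI -> slope 0
  regC <- suppressWarnings(
    liAgeRegression(rep(0.2, 20), seq(20, 39, length.out = 20)))
  expect_equal(regC$slope, 0)
  expect_error(liAgeRegression(c(NA, NA, 0.1, 0.2), c(20, 25, 30, 35)),
               "fewer than 3")
})

test_that("cohort laterality table reports the tau grid with FDR flags", {
  co <- generateCohort(24, seed = 13)
  seeds <- childSeeds(13, 24)
  fc <- lapply(seq_len(24), function(i)
    simulateFcMatrix(defaultTruth, co$ga_weeks[i], seed = seeds[i],
                     subjectId = co$subject_id[i]))
  suppressWarnings(tab <- cohortLaterality(
    fc, fullParc, regions = list(SuperiorTemporal = "STG",
                                 InferiorTemporal = "ITG"),
    ga = co$ga_weeks, tauGrid = c(0.05, 0.1)))
  expect_equal(nrow(tab), 4)    # 2 regions x 2 taus
  expect_setequal(unique(tab$tau), c(0.05, 0.1))
  expect_true(all(tab$q >= tab$p - 1e-15))
})
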