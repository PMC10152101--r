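test_that("sigmoid curve evaluation matches its closed form and limits", {
  b <- table1MogL
  expect_equal(sigmoidCurve(b["beta3"], b), b[["beta2"]] + b[["beta1"]] / 2,
               ignore_attr = TRUE)
  expect_equal(sigmoidCurve(29.3857, c(0.3587, -0.0133, 29.3857, 0.4614)),
               -0.0133 + 0.3587 / 2)
  expect_equal(sigmoidCurve(-1e6, b), b[["beta2"]], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sigmoidCurve(1e6, b), b[["beta1"]] + b[["beta2"]],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(sigmoidCurve(25, c(1, 0, 29, 0)), "beta4")
})

test_that("sigmoid fitting recovers noiseless parameters and flags degenerate regimes", {
  ga <- withSeed(2, runif(48, 19.7, 39.3))
  f <- fitSigmoid(ga, sigmoidCurve(ga, table1MogL))
  expect_lt(max(abs(f@beta - table1MogL)), 1e-4)
  expect_true(f@converged)
  expect_false(f@degenerate)
  expect_gt(f@adjR2, 0.999)
  ## fitted value at the inflection equals baseline + span/2
  expect_equal(sigmoidCurve(f@beta[3], f@beta),
               f@beta[[2]] + f@beta[[1]] / 2, tolerance = 1e-6,
               ignore_attr = TRUE)
  ## constant response: no signal
  fc <- fitSigmoid(ga, rep(0.3, 48))
  expect_lte(fc@adjR2, 0)
  ## exactly linear data: the fit escapes to large |beta4| and is flagged
  fl <- fitSigmoid(ga, 0.01 * ga)
  expect_true(fl@degenerate)
  expect_gt(abs(fl@beta[4]), diff(range(ga)))
  expect_error(fitSigmoid(ga[1:5], rnorm(5)), "at least 8")
  expect_error(fitSigmoid(rep(25, 10), rnorm(10)), "not all be equal")
})

test_that("linear fits agree with closed-form normal equations", {
  ga <- c(20, 24, 27, 31, 33, 38)
  y <- c(0.11, 0.15, 0.14, 0.22, 0.24, 0.29)
  lf <- fitLinear(ga, y)
  ## closed-form oracle
  slope <- sum((ga - mean(ga)) * (y - mean(y))) / sum((ga - mean(ga))^2)
  expect_equal(lf$slope, slope, tolerance = 1e-12)
  expect_equal(lf$intercept, mean(y) - slope * mean(ga), tolerance = 1e-12)
  exact <- suppressWarnings(fitLinear(ga, 2 * ga))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$adjR2, 1, tolerance = 1e-12)
  expect_error(fitLinear(ga[1:2], y[1:2]), "at least 3")
  ## null slope CI covers zero at ~95%
  cover <- vapply(1:200, function(s) {
    gaS <- withSeed(100 + s, runif(30, 19.7, 39.3))
    yS <- withSeed(300 + s, rnorm(30))
    ci <- fitLinear(gaS, yS)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  expect_lte(mean(cover), 0.99)
})

test_that("case bootstrap is seeded, tight when noiseless, and covers the truth", {
  ga <- withSeed(4, runif(48, 19.7, 39.3))
  y0 <- sigmoidCurve(ga, table1MogL)
  bp <- bootstrapParams(ga, y0, nBoot = 100, seed = 9)
  expect_lt(diff(bp$ci["beta3", ]), 0.1)
  bp2 <- bootstrapParams(ga, y0, nBoot = 100, seed = 9)
  expect_identical(bp$ci, bp2$ci)
  expect_error(bootstrapParams(ga, y0, nBoot = 50), "at least 100")
  expect_false(bp$flagged)
})

test_that("permutation goodness-of-fit test is exact for strong signal and bounded in (0,1]", {
  ga <- withSeed(5, runif(48, 19.7, 39.3))
  strong <- sigmoidCurve(ga, table1MogL) + withSeed(6, rnorm(48, sd = 0.05))
  pt <- permutationGofTest(ga, strong, nPerm = 199, seed = 7)
  expect_equal(pt$p, 1 / 200)
  expect_gt(pt$adjR2, 0.8)
  ## p always in (0, 1]
  ps <- vapply(1:25, function(s)
    permutationGofTest(ga, withSeed(800 + s, rnorm(48)), nPerm = 99,
                       seed = s)$p, numeric(1))
  expect_true(all(ps > 0 & ps <= 1))
  expect_error(permutationGofTest(ga, strong, nPerm = 50), "at least 99")
})

test_that("permutation p-values are uniform under the null", {
  ps <- vapply(1:400, function(s) {
    ga <- withSeed(9000 + s, runif(48, 19.7, 39.3))
    y <- withSeed(19000 + s, rnorm(48, sd = 0.2))
    permutationGofTest(ga, y, nPerm = 199, seed = 29000 + s)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Benjamini-Hochberg correction reproduces the step-up rule", {
  out <- fdrBH(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$q, stats::p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"))
  all10 <- fdrBH(rep(0.001, 10))
  expect_true(all(all10$reject))
  ## q monotone nondecreasing in sorted-p order
  p <- withSeed(10, runif(50))
  q <- fdrBH(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  empty <- fdrBH(numeric())
  expect_length(empty$q, 0)
  expect_error(fdrBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("homolog inflection equivalence testing behaves under TOST", {
  x <- withSeed(11, rnorm(500, mean = 29, sd = 0.5))
  same <- compareHomologInflections(x, x, margin = 1)
  expect_true(same$equivalent)
  shifted <- compareHomologInflections(x, x + 3, margin = 1)
  expect_false(shifted$equivalent)
  ## swapping sides flips nothing in the verdict
  swap <- compareHomologInflections(x + 3, x, margin = 1)
  expect_identical(shifted$equivalent, swap$equivalent)
  expect_equal(shifted$pEquiv, swap$pEquiv)
  expect_error(compareHomologInflections(x, x, margin = 0), "positive")
  expect_error(compareHomologInflections(numeric(), x, margin = 1),
               "nonempty")
  ## window equivalence: tight distribution inside the reference window
  win <- inflectionWindowTost(x, window = c(24, 32))
  expect_true(win$within)
  off <- inflectionWindowTost(x + 10, window = c(24, 32))
  expect_false(off$within)
})

test_that("one-way lobe ANOVA matches a hand-computed toy and degenerate groups error", {
  vals <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  grp <- rep(c("a", "b", "c"), each = 3)
  out <- lobeInflectionAnova(vals, grp)
  expect_equal(out$F, 3)                       # SSB/2 / (SSW/6) = 3/1
  expect_equal(out$df, c(2, 6))
  expect_equal(out$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  ident <- lobeInflectionAnova(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(ident$F, 0)
  huge <- lobeInflectionAnova(c(rnorm(5), rnorm(5) + 100),
                              rep(c("a", "b"), each = 5))
  expect_lt(huge$p, 1e-6)
  expect_error(lobeInflectionAnova(1:4, rep("a", 4)), "2 groups")
  expect_error(lobeInflectionAnova(1:3, c("a", "a", "b")), "at least 2 values")
})

test_that("information criteria prefer the generating model family", {
  ga <- withSeed(12, runif(48, 19.7, 39.3))
  sigWins <- vapply(1:30, function(s) {
    y <- sigmoidCurve(ga, table1MogL) + withSeed(1200 + s, rnorm(48, sd = 0.1))
    fitSigmoid(ga, y)@aic < fitLinear(ga, y)$aic
  }, logical(1))
  expect_gte(mean(sigWins), 0.9)
  ## On linear truth the two extra sigmoid parameters buy a chi-square(2)
  ## improvement, which beats AIC's penalty of 4 in about a quarter of
  ## datasets by construction; BIC's log(n) penalty makes the family choice
  ## reliable, so BIC carries the strict bound and AIC the majority bound.
  linN <- 30
  aicLin <- bicLin <- logical(linN)
  for (s in seq_len(linN)) {
    y <- 0.01 * ga + withSeed(1300 + s, rnorm(48, sd = 0.1))
    f <- fitSigmoid(ga, y); l <- fitLinear(ga, y)
    aicLin[s] <- f@aic > l$aic
    bicLin[s] <- f@bic > l$aic - 2 * 3 + log(48) * 3   # BIC of the lm
  }
  expect_gte(mean(bicLin), 0.9)
  expect_gte(mean(aicLin), 0.6)
})
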