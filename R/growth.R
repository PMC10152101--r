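#' Sigmoid developmental trajectory
#'
#' Evaluates
#' \code{f(t) = beta1 / (1 + exp(-(t - beta3)/beta4)) + beta2}:
#' \code{beta2} is the initial plateau, \code{beta1} the span to the final
#' plateau \code{beta1 + beta2}, \code{beta3} the inflection week (where the
#' derivative peaks and the curve equals \code{beta2 + beta1/2}), and
#' \code{beta4} the growth-rate scale in weeks.
#'
#' @param t gestational age(s), decimal weeks.
#' @param beta numeric vector \code{c(beta1, beta2, beta3, beta4)} (named or
#'   positional).
#' @return numeric vector of trajectory values.
#' @examples
#' sigmoidCurve(29.3857, c(0.3587, -0.0133, 29.3857, 0.4614))
#' @export
sigmoidCurve <- function(t, beta) {
  beta <- .betaVec(beta)
  if (beta[4] == 0) stop("beta4 must be nonzero")
  beta[2] + beta[1] / (1 + exp(-(t - beta[3]) / beta[4]))
}

.betaVec <- function(beta) {
  stopifnot(length(beta) == 4)
  if (!is.null(names(beta)) && all(c("beta1", "beta2", "beta3", "beta4")
                                   %in% names(beta)))
    beta <- beta[c("beta1", "beta2", "beta3", "beta4")]
  as.numeric(beta)
}

## ---- variable-projection grid machinery -------------------------------
## For fixed (beta3, beta4) the model is linear in (beta1, beta2):
## y = beta2 + beta1 * s(t), s = logistic((t - beta3)/beta4). The grid
## profiles (beta1, beta2) out by closed-form simple regression, giving a
## cheap global multi-start whose best cell seeds the nonlinear polish.

.gridCells <- function(ga) {
  b3 <- seq(min(ga), max(ga), length.out = 9)
  b4 <- c(0.25, 0.5, 1, 2, 4, 8, 32, 128)
  expand.grid(b3 = b3, b4 = c(b4, -b4))
}

.gridS <- function(ga, cells) {
  S <- matrix(0, length(ga), nrow(cells))
  for (c in seq_len(nrow(cells)))
    S[, c] <- 1 / (1 + exp(-(ga - cells$b3[c]) / cells$b4[c]))
  S
}

## Best profile fit over the grid for one response vector.
.gridFit <- function(ga, y, cells = .gridCells(ga), S = .gridS(ga, cells)) {
  n <- length(y)
  sx <- colSums(S); sxx <- colSums(S * S)
  sy <- sum(y); syy <- sum(y * y)
  sxy <- as.numeric(crossprod(S, y))
  den <- n * sxx - sx^2
  ok <- den > 1e-10
  slope <- ifelse(ok, (n * sxy - sx * sy) / den, 0)
  icept <- (sy - slope * sx) / n
  rss <- syy - icept * sy - slope * sxy
  rss[!is.finite(rss)] <- Inf
  ord <- order(rss)
  list(order = ord, rss = rss, slope = slope, intercept = icept,
       cells = cells)
}

.polishNls <- function(ga, y, start, b3Bounds) {
  lower <- c(-Inf, -Inf, b3Bounds[1], if (start[4] > 0) 1e-3 else -Inf)
  upper <- c(Inf, Inf, b3Bounds[2], if (start[4] > 0) Inf else -1e-3)
  df <- data.frame(ga = ga, y = y)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ b2 + b1 / (1 + exp(-(ga - b3) / b4)), data = df,
    start = list(b1 = start[1], b2 = start[2], b3 = start[3], b4 = start[4]),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  cf <- stats::coef(fit)
  list(beta = c(beta1 = unname(cf["b1"]), beta2 = unname(cf["b2"]),
                beta3 = unname(cf["b3"]), beta4 = unname(cf["b4"])),
       rss = sum(stats::resid(fit)^2))
}

#' Fit the sigmoid developmental model
#'
#' Nonlinear least squares with a global multi-start: the inflection and
#' growth-rate parameters are searched on a grid over the observed age range
#' (both signs of the rate, spanning fast transitions to near-linear
#' regimes), the two linear parameters are profiled out in closed form, and
#' the best grid cells seed a Levenberg-Marquardt polish with the inflection
#' bounded to the observed age range plus/minus 5 weeks. Fits whose
#' growth-rate scale exceeds the observed age span are flagged degenerate
#' (near-linear data produce such fits; they are kept, not discarded).
#'
#' @param ga gestational ages (decimal weeks).
#' @param y response (edge connectivity values).
#' @param polish run the nonlinear polish (default \code{TRUE}; grid-only
#'   fits are used inside permutation loops for exchangeability and speed).
#' @param nPolish number of best grid cells to polish from (default 3).
#' @return a \code{\linkS4class{SigmoidFit}}.
#' @export
fitSigmoid <- function(ga, y, polish = TRUE, nPolish = 3) {
  stopifnot(length(ga) == length(y))
  n <- length(y)
  if (n < 8) stop("at least 8 observations required")
  if (stats::sd(ga) < 1e-12) stop("gestational ages must not all be equal")
  gf <- .gridFit(ga, y)
  best <- gf$order[1]
  beta <- c(beta1 = gf$slope[best], beta2 = gf$intercept[best],
            beta3 = gf$cells$b3[best], beta4 = gf$cells$b4[best])
  rss <- gf$rss[best]
  converged <- !polish
  if (polish) {
    b3Bounds <- c(min(ga) - 5, max(ga) + 5)
    for (c in gf$order[seq_len(min(nPolish, length(gf$order)))]) {
      start <- c(gf$slope[c], gf$intercept[c], gf$cells$b3[c], gf$cells$b4[c])
      pol <- .polishNls(ga, y, start, b3Bounds)
      if (!is.null(pol) && pol$rss <= rss + 1e-12) {
        if (pol$rss < rss) { beta <- pol$beta; rss <- pol$rss }
        converged <- TRUE
      }
    }
  }
  .makeSigmoidFit(beta, rss, n, ga, converged,
                  tss = sum((y - mean(y))^2))
}

.makeSigmoidFit <- function(beta, rss, n, ga, converged, y = NULL,
                            tss = NULL) {
  if (is.null(tss)) stop("internal: tss required")
  rss <- max(rss, 0)
  k <- 5  # 4 mean parameters + error variance
  rssA <- max(rss, 1e-300)
  aic <- n * log(2 * pi * rssA / n) + n + 2 * k
  bic <- n * log(2 * pi * rssA / n) + n + log(n) * k
  new("SigmoidFit",
      beta = stats::setNames(as.numeric(beta), paste0("beta", 1:4)),
      adjR2 = adjustedR2(rss, tss, n, 4),
      aic = aic, bic = bic, rss = rss,
      converged = converged,
      degenerate = abs(beta[[4]]) > diff(range(ga)),
      nObs = as.integer(n))
}

#' @rdname fitLinear
#' @export
adjustedR2 <- function(rss, tss, n, p) {
  if (tss < 1e-24) return(0)
  1 - (rss / (n - p)) / (tss / (n - 1))
}

#' Ordinary least-squares developmental model
#'
#' Linear counterpart of \code{\link{fitSigmoid}}: OLS of connectivity on
#' gestational age with the usual t-based slope inference.
#'
#' @param ga gestational ages.
#' @param y response.
#' @return list with \code{slope}, \code{intercept}, \code{se} (slope
#'   standard error), \code{p} (two-sided slope p-value), \code{adjR2},
#'   \code{aic}, \code{ci} (95\% slope CI).
#' @export
fitLinear <- function(ga, y) {
  if (length(y) < 3) stop("at least 3 observations required")
  fit <- stats::lm(y ~ ga)
  s <- summary(fit)
  ci <- stats::confint(fit)["ga", ]
  list(slope = unname(stats::coef(fit)["ga"]),
       intercept = unname(stats::coef(fit)[1]),
       se = s$coefficients["ga", "Std. Error"],
       p = s$coefficients["ga", "Pr(>|t|)"],
       adjR2 = s$adj.r.squared,
       aic = stats::AIC(fit),
       ci = unname(ci))
}

#' Bootstrap confidence intervals for the sigmoid parameters
#'
#' Case-resampling bootstrap: subjects are resampled with replacement,
#' the sigmoid is refitted to each replicate, and percentile 95\%
#' confidence intervals are formed per parameter. Non-converged replicates
#' are dropped and counted; the result is flagged when more than half fail.
#'
#' @param ga,y data as in \code{\link{fitSigmoid}}.
#' @param nBoot bootstrap replicates (default 1000, minimum 100).
#' @param seed integer seed.
#' @param polish polish each replicate fit (default \code{TRUE}).
#' @return list with \code{ci} (4 x 2 matrix), \code{samples}
#'   (replicates x 4), \code{nNonConverged}, \code{flagged}, \code{fit}
#'   (the full-data \code{\linkS4class{SigmoidFit}}).
#' @export
bootstrapParams <- function(ga, y, nBoot = 1000, seed = 1, polish = TRUE) {
  if (nBoot < 100) stop("nBoot must be at least 100")
  n <- length(y)
  fit <- fitSigmoid(ga, y, polish = polish)
  cells <- .gridCells(ga)
  S <- .gridS(ga, cells)
  b3Bounds <- c(min(ga) - 5, max(ga) + 5)
  samples <- matrix(NA_real_, nBoot, 4,
                    dimnames = list(NULL, paste0("beta", 1:4)))
  idxMat <- withSeed(seed, matrix(sample.int(n, n * nBoot, replace = TRUE),
                                  n, nBoot))
  for (b in seq_len(nBoot)) {
    idx <- idxMat[, b]
    gf <- .gridFit(ga[idx], y[idx], cells = cells,
                   S = S[idx, , drop = FALSE])
    best <- gf$order[1]
    beta <- c(gf$slope[best], gf$intercept[best],
              cells$b3[best], cells$b4[best])
    okFit <- !polish
    if (polish) {
      pol <- .polishNls(ga[idx], y[idx], beta, b3Bounds)
      if (!is.null(pol)) { beta <- unname(pol$beta); okFit <- TRUE }
    }
    if (okFit) samples[b, ] <- beta
  }
  keep <- stats::complete.cases(samples)
  nBad <- sum(!keep)
  ci <- t(apply(samples[keep, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975)))
  list(ci = ci, samples = samples[keep, , drop = FALSE],
       nNonConverged = nBad, flagged = nBad > nBoot / 2, fit = fit)
}

#' Permutation test of the sigmoid goodness of fit
#'
#' Tests whether the sigmoid model explains the developmental trajectory:
#' the response is permuted against age, the model refitted, and the
#' adjusted R-squared compared with the observed one. Observed and permuted
#' statistics both use the variable-projection grid fitter, keeping the test
#' exchangeable. The add-one estimator
#' \code{p = (1 + #\{perm >= obs\}) / (nPerm + 1)} keeps p in (0, 1].
#'
#' @param ga,y data.
#' @param nPerm permutations (default 999, minimum 99).
#' @param seed integer seed.
#' @return list with \code{p}, \code{adjR2} (observed, grid fit),
#'   \code{nPerm}.
#' @export
permutationGofTest <- function(ga, y, nPerm = 999, seed = 1) {
  if (nPerm < 99) stop("nPerm must be at least 99")
  n <- length(y)
  cells <- .gridCells(ga)
  S <- .gridS(ga, cells)
  Y <- withSeed(seed, {
    P <- matrix(0, n, nPerm)
    for (j in seq_len(nPerm)) P[, j] <- y[sample.int(n)]
    cbind(y, P)
  })
  sy <- sum(y); syy <- sum(y * y)
  bestRss <- rep(Inf, ncol(Y))
  for (c in seq_len(nrow(cells))) {
    s <- S[, c]
    sx <- sum(s); sxx <- sum(s * s)
    den <- n * sxx - sx^2
    sxy <- as.numeric(crossprod(Y, s))
    if (den > 1e-10) {
      slope <- (n * sxy - sx * sy) / den
      icept <- (sy - slope * sx) / n
      rss <- syy - icept * sy - slope * sxy
    } else {
      rss <- rep(syy - sy^2 / n, ncol(Y))
    }
    bestRss <- pmin(bestRss, rss)
  }
  tss <- syy - sy^2 / n
  adj <- vapply(bestRss, adjustedR2, numeric(1), tss = tss, n = n, p = 4)
  p <- (1 + sum(adj[-1] >= adj[1])) / (nPerm + 1)
  list(p = p, adjR2 = adj[1], nPerm = nPerm)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' @param pvals p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with \code{q} (BH-adjusted values) and \code{reject}
#'   (logical).
#' @export
fdrBH <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) return(list(q = numeric(), reject = logical()))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

## Welch two-sample summary used by the equivalence machinery.
.welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  se <- sqrt(v1 / n1 + v2 / n2)
  df <- if (se > 0) se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        else n1 + n2 - 2
  list(diff = mean(a) - mean(b), se = se, df = df)
}

#' Equivalence test of homolog inflection times
#'
#' Two-one-sided-tests (TOST) equivalence of the bootstrap distributions of
#' the inflection week for a left/right homolog pair, with a declared
#' equivalence margin; the raw Welch t statistic is also reported because
#' the plain difference test answers a different question than equivalence.
#'
#' @param bootLeft,bootRight bootstrap samples of beta3 (weeks).
#' @param margin equivalence margin in weeks (> 0).
#' @param alpha test level (default 0.05).
#' @return list with \code{equivalent} (logical), \code{pEquiv},
#'   \code{tRaw}, \code{pRaw}, \code{diff}, \code{margin}.
#' @export
compareHomologInflections <- function(bootLeft, bootRight, margin,
                                      alpha = 0.05) {
  if (!length(bootLeft) || !length(bootRight))
    stop("bootstrap samples must be nonempty")
  if (!is.finite(margin) || margin <= 0) stop("margin must be positive")
  w <- .welch(bootLeft, bootRight)
  if (!is.finite(w$se) || w$se < 1e-12) {
    inside <- abs(w$diff) < margin
    return(list(equivalent = inside, pEquiv = if (inside) 0 else 1,
                tRaw = if (abs(w$diff) < 1e-12) 0 else sign(w$diff) * Inf,
                pRaw = if (abs(w$diff) < 1e-12) 1 else 0,
                diff = w$diff, margin = margin))
  }
  pLower <- stats::pt((w$diff + margin) / w$se, w$df, lower.tail = FALSE)
  pUpper <- stats::pt((w$diff - margin) / w$se, w$df)
  pEquiv <- max(pLower, pUpper)
  tRaw <- w$diff / w$se
  list(equivalent = pEquiv < alpha, pEquiv = pEquiv,
       tRaw = tRaw, pRaw = 2 * stats::pt(-abs(tRaw), w$df),
       diff = w$diff, margin = margin)
}

#' Equivalence of an inflection-time distribution with a reference window
#'
#' One-sample TOST of the bootstrap distribution of the inflection week
#' against a reference gestational window (default 24-32 weeks, the
#' period of thalamocortical afferent invasion of the cortical plate).
#'
#' @param boot3 bootstrap sample of beta3 (weeks).
#' @param window two-element numeric window (weeks).
#' @param alpha test level.
#' @return list with \code{within} (logical), \code{p}, \code{mean}.
#' @export
inflectionWindowTost <- function(boot3, window = c(24, 32), alpha = 0.05) {
  stopifnot(length(window) == 2, window[1] < window[2])
  n <- length(boot3)
  m <- mean(boot3)
  se <- stats::sd(boot3) / sqrt(n)
  if (!is.finite(se) || se < 1e-12) {
    inside <- m > window[1] && m < window[2]
    return(list(within = inside, p = if (inside) 0 else 1, mean = m))
  }
  pLow <- stats::pt((m - window[1]) / se, n - 1, lower.tail = FALSE)
  pHigh <- stats::pt((m - window[2]) / se, n - 1)
  p <- max(pLow, pHigh)
  list(within = p < alpha, p = p, mean = m)
}

#' One-way ANOVA of inflection times across lobes
#'
#' @param values inflection times (weeks).
#' @param groups lobe labels, same length.
#' @return list with \code{F}, \code{p}, \code{df} (numerator, denominator).
#' @export
lobeInflectionAnova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least 2 groups required")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  s <- summary(stats::aov(values ~ g))[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = c(s[["Df"]][1], s[["Df"]][2]))
}

setMethod("show", "SigmoidFit", function(object) {
  b <- object@beta
  cat(sprintf("SigmoidFit: beta1=%.4g beta2=%.4g beta3=%.4g beta4=%.4g\n",
              b[1], b[2], b[3], b[4]))
  cat(sprintf("  adjR2=%.3f AIC=%.2f BIC=%.2f n=%d%s%s\n",
              object@adjR2, object@aic, object@bic, object@nObs,
              if (!object@converged) " [not converged]" else "",
              if (object@degenerate) " [degenerate |beta4|]" else ""))
})
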