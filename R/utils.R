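#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates \code{expr}, and restores the caller's RNG
#' state on exit, so seeded helpers do not disturb global random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive per-unit child seeds from a master seed
#'
#' Deterministically expands one master seed into \code{n} independent child
#' seeds (one per subject, replicate, ...), all below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}.
#' @export
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Parse gestational age notation
#'
#' Converts clinical "W+D" gestational-age strings (weeks + days) to decimal
#' weeks; plain numeric strings pass through unchanged.
#'
#' @param x character or numeric vector; e.g. \code{"19+5"} -> 19 + 5/7.
#' @return numeric vector of decimal weeks.
#' @examples
#' parseGestationalAge(c("19+5", "39+2", "28"))
#' @export
parseGestationalAge <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- trimws(x[i])
    if (grepl("+", s, fixed = TRUE)) {
      parts <- strsplit(s, "+", fixed = TRUE)[[1]]
      if (length(parts) != 2L || anyNA(suppressWarnings(as.numeric(parts))))
        stop("cannot parse gestational age '", s, "'")
      wd <- as.numeric(parts)
      if (wd[2] < 0 || wd[2] >= 7)
        stop("days component out of range in '", s, "'")
      out[i] <- wd[1] + wd[2] / 7
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("cannot parse gestational age '", s, "'")
      out[i] <- v
    }
  }
  out
}

## ---- symmetric / SPD matrix helpers (eigen based) ----

stopifnotSymmetric <- function(M, tol = 1e-8, label = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(label, " must be a square matrix")
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(label, " is not symmetric")
  invisible(TRUE)
}

spdFun <- function(M, f) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

#' @rdname spdGeometricMean
#' @export
spdSqrt <- function(M) spdFun(M, function(v) sqrt(pmax(v, 0)))

#' @rdname spdGeometricMean
#' @export
spdLog <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("matrix logarithm requires a positive-definite matrix")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

spdExp <- function(M) spdFun(M, exp)

spdInvSqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("inverse square root requires a positive-definite matrix")
  e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
}

## Project a symmetric matrix onto the correlation-matrix cone:
## clip negative eigenvalues, then renormalize to unit diagonal.
nearestCorrelation <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= 0) {
    diag(M) <- 1
    return(M)
  }
  C <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  d <- diag(C)
  d[d <= 0] <- 1
  C <- C / sqrt(outer(d, d))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

## Pearson correlation that returns 0 (with attribute) for zero-variance input.
safeCor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0)
    return(structure(0, degenerate = TRUE))
  structure(stats::cor(x, y), degenerate = FALSE)
}

fmtNum <- function(x) sprintf("%.15g", x)
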