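.asMat <- function(M) if (is(M, "ConnectivityMatrix")) M@mat else M

## Threshold a connectivity matrix for profile/degree work: entries strictly
## below tau (including all negative connections) are zeroed.
thresholdFc <- function(M, tau = 0.1) {
  M <- .asMat(M)
  M[M < tau] <- 0
  M
}

#' Mirrored connectivity profile
#'
#' Row \code{p} of a connectivity matrix with the entries re-indexed by the
#' homolog permutation (thalamus nodes map to themselves), so the profile of
#' a parcel can be compared entry-wise with the profile of its contralateral
#' twin. Applying the mirror twice returns the original profile.
#'
#' @param M a \code{\linkS4class{ConnectivityMatrix}} or plain matrix.
#' @param p parcel index.
#' @param parcellation a \code{\linkS4class{Parcellation}}.
#' @return numeric profile vector of length n.
#' @export
mirrorProfile <- function(M, p, parcellation) {
  M <- .asMat(M)
  h <- homologMap(parcellation)
  stopifnot(nrow(M) == length(h), p >= 1, p <= nrow(M))
  M[p, h]
}

## Correlation between the profiles of p and q with self/twin entries
## excluded; when the parcels lie in opposite hemispheres, q's profile is
## mirrored so homotopic entries line up.
.profileSimilarity <- function(Mt, p, q, h, hemi) {
  n <- nrow(Mt)
  drop <- unique(c(p, h[p], q, h[q]))
  idx <- setdiff(seq_len(n), drop)
  a <- Mt[p, idx]
  b <- if (hemi[p] != hemi[q] && hemi[p] != "M" && hemi[q] != "M")
    Mt[q, h[idx]] else Mt[q, idx]
  safeCor(a, b)
}

#' Similarity map of connectivity profiles
#'
#' Entry (p, q) is the Pearson correlation between the thresholded
#' connectivity profiles of parcels p and q, computed on the mirrored
#' profile when the two parcels lie in opposite hemispheres so homotopic
#' edges are compared with each other. The entries at the two parcels and
#' their homologs are excluded from every comparison (self/twin exclusion).
#' Zero-variance profiles give similarity 0 and are flagged.
#'
#' @param M a \code{\linkS4class{ConnectivityMatrix}} or plain matrix.
#' @param parcellation a \code{\linkS4class{Parcellation}}.
#' @param tau profile threshold (default 0.1); negative and weak connections
#'   are zeroed before correlating.
#' @return symmetric matrix with unit diagonal and attribute
#'   \code{"degenerate"} (logical matrix).
#' @export
similarityMap <- function(M, parcellation, tau = 0.1) {
  Mt <- thresholdFc(M, tau)
  n <- nrow(Mt)
  if (n < 3) stop("at least 3 parcels required")
  h <- homologMap(parcellation)
  stopifnot(n == length(h))
  hemi <- c(hemisphereOf(parcellation),
            rep("M", n - nParcels(parcellation)))
  S <- diag(n)
  deg <- matrix(FALSE, n, n)
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    s <- .profileSimilarity(Mt, p, q, h, hemi)
    S[p, q] <- S[q, p] <- as.numeric(s)
    deg[p, q] <- deg[q, p] <- attr(s, "degenerate")
  }
  dimnames(S) <- dimnames(Mt)
  attr(S, "degenerate") <- deg
  S
}

#' Homolog profile similarities
#'
#' Fast path computing only the mirrored-profile similarity of each homolog
#' pair (one value per left parcel), as used in cohort-scale age-trend
#' analyses.
#'
#' @inheritParams similarityMap
#' @return named numeric vector over left-hemisphere parcels.
#' @export
homologSimilarities <- function(M, parcellation, tau = 0.1) {
  Mt <- thresholdFc(M, tau)
  h <- homologMap(parcellation)
  hemi <- c(hemisphereOf(parcellation),
            rep("M", nrow(Mt) - nParcels(parcellation)))
  left <- which(hemisphereOf(parcellation) == "L")
  out <- vapply(left, function(p)
    as.numeric(.profileSimilarity(Mt, p, h[p], h, hemi)), numeric(1))
  names(out) <- parcelNames(parcellation)[left]
  out
}

#' Test homolog similarity against similarity to all other parcels
#'
#' For every cortical parcel, a one-sided one-sample test of whether its
#' similarity to its contralateral homolog exceeds the distribution of its
#' similarities to all non-homolog parcels:
#' \code{t = (s_homolog - mean(s_others)) / sd(s_others)} referred to a t
#' distribution on \code{n_others - 1} degrees of freedom.
#'
#' @param sim similarity map from \code{\link{similarityMap}} (or a
#'   \code{ConnectivityMatrix}/matrix, in which case the map is computed).
#' @param parcellation a \code{\linkS4class{Parcellation}}.
#' @param tau threshold used if the map must be computed.
#' @return data.frame per cortical parcel: \code{parcel}, \code{sHomolog},
#'   \code{meanOthers}, \code{sdOthers}, \code{t}, \code{p},
#'   \code{degenerate}.
#' @export
homologSimilarityTest <- function(sim, parcellation, tau = 0.1) {
  if (is(sim, "ConnectivityMatrix") || is.null(attr(sim, "degenerate")))
    sim <- similarityMap(sim, parcellation, tau)
  n <- nParcels(parcellation)
  h <- homologMap(parcellation)
  res <- lapply(seq_len(n), function(p) {
    others <- setdiff(seq_len(n), c(p, h[p]))
    if (length(others) < 10)
      stop("at least 10 non-homolog comparison parcels required")
    sO <- sim[p, others]
    sH <- sim[p, h[p]]
    sdO <- stats::sd(sO)
    if (!is.finite(sdO) || sdO < 1e-12)
      return(data.frame(parcel = parcelNames(parcellation)[p],
                        sHomolog = sH, meanOthers = mean(sO),
                        sdOthers = sdO, t = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    tv <- (sH - mean(sO)) / sdO
    data.frame(parcel = parcelNames(parcellation)[p], sHomolog = sH,
               meanOthers = mean(sO), sdOthers = sdO, t = tv,
               p = stats::pt(tv, df = length(others) - 1,
                             lower.tail = FALSE),
               degenerate = FALSE)
  })
  do.call(rbind, res)
}

#' Age trend of homolog similarity
#'
#' OLS regression of a per-subject homolog-similarity statistic (e.g. the
#' mean mirrored-profile similarity over homolog pairs) on gestational age.
#'
#' @param statistic per-subject values.
#' @param ga gestational ages.
#' @return list as in \code{\link{fitLinear}}.
#' @export
similarityAgeTrend <- function(statistic, ga) {
  if (length(statistic) < 10) stop("at least 10 subjects required")
  fitLinear(ga, statistic)
}

#' Laterality index of a region
#'
#' \code{LI = (Left - Right) / (Left + Right)} on thresholded nodal degrees
#' summed over the region's left and right parcels. Positive LI means
#' left-hemispheric dominance, negative right-hemispheric dominance. When
#' both degree sums are zero the index is undefined and \code{NA} is
#' returned (flagged, not 0).
#'
#' @param M a \code{\linkS4class{ConnectivityMatrix}} or plain matrix.
#' @param parcellation a \code{\linkS4class{Parcellation}}.
#' @param region character vector of base region names (no hemisphere
#'   suffix), e.g. \code{"ITG"} or \code{c("STG", "TPOsup")}.
#' @param tau degree threshold (default 0.1).
#' @param binary binary degrees instead of weighted (default \code{FALSE}).
#' @return scalar LI in [-1, 1] or \code{NA} if undefined.
#' @export
lateralityIndex <- function(M, parcellation, region, tau = 0.1,
                            binary = FALSE) {
  li <- regionIndices(parcellation, region, "L")
  ri <- regionIndices(parcellation, region, "R")
  deg <- thresholdedDegree(.asMat(M), tau = tau, binary = binary)
  L <- sum(deg[li]); R <- sum(deg[ri])
  if (L + R == 0) return(NA_real_)
  (L - R) / (L + R)
}

#' Development of the laterality index with age
#'
#' OLS of per-subject LI on gestational age; subjects with undefined LI are
#' dropped and counted.
#'
#' @param li per-subject laterality indices (may contain \code{NA}).
#' @param ga gestational ages, same length.
#' @return list as in \code{\link{fitLinear}} plus \code{nDropped}.
#' @export
liAgeRegression <- function(li, ga) {
  stopifnot(length(li) == length(ga))
  ok <- !is.na(li)
  if (sum(ok) < 3) stop("fewer than 3 defined laterality values")
  if (sum(ok) < 10)
    warning("fewer than 10 subjects with defined LI")
  out <- fitLinear(ga[ok], li[ok])
  out$nDropped <- sum(!ok)
  out
}

#' Cohort-level laterality analysis
#'
#' Per-subject laterality indices for a set of regions across a threshold
#' grid, cohort-mean one-sample t-tests against zero (two-sided, BH
#' corrected across regions), and the LI-age regression per region.
#'
#' @param fcList list of \code{\linkS4class{ConnectivityMatrix}}.
#' @param parcellation a \code{\linkS4class{Parcellation}}.
#' @param regions named list of base-name vectors, e.g.
#'   \code{list(SuperiorTemporal = "STG")}.
#' @param ga gestational ages (taken from the matrices when omitted).
#' @param tauGrid thresholds to report across (default
#'   \code{c(0.05, 0.1, 0.2)}).
#' @param alpha FDR level.
#' @return data.frame with one row per region x tau: mean LI, t, p, q,
#'   significant flag, age slope, slope p, subjects used.
#' @export
cohortLaterality <- function(fcList, parcellation, regions, ga = NULL,
                             tauGrid = c(0.05, 0.1, 0.2), alpha = 0.05) {
  if (is.null(ga))
    ga <- vapply(fcList, function(m) m@gaWeeks, numeric(1))
  rows <- list()
  for (tau in tauGrid) {
    li <- vapply(names(regions), function(rn)
      vapply(fcList, lateralityIndex, numeric(1), parcellation,
             regions[[rn]], tau),
      numeric(length(fcList)))
    stats <- lapply(names(regions), function(rn) {
      v <- li[, rn]
      ok <- !is.na(v)
      tt <- stats::t.test(v[ok])
      reg <- liAgeRegression(v, ga)
      data.frame(region = rn, tau = tau, n = sum(ok),
                 meanLI = mean(v[ok]), t = unname(tt$statistic),
                 p = tt$p.value, slope = reg$slope, slopeSe = reg$se,
                 slopeP = reg$p, adjR2 = reg$adjR2,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, stats)
    bh <- fdrBH(tab$p, alpha)
    tab$q <- bh$q
    tab$significant <- bh$reject
    rows[[length(rows) + 1]] <- tab
  }
  do.call(rbind, rows)
}
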