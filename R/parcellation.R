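## 39 cortical regions per hemisphere, grouped into the six classical lobes.
## Abbreviations follow common automated-anatomical-labelling usage.
.fetalRegions <- list(
  frontal  = c("PreCG", "SFGdor", "SFGmed", "MFG", "IFGoperc", "IFGtriang",
               "ORBsup", "ORBmid", "ORBinf", "ROL", "SMA", "OLF", "REC"),
  parietal = c("PoCG", "SPG", "IPL", "SMG", "ANG", "PCUN", "PCL"),
  temporal = c("HES", "STG", "TPOsup", "MTG", "TPOmid", "ITG", "FFG"),
  occipital = c("CAL", "CUN", "LING", "SOG", "MOG", "IOG"),
  insular  = "INS",
  limbic   = c("ACG", "MCG", "PCG", "PHG", "HIP")
)

#' Default fetal parcellation
#'
#' Builds the 78-parcel cortical parcellation (39 regions per hemisphere in
#' left/right homolog pairs, assigned to the six classical lobes), optionally
#' followed by a single thalamus node. Parcels are ordered all-left then
#' all-right, so the homolog permutation maps index \code{i} to \code{i +- 39}.
#'
#' @param thalamus logical; append a \code{"THA"} node after the cortical
#'   parcels (default \code{TRUE}).
#' @return a \code{\linkS4class{Parcellation}}.
#' @examples
#' p <- defaultParcellation()
#' nParcels(p)   # 78 cortical parcels
#' nNodes(p)     # 79 with the thalamus node
#' @export
defaultParcellation <- function(thalamus = TRUE) {
  base <- unlist(.fetalRegions, use.names = FALSE)
  lobe <- rep(names(.fetalRegions), lengths(.fetalRegions))
  nh <- length(base)
  new("Parcellation",
      parcels = c(paste0(base, ".L"), paste0(base, ".R")),
      hemisphere = rep(c("L", "R"), each = nh),
      lobe = rep(lobe, 2),
      homolog = as.integer(c(seq_len(nh) + nh, seq_len(nh))),
      thalamus = if (thalamus) "THA" else character())
}

## Small parcellation for examples/tests: nPerHemi regions, one lobe cycle.
#' @rdname defaultParcellation
#' @param nPerHemi number of regions per hemisphere for the reduced
#'   parcellation used in examples and tests.
#' @export
toyParcellation <- function(nPerHemi = 4, thalamus = TRUE) {
  stopifnot(nPerHemi >= 2)
  base <- sprintf("P%02d", seq_len(nPerHemi))
  lobe <- rep_len(c("frontal", "temporal", "parietal", "occipital"), nPerHemi)
  new("Parcellation",
      parcels = c(paste0(base, ".L"), paste0(base, ".R")),
      hemisphere = rep(c("L", "R"), each = nPerHemi),
      lobe = rep(lobe, 2),
      homolog = as.integer(c(seq_len(nPerHemi) + nPerHemi,
                             seq_len(nPerHemi))),
      thalamus = if (thalamus) "THA" else character())
}

#' Parcellation accessors
#'
#' @param x a \code{\linkS4class{Parcellation}}.
#' @return \code{parcelNames}: cortical parcel names; \code{nodeNames}:
#'   cortical parcels plus thalamus nodes; \code{nParcels}/\code{nNodes}:
#'   counts; \code{homologMap}: involution over all nodes (thalamus nodes map
#'   to themselves); \code{hemisphereOf}/\code{lobeOf}: per-parcel labels.
#' @export
parcelNames <- function(x) x@parcels

#' @rdname parcelNames
#' @export
nodeNames <- function(x) c(x@parcels, x@thalamus)

#' @rdname parcelNames
#' @export
nParcels <- function(x) length(x@parcels)

#' @rdname parcelNames
#' @export
nNodes <- function(x) length(x@parcels) + length(x@thalamus)

#' @rdname parcelNames
#' @export
homologMap <- function(x) {
  n <- nParcels(x)
  c(x@homolog, seq_len(nNodes(x) - n) + n)
}

#' @rdname parcelNames
#' @export
hemisphereOf <- function(x) x@hemisphere

#' @rdname parcelNames
#' @export
lobeOf <- function(x) x@lobe

#' Indices of parcels by base region name
#'
#' @param x a \code{\linkS4class{Parcellation}}.
#' @param region character vector of base region names (no \code{.L}/\code{.R}
#'   suffix), e.g. \code{c("STG", "MTG")}.
#' @param hemisphere \code{"L"} or \code{"R"}.
#' @return integer parcel indices.
#' @export
regionIndices <- function(x, region, hemisphere) {
  wanted <- paste0(region, ".", hemisphere)
  idx <- match(wanted, x@parcels)
  if (anyNA(idx))
    stop("unknown parcel(s): ", paste(wanted[is.na(idx)], collapse = ", "))
  idx
}

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation:", nParcels(object), "cortical parcels (",
      sum(object@hemisphere == "L"), "per hemisphere )\n")
  tab <- table(object@lobe[object@hemisphere == "L"])
  cat("  lobes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(object@thalamus))
    cat("  thalamus node(s):", paste(object@thalamus, collapse = ", "), "\n")
})
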