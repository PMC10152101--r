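## Plain-text readers/writers for every exchange format the pipeline uses.
## All numeric output keeps 15 significant digits so that a write/read
## round-trip reproduces values to better than 1e-12 relative error.

#' Cohort table I/O
#'
#' CSV with header \code{subject_id,ga_weeks}; gestational ages may be given
#' in clinical \code{"W+D"} notation and are parsed to decimal weeks on
#' reading.
#'
#' @param cohort data.frame with \code{subject_id}, \code{ga_weeks}.
#' @param path file path.
#' @return \code{readCohortTable}: the parsed data.frame.
#' @export
writeCohortTable <- function(cohort, path) {
  stopifnot(all(c("subject_id", "ga_weeks") %in% names(cohort)))
  out <- data.frame(subject_id = cohort$subject_id,
                    ga_weeks = fmtNum(cohort$ga_weeks))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^subject_id\\s*,\\s*ga_weeks", lines[1]))
    stop("malformed cohort table header at line 1 of ", path)
  tab <- utils::read.csv(path, colClasses = "character")
  ga <- tryCatch(parseGestationalAge(tab$ga_weeks), error = function(e)
    stop("cannot parse ga_weeks in ", path, ": ", conditionMessage(e)))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject ids in ", path)
  data.frame(subject_id = tab$subject_id, ga_weeks = ga,
             stringsAsFactors = FALSE)
}

#' Time-series matrix I/O (TSV)
#'
#' Frames x series matrices (voxel or ROI time series) as tab-separated
#' text with a header row of series names.
#'
#' @param mat numeric matrix.
#' @param path file path.
#' @return \code{readTimeSeries}: the matrix.
#' @export
writeTimeSeries <- function(mat, path) {
  stopifnot(is.matrix(mat))
  cn <- colnames(mat)
  if (is.null(cn)) cn <- sprintf("V%04d", seq_len(ncol(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cn, collapse = "\t"), con)
  utils::write.table(matrix(fmtNum(mat), nrow(mat)), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!nrow(tab)) stop("empty time-series file: ", path)
  as.matrix(tab)
}

#' Voxel label I/O
#'
#' Two-column TSV \code{voxel_id, label}.
#'
#' @param labels character vector of per-voxel labels.
#' @param path file path.
#' @return \code{readVoxelLabels}: character vector.
#' @export
writeVoxelLabels <- function(labels, path) {
  tab <- data.frame(voxel_id = sprintf("V%04d", seq_along(labels)),
                    label = labels)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeVoxelLabels
#' @export
readVoxelLabels <- function(path) {
  if (!file.exists(path)) stop("voxel label file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("voxel_id", "label") %in% names(tab)))
    stop("malformed voxel label header in ", path)
  tab$label
}

#' Connectivity matrix I/O (TSV)
#'
#' Square matrix with a parcel-name header row and a leading parcel-name
#' column; subject id and gestational age travel in \code{#}-prefixed
#' comment lines.
#'
#' @param cm a \code{\linkS4class{ConnectivityMatrix}}.
#' @param path file path.
#' @return \code{readFcMatrix}: a \code{ConnectivityMatrix}.
#' @export
writeFcMatrix <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  M <- cm@mat
  nm <- rownames(M)
  if (is.null(nm)) nm <- sprintf("node%02d", seq_len(nrow(M)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id=%s", cm@subjectId),
               sprintf("# ga_weeks=%s", fmtNum(cm@gaWeeks)),
               paste(c("parcel", nm), collapse = "\t")), con)
  body <- cbind(nm, matrix(fmtNum(M), nrow(M)))
  utils::write.table(body, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFcMatrix
#' @export
readFcMatrix <- function(path) {
  if (!file.exists(path)) stop("FC matrix file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty or truncated FC matrix file: ", path)
  meta <- grep("^#", lines, value = TRUE)
  sid <- sub("^# subject_id=", "", grep("^# subject_id=", meta, value = TRUE))
  ga <- suppressWarnings(as.numeric(
    sub("^# ga_weeks=", "", grep("^# ga_weeks=", meta, value = TRUE))))
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2)
    stop("malformed FC matrix (no data rows) in ", path)
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           check.names = FALSE)
  nm <- as.character(tab[[1]])
  M <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(M) != ncol(M))
    stop("FC matrix not square in ", path, " (line ", length(meta) + 1, ")")
  dimnames(M) <- list(nm, nm)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  new("ConnectivityMatrix", mat = M,
      subjectId = if (length(sid)) sid else NA_character_,
      gaWeeks = if (length(ga)) ga else NA_real_)
}

#' Censor mask I/O
#'
#' One-column TSV coding each frame 0 (valid), 1 (rejected) or 2 (rejected
#' and interpolated).
#'
#' @param censor a \code{\linkS4class{CensorMask}}.
#' @param path file path.
#' @return \code{readCensorMask}: a \code{CensorMask}.
#' @export
writeCensorMask <- function(censor, path) {
  code <- ifelse(censor@interpolated, 2L, ifelse(censor@rejected, 1L, 0L))
  utils::write.table(data.frame(censor = code), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCensorMask
#' @export
readCensorMask <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  code <- tab$censor
  if (is.null(code) || !all(code %in% 0:2))
    stop("malformed censor mask in ", path)
  new("CensorMask", rejected = code >= 1, interpolated = code == 2)
}

#' Ground-truth JSON round trip
#'
#' Serializes every generating parameter of a
#' \code{\linkS4class{GroundTruth}} (including the parcellation and the
#' asymmetry direction matrix) to JSON at full floating-point precision and
#' reads it back.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param path file path.
#' @return \code{readGroundTruth}: a \code{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
  p <- truth@parcellation
  obj <- list(
    parcellation = list(parcels = p@parcels, hemisphere = p@hemisphere,
                        lobe = p@lobe, homolog = p@homolog,
                        thalamus = p@thalamus),
    beta1 = truth@beta1, beta2 = truth@beta2,
    beta3 = truth@beta3, beta4 = truth@beta4,
    structMatrix = truth@structMatrix,
    homologDecay = truth@homologDecay,
    asymMatrix = truth@asymMatrix,
    lateralityOffset = truth@lateralityOffset,
    lateralitySlope = truth@lateralitySlope,
    lateralityParcels = truth@lateralityParcels,
    gaRef = truth@gaRef,
    noiseSd = truth@noiseSd, tissueNoiseSd = truth@tissueNoiseSd,
    spikeProb = truth@spikeProb, spikeAmp = truth@spikeAmp,
    spikeVoxelFrac = truth@spikeVoxelFrac,
    nWm = truth@nWm, nCsf = truth@nCsf,
    wmLeak = truth@wmLeak, csfLeak = truth@csfLeak,
    voxelsPerParcel = truth@voxelsPerParcel,
    nWmVoxels = truth@nWmVoxels, nCsfVoxels = truth@nCsfVoxels,
    ar = truth@ar, seed = truth@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  if (!file.exists(path)) stop("ground-truth file not found: ", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- new("Parcellation",
            parcels = as.character(o$parcellation$parcels),
            hemisphere = as.character(o$parcellation$hemisphere),
            lobe = as.character(o$parcellation$lobe),
            homolog = as.integer(o$parcellation$homolog),
            thalamus = as.character(unlist(o$parcellation$thalamus)))
  new("GroundTruth", parcellation = pc,
      beta1 = as.matrix(o$beta1), beta2 = as.matrix(o$beta2),
      beta3 = as.matrix(o$beta3), beta4 = as.matrix(o$beta4),
      structMatrix = as.matrix(o$structMatrix),
      homologDecay = o$homologDecay,
      asymMatrix = as.matrix(o$asymMatrix),
      lateralityOffset = o$lateralityOffset,
      lateralitySlope = o$lateralitySlope,
      lateralityParcels = as.character(unlist(o$lateralityParcels)),
      gaRef = o$gaRef,
      noiseSd = o$noiseSd, tissueNoiseSd = o$tissueNoiseSd,
      spikeProb = o$spikeProb, spikeAmp = o$spikeAmp,
      spikeVoxelFrac = o$spikeVoxelFrac,
      nWm = as.integer(o$nWm), nCsf = as.integer(o$nCsf),
      wmLeak = o$wmLeak, csfLeak = o$csfLeak,
      voxelsPerParcel = as.integer(o$voxelsPerParcel),
      nWmVoxels = as.integer(o$nWmVoxels),
      nCsfVoxels = as.integer(o$nCsfVoxels),
      ar = o$ar, seed = as.integer(o$seed))
}
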