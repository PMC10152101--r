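## Tiny polynomial string hash; used only to stamp the configuration into
## the result bundle (no cryptographic intent).
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Assembles the full set of tunable parameters of the analysis with their
#' defaults (acquisition geometry of the emulated study, preprocessing
#' thresholds, QC settings, inference sizes). Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return named list of class \code{fetoconnConfig}.
#' @export
fetoconnConfig <- function(...) {
  defaults <- list(
    nSubjects = 48,
    gaMin = 19 + 5 / 7,
    gaMax = 39 + 2 / 7,
    frames = 96,
    tr = 3.0,
    seed = 7,
    spikeZ = 5,
    volumeFraction = 0.05,
    highpassHz = 0.008,
    nWm = 5, nCsf = 5,
    minValidFrames = 8,
    tau = 0.1,
    tauGrid = c(0.05, 0.1, 0.2),
    windowFrames = 10,
    windowStep = 1,
    shrinkage = 0.1,
    minKeep = 10,
    nBoot = 1000,
    nPerm = 199,
    alpha = 0.05,
    homologMargin = 1,
    kostovicWindow = c(24, 32),
    regions = list(SuperiorTemporal = "STG", MedialTemporal = "MTG",
                   InferiorTemporal = "ITG"),
    groundTruth = list()
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- c("fetoconnConfig", "list")
  cfg
}

#' Read a configuration file (YAML or JSON)
#'
#' @param path file path ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return a \code{fetoconnConfig}.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  fetoconnConfig(obj)
}

.stage <- function(stage, subject = NULL, expr, log) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s%s] %s", stage,
                 if (is.null(subject)) "" else paste0(", subject ", subject),
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> connectivity -> quality
#' control -> growth-model fitting -> asymmetry/laterality, writing a
#' plain-text result bundle that is byte-identical across reruns with the
#' same configuration and seed. Wall-clock information goes to stderr only.
#'
#' @param config a \code{\link{fetoconnConfig}}.
#' @param outDir output directory (created if missing).
#' @param inputDir optional directory with \code{cohort.csv} and per-subject
#'   \code{<id>_ts.tsv}, \code{<id>_labels.tsv}, \code{<id>_motion.tsv};
#'   when \code{NULL} a synthetic cohort is simulated.
#' @param verbose emit per-stage log lines to stderr (default \code{TRUE}).
#' @return invisibly, a list with the cohort, QC report, fit table,
#'   similarity trend, laterality table, and output paths.
#' @export
runPipeline <- function(config = fetoconnConfig(), outDir,
                        inputDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "fetoconnConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "fc"), showWarnings = FALSE)
  logLines <- character()
  note <- function(stage, msg, subject = NULL) {
    line <- sprintf("[%s]%s %s", stage,
                    if (is.null(subject)) "" else paste0(" subject=", subject),
                    msg)
    logLines <<- c(logLines, line)
    if (verbose) message(format(Sys.time(), "%H:%M:%OS1 "), line)
  }

  parc <- defaultParcellation()
  truth <- NULL

  ## ---- stage: cohort -------------------------------------------------
  if (is.null(inputDir)) {
    cohort <- .stage("simulate", NULL, generateCohort(
      config$nSubjects, config$gaMin, config$gaMax, config$seed))
    truth <- .stage("simulate", NULL, buildGroundTruth(
      parc, config$groundTruth, seed = config$seed))
    note("simulate", sprintf("synthetic cohort of %d fetuses", nrow(cohort)))
  } else {
    cohortPath <- file.path(inputDir, "cohort.csv")
    cohort <- .stage("load", NULL, readCohortTable(cohortPath))
    note("load", sprintf("cohort of %d subjects from %s", nrow(cohort),
                         cohortPath))
  }
  n <- nrow(cohort)
  seeds <- childSeeds(config$seed, n + 2)

  ## ---- stages: preprocess + connectivity per subject -----------------
  fcList <- vector("list", n)
  excluded <- logical(n)
  nRejected <- integer(n)
  dfcStat <- rep(NA_real_, n)
  meanFd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sid <- cohort$subject_id[i]
    if (is.null(inputDir)) {
      rec <- .stage("simulate", sid, simulateSubject(
        truth, cohort$ga_weeks[i], frames = config$frames, tr = config$tr,
        seed = seeds[i], subjectId = sid))
      vts <- rec@voxelTs; vlab <- rec@voxelLabels; motion <- rec@motionTrace
    } else {
      tsPath <- file.path(inputDir, paste0(sid, "_ts.tsv"))
      labPath <- file.path(inputDir, paste0(sid, "_labels.tsv"))
      motPath <- file.path(inputDir, paste0(sid, "_motion.tsv"))
      vts <- .stage("load", sid, readTimeSeries(tsPath))
      vlab <- .stage("load", sid, readVoxelLabels(labPath))
      motion <- if (file.exists(motPath)) unname(readTimeSeries(motPath))
                else matrix(0, nrow(vts), 6)
    }
    censor <- .stage("censor", sid, detectOutlierVolumes(
      vts, spikeZ = config$spikeZ, volumeFraction = config$volumeFraction))
    nRejected[i] <- sum(censor@rejected)
    if (sum(!censor@rejected) < config$minValidFrames) {
      excluded[i] <- TRUE
      note("censor", sprintf("excluded: only %d valid frames",
                             sum(!censor@rejected)), sid)
      next
    }
    design <- .stage("acompcor", sid, computeACompCor(
      vts, vlab, nWm = config$nWm, nCsf = config$nCsf, censor = censor))
    roi <- .stage("roi", sid, roiAverage(vts, vlab, parc))
    clean <- .stage("clean", sid, cleanTimeseries(
      roi, design, highpassHz = config$highpassHz, tr = config$tr,
      censor = censor))
    fcList[[i]] <- .stage("fc", sid, computeFC(
      clean, subjectId = sid, gaWeeks = cohort$ga_weeks[i]))
    fdStat <- .stage("qc", sid, framewiseDisplacement(motion))
    meanFd[i] <- fdStat@meanFd
    dfcStat[i] <- .stage("qc", sid, dfcFdAssociation(
      roi, fdStat, windowFrames = config$windowFrames,
      step = config$windowStep))$statistic
    writeFcMatrix(fcList[[i]], file.path(outDir, "fc",
                                         paste0(sid, ".tsv")))
    note("fc", sprintf("%d rejected frame(s), dFC-FD %.3f",
                       nRejected[i], dfcStat[i]), sid)
  }

  ## ---- stage: group QC ----------------------------------------------
  avail <- which(!excluded)
  qc <- .stage("qc", NULL, iterativeAgeConsistencyFilter(
    fcList[avail], gaWeeks = cohort$ga_weeks[avail],
    minKeep = min(config$minKeep, length(avail)),
    shrinkage = config$shrinkage,
    subjectIds = cohort$subject_id[avail]))
  qcPass <- rep(FALSE, n)
  qcPass[avail] <- qc@kept
  note("qc", sprintf("%d/%d subjects pass group QC", sum(qcPass), n))

  manifest <- data.frame(subject_id = cohort$subject_id,
                         ga_weeks = fmtNum(cohort$ga_weeks),
                         n_rejected = nRejected,
                         mean_fd = fmtNum(meanFd),
                         dfc_fd = fmtNum(dfcStat),
                         qc_pass = qcPass)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  writeCohortTable(cohort, file.path(outDir, "cohort.csv"))

  kept <- which(qcPass)
  ga <- cohort$ga_weeks[kept]
  mats <- lapply(fcList[kept], fcMatrix)

  ## ---- stage: growth models (thalamocortical edges) ------------------
  fitTab <- NULL
  lobeTest <- NULL
  if (length(parc@thalamus) && length(kept) >= 8) {
    nodes <- nodeNames(parc)
    thal <- which(nodes == parc@thalamus[1])
    permSeeds <- childSeeds(seeds[n + 1], nParcels(parc))
    rows <- vector("list", nParcels(parc))
    for (pIdx in seq_len(nParcels(parc))) {
      y <- vapply(mats, function(M) M[thal, pIdx], numeric(1))
      sf <- .stage("fit", nodes[pIdx], fitSigmoid(ga, y))
      lf <- .stage("fit", nodes[pIdx], fitLinear(ga, y))
      pt <- .stage("fit", nodes[pIdx], permutationGofTest(
        ga, y, nPerm = config$nPerm, seed = permSeeds[pIdx]))
      rows[[pIdx]] <- data.frame(
        parcel = nodes[pIdx], lobe = lobeOf(parc)[pIdx],
        initial_plateau = sf@beta[2], final_plateau = sf@beta[1],
        inflection_time = sf@beta[3], growth_rate = sf@beta[4],
        adj_r2 = sf@adjR2, aic = sf@aic, bic = sf@bic,
        linear_adj_r2 = lf$adjR2, linear_aic = lf$aic,
        p_perm = pt$p, degenerate = sf@degenerate,
        converged = sf@converged, stringsAsFactors = FALSE)
    }
    fitTab <- do.call(rbind, rows)
    bh <- fdrBH(fitTab$p_perm, config$alpha)
    fitTab$q <- bh$q
    fitTab$significant <- bh$reject
    note("fit", sprintf("%d/%d thalamocortical edges significant (FDR %g)",
                        sum(fitTab$significant), nrow(fitTab), config$alpha))

    ## bootstrap CIs for the significant, non-degenerate edges
    bootSeeds <- childSeeds(seeds[n + 2], nParcels(parc))
    fitTab$b3_lo <- NA_real_; fitTab$b3_hi <- NA_real_
    for (pIdx in which(fitTab$significant & !fitTab$degenerate)) {
      y <- vapply(mats, function(M) M[thal, pIdx], numeric(1))
      bp <- .stage("bootstrap", fitTab$parcel[pIdx], bootstrapParams(
        ga, y, nBoot = config$nBoot, seed = bootSeeds[pIdx]))
      fitTab$b3_lo[pIdx] <- bp$ci["beta3", 1]
      fitTab$b3_hi[pIdx] <- bp$ci["beta3", 2]
    }
    out <- fitTab
    for (cc in names(out)) if (is.numeric(out[[cc]]))
      out[[cc]] <- fmtNum(out[[cc]])
    utils::write.csv(out, file.path(outDir, "fits_thalamocortical.csv"),
                     row.names = FALSE, quote = FALSE)

    sig <- fitTab[fitTab$significant & !fitTab$degenerate, ]
    if (nrow(sig) >= 4 && length(unique(sig$lobe)) >= 2 &&
        all(table(sig$lobe) >= 2))
      lobeTest <- lobeInflectionAnova(sig$inflection_time, sig$lobe)
  }

  ## ---- stage: asymmetry ----------------------------------------------
  simStat <- vapply(mats, function(M)
    mean(homologSimilarities(M, parc, tau = config$tau)), numeric(1))
  simTrend <- if (length(kept) >= 10) similarityAgeTrend(simStat, ga)
              else NULL
  latTab <- .stage("asymmetry", NULL, cohortLaterality(
    fcList[kept], parc, config$regions, ga = ga,
    tauGrid = config$tauGrid, alpha = config$alpha))
  out <- latTab
  for (cc in names(out)) if (is.numeric(out[[cc]]))
    out[[cc]] <- fmtNum(out[[cc]])
  utils::write.csv(out, file.path(outDir, "laterality.csv"),
                   row.names = FALSE, quote = FALSE)
  note("asymmetry", sprintf(
    "mean homolog similarity %.3f; %d significant region/tau cells",
    mean(simStat), sum(latTab$significant)))

  ## ---- reports --------------------------------------------------------
  cfgJson <- jsonlite::toJSON(unclass(config), digits = NA,
                              auto_unbox = TRUE)
  provenance <- list(package = "fetoconn",
                     version = as.character(utils::packageVersion("fetoconn")),
                     configHash = .fnv1a(as.character(cfgJson)))
  qcReport <- list(
    provenance = provenance,
    subjects = data.frame(subject_id = qc@subjectIds, kept = qc@kept,
                          age_consistency = qc@ageConsistency,
                          removed_at = qc@removedAt),
    iterations = qc@iterations)
  jsonlite::write_json(qcReport, file.path(outDir, "qc_report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  summaryReport <- list(
    provenance = provenance,
    nSubjects = n, nExcludedCensor = sum(excluded),
    nRemovedQc = sum(!excluded) - length(kept), nAnalyzed = length(kept),
    meanOutlierFraction = mean(nRejected / config$frames),
    similarityTrend = simTrend,
    lobeAnova = lobeTest)
  jsonlite::write_json(summaryReport, file.path(outDir, "report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  jsonlite::write_json(c(unclass(config), provenance = list(provenance)),
                       file.path(outDir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  writeLines(logLines, file.path(outDir, "run.log"))

  invisible(list(cohort = cohort, qc = qc, fits = fitTab,
                 similarityTrend = simTrend, laterality = latTab,
                 lobeAnova = lobeTest, outDir = outDir,
                 manifest = manifest))
}
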