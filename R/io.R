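# Session container, model serialization and report export. The container
# is a directory holding a JSON header, the sensor array as raw little-
# endian float64, and the trial-metadata CSV; numeric metadata columns are
# printed with 17 significant digits so the round trip is lossless.

SCHEMA_VERSION <- "1.0"

fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

writeF64 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(x), con, size = 8, endian = "little")
}

readF64 <- function(path, dims = NULL) {
  n <- file.size(path) / 8
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (!is.null(dims)) array(x, dim = dims) else x
}

#' Write a session container
#'
#' Serializes a [SessionData-class] to a directory: `header.json`,
#' `sensors.f64` (raw little-endian float64), `trialmeta.csv`, and (for
#' synthetic sessions, unless `keepGroundTruth = FALSE`) the ground-truth
#' mixing, labels and source traces. `writeSession` followed by
#' [readSession()] is lossless.
#'
#' @param session a [SessionData-class].
#' @param path directory to create/overwrite.
#' @param keepGroundTruth write the ground-truth group (default TRUE).
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path, keepGroundTruth = TRUE) {
  stopifnot(is(session, "SessionData"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(session@sensors)
  header <- list(schemaVersion = SCHEMA_VERSION, dims = d, fs = session@fs,
                 traceStartMs = session@traceStartMs,
                 sessionTag = session@sessionTag, seed = session@seed,
                 hasGroundTruth = keepGroundTruth && length(session@groundTruth) > 0)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  writeF64(session@sensors, file.path(path, "sensors.f64"))
  meta <- session@meta
  for (cl in c("perturbationOnsetS", "manualRtMs", "descentRateMps"))
    meta[[cl]] <- fmtNum(meta[[cl]])
  write.csv(meta, file.path(path, "trialmeta.csv"), row.names = FALSE)
  if (header$hasGroundTruth) {
    gt <- session@groundTruth
    gtDir <- file.path(path, "ground_truth")
    dir.create(gtDir, showWarnings = FALSE)
    jsonlite::write_json(
      list(taskSourceIndex = gt$taskSourceIndex, trueLabels = gt$trueLabels,
           mixingDims = dim(gt$mixing),
           sourceDims = if (!is.null(gt$sourceTraces)) dim(gt$sourceTraces)),
      file.path(gtDir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    writeF64(gt$mixing, file.path(gtDir, "mixing.f64"))
    if (!is.null(gt$sourceTraces))
      writeF64(gt$sourceTraces, file.path(gtDir, "sources.f64"))
  }
  invisible(path)
}

#' Read a session container
#'
#' @param path directory written by [writeSession()].
#' @return a [SessionData-class]; `groundTruth` is empty when the container
#'   carries none (real-data mode).
#' @export
readSession <- function(path) {
  hp <- file.path(path, "header.json")
  if (!file.exists(hp)) stop("no session container at ", path)
  header <- jsonlite::read_json(hp, simplifyVector = TRUE)
  if (!identical(header$schemaVersion, SCHEMA_VERSION))
    stop("session container schema version ", header$schemaVersion,
         " is not supported (expected ", SCHEMA_VERSION, ")")
  sensors <- readF64(file.path(path, "sensors.f64"), dims = header$dims)
  meta <- read.csv(file.path(path, "trialmeta.csv"), stringsAsFactors = FALSE)
  if (nrow(meta) != header$dims[1])
    stop("metadata row count (", nrow(meta), ") does not match sensor trials (",
         header$dims[1], "); trial(s) ",
         paste(setdiff(seq_len(header$dims[1]), meta$trialIndex), collapse = ", "),
         " missing from trialmeta.csv")
  for (cl in c("perturbationOnsetS", "manualRtMs", "descentRateMps"))
    meta[[cl]] <- as.numeric(meta[[cl]])
  gt <- list()
  gtDir <- file.path(path, "ground_truth")
  if (isTRUE(header$hasGroundTruth) && dir.exists(gtDir)) {
    gj <- jsonlite::read_json(file.path(gtDir, "ground_truth.json"),
                              simplifyVector = TRUE)
    gt <- list(mixing = readF64(file.path(gtDir, "mixing.f64"), gj$mixingDims),
               taskSourceIndex = as.integer(gj$taskSourceIndex),
               trueLabels = gj$trueLabels)
    if (!is.null(gj$sourceDims) && file.exists(file.path(gtDir, "sources.f64")))
      gt$sourceTraces <- readF64(file.path(gtDir, "sources.f64"), gj$sourceDims)
  }
  new("SessionData", sensors = sensors, fs = header$fs,
      traceStartMs = header$traceStartMs, meta = meta,
      sessionTag = header$sessionTag, groundTruth = gt,
      seed = as.integer(header$seed))
}

#' Serialize / restore an unmixing model
#'
#' Weights go to raw float64 files and metadata to JSON, so a reloaded
#' model reproduces activations bit-exactly.
#'
#' @param model an [UnmixingModel-class].
#' @param path directory.
#' @return `path` (write) or the model (read).
#' @export
saveUnmixingModel <- function(model, path) {
  stopifnot(is(model, "UnmixingModel"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(schemaVersion = SCHEMA_VERSION,
         dims = dim(model@combinedWeights),
         selectedComponent = model@selectedComponent,
         varianceExplained = model@varianceExplained,
         sessionsUsed = model@sessionsUsed, seed = model@seed,
         sweeps = model@sweeps),
    file.path(path, "model.json"), auto_unbox = TRUE, digits = NA)
  writeF64(model@pcaMatrix, file.path(path, "pca.f64"))
  writeF64(model@icaUnmixing, file.path(path, "ica.f64"))
  writeF64(model@combinedWeights, file.path(path, "combined.f64"))
  writeF64(model@channelMean, file.path(path, "channel_mean.f64"))
  if (nrow(model@selectionScores))
    write.csv(model@selectionScores, file.path(path, "selection_scores.csv"),
              row.names = FALSE)
  invisible(path)
}

#' @rdname saveUnmixingModel
#' @export
loadUnmixingModel <- function(path) {
  mj <- jsonlite::read_json(file.path(path, "model.json"), simplifyVector = TRUE)
  k <- mj$dims[1]; nCh <- mj$dims[2]
  scores <- if (file.exists(file.path(path, "selection_scores.csv")))
    read.csv(file.path(path, "selection_scores.csv")) else data.frame()
  # NA-valued scalars come back from JSON as "NA" strings or NULL
  asNum <- function(x) if (is.null(x)) NA_real_ else suppressWarnings(as.numeric(x))
  asInt <- function(x) if (is.null(x)) NA_integer_ else suppressWarnings(as.integer(x))
  new("UnmixingModel",
      pcaMatrix = readF64(file.path(path, "pca.f64"), c(k, nCh)),
      icaUnmixing = readF64(file.path(path, "ica.f64"), c(k, k)),
      combinedWeights = readF64(file.path(path, "combined.f64"), c(k, nCh)),
      channelMean = readF64(file.path(path, "channel_mean.f64")),
      selectedComponent = asInt(mj$selectedComponent),
      selectionScores = scores,
      varianceExplained = asNum(mj$varianceExplained),
      sessionsUsed = mj$sessionsUsed, seed = asInt(mj$seed),
      sweeps = asInt(mj$sweeps))
}

#' Serialize / restore an LSPC decoder
#'
#' @param decoder an [LspcDecoder-class].
#' @param path directory.
#' @return `path` (write) or the decoder (read).
#' @export
saveLspcDecoder <- function(decoder, path) {
  stopifnot(is(decoder, "LspcDecoder"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(schemaVersion = SCHEMA_VERSION, n = nrow(decoder@centers),
         classes = decoder@classes, foldSeed = decoder@foldSeed),
    file.path(path, "decoder.json"), auto_unbox = TRUE, digits = NA)
  # numeric hyperparameters and normalization go through raw float64 so the
  # round trip is bit-exact (JSON text would round the last bits)
  writeF64(c(decoder@sigma, decoder@rho, decoder@featMean, decoder@featSd,
             decoder@anchorMs, decoder@cvLoss),
           file.path(path, "params.f64"))
  writeF64(decoder@centers, file.path(path, "centers.f64"))
  writeF64(decoder@weights, file.path(path, "weights.f64"))
  invisible(path)
}

#' @rdname saveLspcDecoder
#' @export
loadLspcDecoder <- function(path) {
  dj <- jsonlite::read_json(file.path(path, "decoder.json"), simplifyVector = TRUE)
  p <- readF64(file.path(path, "params.f64"))
  new("LspcDecoder",
      centers = readF64(file.path(path, "centers.f64"), c(dj$n, 3L)),
      weights = readF64(file.path(path, "weights.f64"), c(dj$n, 2L)),
      sigma = p[1], rho = p[2], classes = dj$classes,
      featMean = p[3:5], featSd = p[6:8], anchorMs = p[9],
      foldSeed = as.integer(dj$foldSeed), cvLoss = p[10])
}

#' Reference performance tables of the original study
#'
#' The per-participant results printed in the original flight-simulation
#' MEG study, shipped as plain CSV: classification performance on the
#' held-out simple and complex sessions (confusion counts, balanced
#' accuracies, signal-detection indices), the response-time improvement and
#' permutation statistics, the cross-subject generalization analogues, the
#' flight characteristics (descent rates and altitude savings), behavioral
#' reaction times, and the per-participant evoked peak latencies. These are
#' inputs for reproducing the study's derived statistics, not outputs of
#' this package.
#'
#' @return named list of data.frames: `simpleConfusion`, `complexConfusion`,
#'   `generalizedConfusion`, `timing`, `generalizedTiming`, `flight`,
#'   `behavior`, `peakLatencies`.
#' @export
referenceTables <- function() {
  rd <- function(f) read.csv(system.file("extdata", f, package = "neuroadapt"),
                             stringsAsFactors = FALSE)
  list(simpleConfusion = rd("reference_confusion_simple.csv"),
       complexConfusion = rd("reference_confusion_complex.csv"),
       generalizedConfusion = rd("reference_confusion_generalized.csv"),
       timing = rd("reference_timing_own.csv"),
       generalizedTiming = rd("reference_timing_generalized.csv"),
       flight = rd("reference_flight.csv"),
       behavior = rd("reference_behavior.csv"),
       peakLatencies = rd("reference_peak_latency.csv"))
}

REPORT_HEADERS <- list(
  performance = c("id", "bacc_mean", "bacc_ppi1", "bacc_ppi2", "bacc_p",
                  "tp", "fn", "fp", "tn", "hr", "far", "dprime", "aprime"),
  timing = c("id", "n", "tp", "fp", "org_mean_ms", "org_se_ms", "bci_mean_ms",
             "bci_se_ms", "rt_diff_mean_ms", "rt_diff_se_ms",
             "perm_rt_diff_mean_ms", "perm_p"),
  flight = c("id", "descent_rate_mean_mps", "descent_rate_greatest_mps",
             "rt_improvement_ms", "altitude_savings_mean_dr_m",
             "altitude_savings_greatest_dr_m"))

performanceRow <- function(id, conf, bp = NULL) {
  if (is.null(bp))
    bp <- baccPosterior(conf[["tp"]], conf[["fn"]], conf[["fp"]], conf[["tn"]])
  sdt <- sdtStats(conf[["tp"]], conf[["fn"]], conf[["fp"]], conf[["tn"]])
  data.frame(id = id, bacc_mean = bp$meanPct, bacc_ppi1 = bp$loPct,
             bacc_ppi2 = bp$hiPct, bacc_p = bp$pBelowChance,
             tp = conf[["tp"]], fn = conf[["fn"]], fp = conf[["fp"]],
             tn = conf[["tn"]], hr = sdt$hr, far = sdt$far,
             dprime = sdt$dprime, aprime = sdt$aprime,
             stringsAsFactors = FALSE)
}

#' Export result tables
#'
#' Writes the per-subject result CSVs in the canonical column layouts
#' (classification performance for the simple and complex sessions, the
#' response-time improvement table, and the flight/altitude-savings table),
#' each with a trailing `group_mean` row of unweighted subject means.
#'
#' @param results a cohort result list from [runCohortPipeline()] (or a
#'   single-subject list from [runSubjectPipeline()] wrapped in a list).
#' @param dir output directory.
#' @return invisible character vector of the files written.
#' @export
exportReport <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- if (!is.null(results$subjects)) results$subjects else results
  addGroupMean <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    gm <- df[1, , drop = FALSE]
    gm$id <- "group_mean"
    for (cl in names(df)[num]) gm[[cl]] <- mean(df[[cl]])
    rbind(df, gm)
  }
  perfS <- do.call(rbind, lapply(subjects, function(s)
    performanceRow(s$id, s$simpleEval$confusion)))
  perfC <- do.call(rbind, lapply(subjects, function(s)
    performanceRow(s$id, confusionCounts(s$complexSummary))))
  timing <- do.call(rbind, lapply(subjects, function(s) {
    st <- savingsStats(s$complexSummary)
    conf <- confusionCounts(s$complexSummary)
    data.frame(id = s$id, n = conf[["tp"]] + conf[["fn"]], tp = conf[["tp"]],
               fp = conf[["fp"]], org_mean_ms = st$orgMeanMs,
               org_se_ms = st$orgSeMs, bci_mean_ms = st$bciMeanMs,
               bci_se_ms = st$bciSeMs, rt_diff_mean_ms = st$diffMeanMs,
               rt_diff_se_ms = st$diffSeMs,
               perm_rt_diff_mean_ms = if (!is.null(s$perm)) mean(s$perm$nullDiffsMs) else NA_real_,
               perm_p = if (!is.null(s$perm)) s$perm$p else NA_real_,
               stringsAsFactors = FALSE)
  }))
  flight <- do.call(rbind, lapply(subjects, function(s) {
    st <- savingsStats(s$complexSummary)
    data.frame(id = s$id, descent_rate_mean_mps = st$descentRateMeanMps,
               descent_rate_greatest_mps = st$descentRateGreatestMps,
               rt_improvement_ms = st$diffMeanMs,
               altitude_savings_mean_dr_m = st$altitudeSavingsMeanM,
               altitude_savings_greatest_dr_m = st$altitudeSavingsGreatestM,
               stringsAsFactors = FALSE)
  }))
  files <- c(performance_simple = "performance_simple.csv",
             performance_complex = "performance_complex.csv",
             timing_complex = "timing_complex.csv",
             flight_savings = "flight_savings.csv")
  tabs <- list(addGroupMean(perfS), addGroupMean(perfC),
               addGroupMean(timing), addGroupMean(flight))
  expect <- REPORT_HEADERS[c("performance", "performance", "timing", "flight")]
  for (i in seq_along(files)) {
    stopifnot(identical(names(tabs[[i]]), expect[[i]]))
    write.csv(tabs[[i]], file.path(dir, files[i]), row.names = FALSE)
  }
  invisible(file.path(dir, files))
}

#' Save / load a subject configuration as JSON
#'
#' Every generator field is written by name; unknown fields in the file are
#' rejected so silent typos cannot change the study conditions.
#'
#' @param config a [SubjectConfig-class].
#' @param path JSON file path.
#' @return `path` (write) or the [SubjectConfig-class] (read).
#' @export
saveSubjectConfig <- function(config, path) {
  stopifnot(is(config, "SubjectConfig"))
  fields <- methods::slotNames("SubjectConfig")
  vals <- lapply(fields, function(f) slot(config, f))
  names(vals) <- fields
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveSubjectConfig
#' @export
loadSubjectConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), methods::slotNames("SubjectConfig"))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(subjectConfig, vals)
}
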