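# End-to-end orchestration. The stages mirror the analysis protocol:
# simulate -> preprocess -> unmix -> train -> decode-simple ->
# decode-complex -> permute (-> generalize at cohort level). Every stage is
# deterministic given the subject configuration's master seed.

PIPELINE_STAGES <- c("simulate", "preprocess", "unmix", "train",
                     "decodeSimple", "decodeComplex", "permute")

# Extract the trials of an EpochArray matching a condition.
subsetEpochs <- function(epochs, idx) {
  new("EpochArray", data = epochs@data[idx, , , drop = FALSE], fs = epochs@fs,
      space = epochs@space, meta = epochs@meta[idx, , drop = FALSE],
      screeningLog = epochs@screeningLog)
}

#' Ground-truth unmixing model
#'
#' Builds an [UnmixingModel-class] directly from a synthetic session's
#' planted mixing matrix (its pseudo-inverse recovers the sources up to
#' sensor noise). This bypasses ICA and exists for validation and
#' calibration studies where the blind-separation step is not under test.
#'
#' @param session a synthetic [SessionData-class] with ground truth.
#' @return an [UnmixingModel-class] whose components are the planted
#'   sources in order.
#' @export
oracleUnmixing <- function(session) {
  gt <- groundTruth(session)
  if (is.null(gt)) stop("session carries no ground truth")
  A <- gt$mixing
  W <- solve(crossprod(A)) %*% t(A)   # pseudo-inverse of the mixing
  rn <- sqrt(rowSums(W^2))
  Wn <- W / rn
  new("UnmixingModel", pcaMatrix = Wn, icaUnmixing = diag(nrow(W)),
      combinedWeights = Wn, channelMean = rep(0, ncol(W)),
      selectedComponent = gt$taskSourceIndex,
      selectionScores = data.frame(), varianceExplained = NA_real_,
      sessionsUsed = "oracle", seed = NA_integer_, sweeps = 0L)
}

#' Run the full analysis for one subject
#'
#' Simulates (or accepts) the subject's four sessions, preprocesses and
#' screens them, fits the unmixing model on the two training sessions,
#' selects the evoked task component, derives the peak anchor from the
#' first session, trains `nDecoders` LSPC decoders and keeps the best by
#' balanced accuracy on the held-out simple session, adjudicates the
#' complex session with the sliding-window detector, and (optionally) runs
#' the permutation null of the time savings.
#'
#' @param config a [SubjectConfig-class].
#' @param stages subset of
#'   `c("simulate", "preprocess", "unmix", "train", "decodeSimple",
#'   "decodeComplex", "permute")`; execution stops after the last requested
#'   stage.
#' @param sessions optionally, a pre-built list of four [SessionData-class]
#'   (skips simulation; real-data entry point).
#' @param nComponents PCA/ICA dimensionality (default 64).
#' @param nDecoders decoders trained and compared (default 100).
#' @param nPerm qualifying permutations for the null (default 1000).
#' @param unmixer `"ica"` (default) or `"oracle"` (ground-truth unmixing,
#'   validation only).
#' @param outDir if given, session containers, models and reports are
#'   written beneath it.
#' @param id subject identifier used in reports.
#' @param ... passed to [fitLspc()] via [trainAndSelect()].
#' @return a list with the artifacts of every executed stage: `sessions`,
#'   `epochs`, `model`, `component`, `anchorMs`, `features`, `selection`,
#'   `decoder`, `simpleEval`, `complexSummary`, `complexEval`, `perm`,
#'   `trainActs`, `complexActs`, `id`, `config`.
#' @export
runSubjectPipeline <- function(config, stages = PIPELINE_STAGES,
                               sessions = NULL, nComponents = 64,
                               nDecoders = 100, nPerm = 1000,
                               unmixer = c("ica", "oracle"), outDir = NULL,
                               id = paste0("subject", config@seed), ...) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  unmixer <- match.arg(unmixer)
  last <- max(match(stages, PIPELINE_STAGES))
  want <- function(st) match(st, PIPELINE_STAGES) <= last
  res <- list(id = id, config = config)

  if (is.null(sessions)) sessions <- simulateSubject(config)$sessions
  res$sessions <- sessions
  if (!is.null(outDir)) {
    for (i in seq_along(sessions))
      writeSession(sessions[[i]], file.path(outDir, id, paste0("session", i)),
                   keepGroundTruth = FALSE)
    saveSubjectConfig(config, file.path(outDir, id, "config.json"))
  }
  if (!want("preprocess")) return(res)

  epochs <- lapply(sessions, segmentAndScreen)
  if (!is.null(outDir))
    for (i in seq_along(epochs))
      write.csv(screeningLog(epochs[[i]]),
                file.path(outDir, id, sprintf("screening_session%d.csv", i)),
                row.names = FALSE)
  res$epochs <- epochs
  res$sessions <- NULL   # raw traces are large; epochs carry everything needed
  if (!want("unmix")) { res$sessions <- sessions; return(res) }

  trainEp <- bindEpochs(epochs[[1]], epochs[[2]])
  model <- if (unmixer == "ica")
    fitUnmixing(trainEp, nComponents = nComponents,
                seed = deriveSeed(config@seed, "ica"))
  else oracleUnmixing(sessions[[1]])
  flyTrain <- subsetEpochs(trainEp, which(trainEp@meta$condition == "fly_perturbation"))
  model <- selectTaskComponent(model, flyTrain)
  res$model <- model
  res$component <- selectedComponent(model)
  if (!is.null(outDir)) saveUnmixingModel(model, file.path(outDir, id, "unmixing"))
  if (!want("train")) return(res)

  comp <- selectedComponent(model)
  trainActs <- componentActivations(model, trainEp)
  res$trainActs <- trainActs
  s1fly <- which(trainActs@meta$sessionId == trainActs@meta$sessionId[1] &
                   trainActs@meta$condition == "fly_perturbation")
  anchor <- findPeakLatency(apply(trainActs@data[s1fly, comp, , drop = FALSE], 3, mean))
  res$anchorMs <- anchor
  features <- assembleTrainingSet(trainActs@data[, comp, ], trainActs@meta, anchor)
  res$features <- features
  evalActs <- componentActivations(model, epochs[[3]])
  sel <- trainAndSelect(features, evalActs@data[, comp, ], evalActs@meta,
                        anchor, nDecoders = nDecoders,
                        seed = deriveSeed(config@seed, "decoders"), ...)
  res$decoder <- sel$best
  res$selection <- sel$report
  if (!is.null(outDir)) saveLspcDecoder(sel$best, file.path(outDir, id, "decoder"))
  if (!want("decodeSimple")) return(res)

  conf <- sel$bestConfusion
  res$simpleEval <- list(
    confusion = conf,
    bacc = baccPosterior(conf[["tp"]], conf[["fn"]], conf[["fp"]], conf[["tn"]]),
    sdt = sdtStats(conf[["tp"]], conf[["fn"]], conf[["fp"]], conf[["tn"]]),
    meanBacc100 = sel$meanBacc, bestBacc = sel$bestBacc)
  if (!want("decodeComplex")) return(res)

  complexActs <- componentActivations(model, epochs[[4]])
  res$complexActs <- complexActs
  summ <- adjudicateSession(sel$best, complexActs, componentIndex = comp)
  res$complexSummary <- summ
  cc <- confusionCounts(summ)
  res$complexEval <- list(
    confusion = cc,
    bacc = baccPosterior(cc[["tp"]], cc[["fn"]], cc[["fp"]], cc[["tn"]]),
    sdt = sdtStats(cc[["tp"]], cc[["fn"]], cc[["fp"]], cc[["tn"]]))
  if (!want("permute")) return(res)

  res$perm <- permutationTimeSavings(
    trainActs, complexActs, savingsStats(summ)$diffMeanMs, nPerm = nPerm,
    seed = deriveSeed(config@seed, "perm"))
  res
}

#' Run a cohort and the cross-subject generalization
#'
#' Runs [runSubjectPipeline()] for `nSubjects` subjects whose seeds derive
#' from `seed`, picks the donor with the best balanced accuracy on the
#' held-out simple session, applies the donor's decoder to every other
#' subject ([generalizeModel()]), and optionally exports the report CSVs.
#'
#' @param nSubjects cohort size (the study had 7).
#' @param baseConfig template [SubjectConfig-class]; per-subject seeds are
#'   derived from `seed`.
#' @param seed cohort master seed.
#' @param nDecoders,nPerm,nComponents,unmixer passed through.
#' @param permute run the permutation null per subject (default FALSE; it
#'   dominates the runtime).
#' @param outDir if given, [exportReport()] is written there.
#' @param ... passed to [runSubjectPipeline()].
#' @return list: `subjects` (per-subject pipeline results), `donorId`,
#'   `generalization` (from [generalizeModel()]).
#' @export
runCohortPipeline <- function(nSubjects = 7, baseConfig = subjectConfig(),
                              seed = 1L, nDecoders = 100, nPerm = 1000,
                              nComponents = 64, unmixer = "ica",
                              permute = FALSE, outDir = NULL, ...) {
  subjects <- list()
  for (i in seq_len(nSubjects)) {
    cfg <- baseConfig
    cfg@seed <- deriveSeed(seed, "subject", i)
    sid <- paste0("subject", i)
    stages <- if (permute) PIPELINE_STAGES else setdiff(PIPELINE_STAGES, "permute")
    subjects[[sid]] <- runSubjectPipeline(cfg, stages = stages,
                                          nComponents = nComponents,
                                          nDecoders = nDecoders, nPerm = nPerm,
                                          unmixer = unmixer, id = sid, ...)
  }
  simpleBacc <- vapply(subjects, function(s) s$simpleEval$bacc$meanPct, numeric(1))
  donorId <- names(subjects)[which.max(simpleBacc)]
  gen <- generalizeModel(
    subjects[[donorId]]$decoder,
    lapply(subjects, function(s)
      list(complexActs = s$complexActs, component = s$component,
           ownSummary = s$complexSummary)),
    donorId)
  out <- list(subjects = subjects, donorId = donorId, generalization = gen)
  if (!is.null(outDir)) exportReport(out, outDir)
  out
}
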