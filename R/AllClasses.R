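#' Subject-level generator configuration
#'
#' An S4 container for every tunable of the synthetic-data generator. The
#' defaults describe one simulated participant of the flight-perturbation
#' study: 1000 Hz multichannel recordings with an evoked task source peaking
#' 190--290 ms after the perturbation, ocular and cardiac artifact sources,
#' ongoing oscillatory background, and manual reaction times of roughly
#' 360 ms (simple task) and 430 ms (complex task).
#'
#' @slot nChannels number of sensor channels (64 at desk scale; the original
#'   recordings used 400).
#' @slot fsRaw raw sampling rate in Hz (1000).
#' @slot nSources number of planted neural/artifact sources.
#' @slot taskAmpFly evoked amplitude on active-piloting perturbation trials
#'   (unitless source amplitude).
#' @slot taskAmpWatch evoked amplitude on passive-viewing perturbation trials
#'   as a fraction of `taskAmpFly`.
#' @slot motorRampAmp amplitude of the pre-movement motor ramp that ends at
#'   the manual reaction time on active trials (fraction of `taskAmpFly`;
#'   0 disables it).
#' @slot peakLatencyMs evoked peak latency in ms, must lie in \[190, 290\].
#' @slot latencyJitterMs trial-to-trial SD of the peak latency, ms.
#' @slot amplitudeJitterSd trial-to-trial lognormal SD of the evoked
#'   amplitude (mean-one multiplier; 0 disables the variability).
#' @slot rtMeanSimpleMs,rtMeanComplexMs,rtSdMs manual reaction-time model
#'   (truncated normal on \[200, 700\] ms).
#' @slot blinkRatePerMin,cardiacHz artifact event rates.
#' @slot backgroundPower RMS of each ongoing background source.
#' @slot complexMotorPower extra continuous visuomotor source power present
#'   throughout complex-task trials.
#' @slot noiseSd per-channel white sensor-noise SD (a 1/f-like component at
#'   0.3 of this SD is added as well).
#' @slot descentRateMeanMps,descentRateSdMps per-trial descent-rate metadata
#'   model, m/s.
#' @slot seed master integer seed for the subject.
#' @export
setClass("SubjectConfig",
  representation(
    nChannels = "integer", fsRaw = "numeric", nSources = "integer",
    taskAmpFly = "numeric", taskAmpWatch = "numeric", motorRampAmp = "numeric",
    peakLatencyMs = "numeric", latencyJitterMs = "numeric",
    amplitudeJitterSd = "numeric",
    rtMeanSimpleMs = "numeric", rtMeanComplexMs = "numeric", rtSdMs = "numeric",
    blinkRatePerMin = "numeric", cardiacHz = "numeric",
    backgroundPower = "numeric", complexMotorPower = "numeric",
    noiseSd = "numeric",
    descentRateMeanMps = "numeric", descentRateSdMps = "numeric",
    seed = "integer"),
  prototype(
    nChannels = 64L, fsRaw = 1000, nSources = 8L,
    taskAmpFly = 2.5, taskAmpWatch = 0.6, motorRampAmp = 0.8,
    peakLatencyMs = 232, latencyJitterMs = 12,
    amplitudeJitterSd = 0.25,
    rtMeanSimpleMs = 360, rtMeanComplexMs = 430, rtSdMs = 40,
    blinkRatePerMin = 15, cardiacHz = 1.1,
    backgroundPower = 0.8, complexMotorPower = 0.15,
    noiseSd = 0.35,
    descentRateMeanMps = 69.6, descentRateSdMps = 12,
    seed = 1L))

setValidity("SubjectConfig", function(object) {
  msg <- character()
  if (object@fsRaw <= 2 * 100)
    msg <- c(msg, "fsRaw must exceed twice the 100 Hz band-pass upper edge")
  if (object@nChannels < object@nSources)
    msg <- c(msg, "nChannels must be >= nSources")
  if (object@nSources < 3L)
    msg <- c(msg, "nSources must be >= 3 (task, blink, cardiac)")
  if (!(object@taskAmpWatch > 0 && object@taskAmpWatch <= 1))
    msg <- c(msg, "taskAmpWatch must be in (0, 1] as a fraction of taskAmpFly")
  if (!(object@peakLatencyMs >= 190 && object@peakLatencyMs <= 290))
    msg <- c(msg, "peakLatencyMs must lie in [190, 290] (and hence < 300)")
  if (object@rtMeanSimpleMs <= object@peakLatencyMs ||
      object@rtMeanComplexMs <= object@peakLatencyMs)
    msg <- c(msg, "reaction-time means must exceed peakLatencyMs")
  if (object@taskAmpFly < 0 || object@motorRampAmp < 0)
    msg <- c(msg, "amplitudes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn SubjectConfig-class Constructor; any slot can be overridden by
#'   name, everything else keeps its default.
#' @param ... named slot overrides, e.g. `subjectConfig(seed = 7L)`.
#' @export
subjectConfig <- function(...) {
  args <- list(...)
  for (nm in c("nChannels", "nSources", "seed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SubjectConfig"), args))
}

#' One recorded (or simulated) session
#'
#' Per-trial multichannel sensor traces together with the trial metadata
#' table. Traces are stored per trial as a fixed window around the real or
#' virtual perturbation onset (`traceStartMs` gives the time of the first
#' sample relative to onset), which preserves the online framing: filtering
#' is applied causally to these continuous traces before epoching.
#'
#' @slot sensors numeric array, trials x channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot traceStartMs time of the first stored sample relative to onset, ms.
#' @slot meta trial metadata: `sessionId`, `trialIndex`, `task`, `condition`,
#'   `perturbationOnsetS`, `manualRtMs`, `badFlag`, `descentRateMps`.
#' @slot sessionTag one of `train`, `test_simple`, `test_complex`.
#' @slot groundTruth list with `mixing`, `taskSourceIndex`, `trueLabels` and
#'   optionally `sourceTraces` (synthetic data only), or empty list for real
#'   recordings.
#' @slot seed integer seed the session was generated with (NA for real data).
#' @export
setClass("SessionData",
  representation(
    sensors = "array", fs = "numeric", traceStartMs = "numeric",
    meta = "data.frame", sessionTag = "character",
    groundTruth = "list", seed = "integer"))

setValidity("SessionData", function(object) {
  msg <- character()
  d <- dim(object@sensors)
  if (length(d) != 3L)
    msg <- c(msg, "sensors must be a trials x channels x samples array")
  if (length(d) == 3L && d[1] != nrow(object@meta))
    msg <- c(msg, "sensor trial count does not match metadata row count")
  need <- c("sessionId", "trialIndex", "task", "condition",
            "perturbationOnsetS", "manualRtMs", "badFlag", "descentRateMps")
  miss <- setdiff(need, names(object@meta))
  if (length(miss))
    msg <- c(msg, paste("metadata lacks column(s):", paste(miss, collapse = ", ")))
  if (!length(miss) && any(!is.na(object@meta$manualRtMs) &
                           object@meta$manualRtMs <= 0))
    msg <- c(msg, "manualRtMs must be positive where present")
  if (!length(miss) && any(is.na(object@meta$perturbationOnsetS)))
    msg <- c(msg, "every trial needs a real or virtual perturbation onset")
  if (length(msg)) msg else TRUE
})

#' Epoched data in sensor or component space
#'
#' Trials x channels (or components) x 500 samples at 250 Hz on the standard
#' epoch grid (see [epochTimes()]), with the screened metadata and the
#' screening log that records every dropped trial and its reason.
#'
#' @slot data numeric array, trials x channels/components x 500.
#' @slot fs sampling rate (250 Hz).
#' @slot space `"sensor"` or `"component"`.
#' @slot meta metadata of the retained trials.
#' @slot screeningLog data.frame with `trialIndex`, `kept`, `reason`.
#' @export
setClass("EpochArray",
  representation(data = "array", fs = "numeric", space = "character",
                 meta = "data.frame", screeningLog = "data.frame"))

setValidity("EpochArray", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != EPOCH_N)
    msg <- c(msg, sprintf("epochs must be trials x channels x %d samples", EPOCH_N))
  if (length(d) == 3L && d[1] != nrow(object@meta))
    msg <- c(msg, "epoch trial count does not match metadata row count")
  if (object@fs != EPOCH_FS)
    msg <- c(msg, sprintf("epoch sampling rate must be %d Hz", EPOCH_FS))
  if (!object@space %in% c("sensor", "component"))
    msg <- c(msg, "space must be 'sensor' or 'component'")
  if (length(msg)) msg else TRUE
})

#' PCA + Infomax ICA unmixing model
#'
#' Fitted on the two training sessions only and then applied with frozen
#' weights to held-out sessions, mirroring online use. The combined weights
#' satisfy `combinedWeights == icaUnmixing %*% pcaMatrix` (the PCA matrix
#' includes whitening), and after task-component selection the selected row
#' is sign-fixed so the evoked peak is positive.
#'
#' @slot pcaMatrix components x channels whitening matrix.
#' @slot icaUnmixing components x components ICA rotation.
#' @slot combinedWeights components x channels; applied to centered sensors.
#' @slot channelMean per-channel mean removed before projection.
#' @slot selectedComponent index of the evoked task component (NA before
#'   selection).
#' @slot selectionScores per-component peak-to-baseline score table.
#' @slot varianceExplained fraction of sensor variance retained by the PCA.
#' @slot sessionsUsed,seed,sweeps fit provenance.
#' @export
setClass("UnmixingModel",
  representation(
    pcaMatrix = "matrix", icaUnmixing = "matrix", combinedWeights = "matrix",
    channelMean = "numeric", selectedComponent = "integer",
    selectionScores = "data.frame", varianceExplained = "numeric",
    sessionsUsed = "character", seed = "integer", sweeps = "integer"))

setValidity("UnmixingModel", function(object) {
  msg <- character()
  cw <- object@icaUnmixing %*% object@pcaMatrix
  if (max(abs(cw - object@combinedWeights)) > 1e-8 * max(1, max(abs(cw))))
    msg <- c(msg, "combinedWeights must equal icaUnmixing %*% pcaMatrix")
  if (ncol(object@pcaMatrix) != length(object@channelMean))
    msg <- c(msg, "channelMean length must match channel count")
  if (length(msg)) msg else TRUE
})

#' Least-squares probabilistic classifier (LSPC)
#'
#' Gaussian-kernel model of the class-posterior probability whose weights
#' have a closed-form regularized least-squares solution. Every training
#' point is a kernel center; feature normalization statistics come from the
#' training set only and are frozen into the decoder.
#'
#' @slot centers n x 3 matrix of z-normalized training feature vectors.
#' @slot weights n x 2 matrix of per-class kernel weights.
#' @slot sigma Gaussian kernel width (on the z-normalized scale).
#' @slot rho ridge regularization strength.
#' @slot classes class labels, `c("intend", "passive")`.
#' @slot featMean,featSd training-set feature normalization.
#' @slot anchorMs evoked-peak anchor time used for feature extraction, ms.
#' @slot foldSeed integer seed of the cross-validation fold assignment.
#' @slot cvLoss cross-validated log-loss of the selected hyperparameters.
#' @export
setClass("LspcDecoder",
  representation(
    centers = "matrix", weights = "matrix", sigma = "numeric", rho = "numeric",
    classes = "character", featMean = "numeric", featSd = "numeric",
    anchorMs = "numeric", foldSeed = "integer", cvLoss = "numeric"))

setValidity("LspcDecoder", function(object) {
  msg <- character()
  if (nrow(object@centers) != nrow(object@weights))
    msg <- c(msg, "one weight row per kernel center is required")
  if (ncol(object@weights) != length(object@classes))
    msg <- c(msg, "one weight column per class is required")
  if (object@sigma <= 0 || object@rho < 0)
    msg <- c(msg, "sigma must be positive and rho non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-session detection outcome summary
#'
#' One row per screened trial plus the aggregate accounting used in the
#' time-savings analysis: confusion counts, original vs. BCI-assisted
#' response-time means, and altitude savings implied by the descent rate.
#'
#' @slot outcomes data.frame with `trialIndex`, `detectionMs`, `manualRtMs`,
#'   `outcome` (hit/miss/false_alarm/correct_rejection), `effectiveRtMs`,
#'   `savingsMs`.
#' @slot confusion named counts `tp`, `fn`, `fp`, `tn`.
#' @slot stats named list: `orgMeanMs`, `orgSeMs`, `bciMeanMs`, `bciSeMs`,
#'   `diffMeanMs`, `diffSeMs`, `descentRateMeanMps`, `descentRateGreatestMps`,
#'   `altitudeSavingsMeanM`, `altitudeSavingsGreatestM`.
#' @export
setClass("SavingsSummary",
  representation(outcomes = "data.frame", confusion = "numeric",
                 stats = "list"))

setValidity("SavingsSummary", function(object) {
  msg <- character()
  if (!all(c("tp", "fn", "fp", "tn") %in% names(object@confusion)))
    msg <- c(msg, "confusion must contain tp, fn, fp, tn")
  oc <- object@outcomes$outcome
  if (!is.null(oc)) {
    npert <- sum(oc %in% c("hit", "miss"))
    nnop <- sum(oc %in% c("false_alarm", "correct_rejection"))
    if (npert != object@confusion[["tp"]] + object@confusion[["fn"]])
      msg <- c(msg, "tp + fn must equal the perturbation-trial count")
    if (nnop != object@confusion[["fp"]] + object@confusion[["tn"]])
      msg <- c(msg, "fp + tn must equal the no-perturbation-trial count")
  }
  if (length(msg)) msg else TRUE
})
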