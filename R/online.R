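# Simulated real-time decoding of the complex session: a 120 ms window
# advanced in 8 ms steps through the first second after (virtual) onset,
# the faster-than-hand adjudication rule, and time/altitude-savings
# accounting.

#' Sliding-window detection on one trial
#'
#' Slides a 120 ms window (three consecutive 40 ms RMS features) in 8 ms
#' steps through the trial. The window ending at t covers \[t-120, t) ms, so
#' the earliest possible detection is at t = 120 ms and the last window ends
#' at 1000 ms. Detection fires at the end of the first window classified as
#' `intend` (or, with `kConsecutive` > 1, at the end of the k-th of the
#' first k consecutive `intend` windows).
#'
#' @param decoder an [LspcDecoder-class].
#' @param componentTrace numeric vector of 500 samples (selected component,
#'   standard epoch grid).
#' @param spanMs scan span post-onset, default `c(0, 1000)` ms.
#' @param windowMs decoder window (default 120 ms).
#' @param stepMs step between window ends (default 8 ms).
#' @param kConsecutive number of consecutive `intend` windows required
#'   (default 1).
#' @return detection time in ms (window end), or `NA_real_` if no window
#'   fires.
#' @export
slidingDetect <- function(decoder, componentTrace, spanMs = c(0, 1000),
                          windowMs = 120, stepMs = 8, kConsecutive = 1L) {
  stopifnot(length(componentTrace) == EPOCH_N)
  ends <- seq(spanMs[1] + windowMs, spanMs[2], by = stepMs)
  if (max(ends) > max(epochTimes()) + EPOCH_STEP_MS || min(ends) - windowMs < min(epochTimes()))
    stop("trace shorter than the requested scan span")
  F <- slidingFeatureMatrix(componentTrace, ends)
  P <- predictPosterior(decoder, F)
  intend <- P[, "intend"] > 0.5
  if (kConsecutive > 1L) {
    r <- rle(intend)
    hitRun <- which(r$values & r$lengths >= kConsecutive)
    if (!length(hitRun)) return(NA_real_)
    first <- sum(r$lengths[seq_len(hitRun[1] - 1L)]) + kConsecutive
    return(ends[first])
  }
  if (!any(intend)) return(NA_real_)
  ends[which(intend)[1]]
}

# Batched sliding detection over many trials: identical to slidingDetect on
# each row, but classifies every window of every trial in one kernel
# evaluation.
slidingDetectBatch <- function(decoder, acts, spanMs = c(0, 1000),
                               windowMs = 120, stepMs = 8, kConsecutive = 1L) {
  nTr <- nrow(acts)
  ends <- seq(spanMs[1] + windowMs, spanMs[2], by = stepMs)
  if (max(ends) > max(epochTimes()) + EPOCH_STEP_MS ||
      min(ends) - windowMs < min(epochTimes()))
    stop("trace shorter than the requested scan span")
  nW <- length(ends)
  F <- matrix(0, nTr * nW, 3)
  for (j in seq_len(nW)) {
    a <- ends[j] - 40
    i0 <- msToEpochIdx(c(a - 80, a - 40, a))
    rows <- (j - 1L) * nTr + seq_len(nTr)
    for (w in 1:3)
      F[rows, w] <- sqrt(rowMeans(acts[, i0[w]:(i0[w] + 9L), drop = FALSE]^2))
  }
  P <- predictPosterior(decoder, F)
  intend <- matrix(P[, "intend"] > 0.5, nTr, nW)   # trials x windows
  vapply(seq_len(nTr), function(i) {
    v <- intend[i, ]
    if (kConsecutive > 1L) {
      r <- rle(v)
      hitRun <- which(r$values & r$lengths >= kConsecutive)
      if (!length(hitRun)) return(NA_real_)
      return(ends[sum(r$lengths[seq_len(hitRun[1] - 1L)]) + kConsecutive])
    }
    if (!any(v)) return(NA_real_)
    ends[which(v)[1]]
  }, numeric(1))
}

# Features for all window ends at once: window ending at t is the feature
# block anchored at t - 40 (windows [t-120,t-80), [t-80,t-40), [t-40,t)).
slidingFeatureMatrix <- function(componentTrace, endsMs) {
  F <- matrix(0, length(endsMs), 3)
  for (j in seq_along(endsMs)) {
    a <- endsMs[j] - 40
    i0 <- msToEpochIdx(c(a - 80, a - 40, a))
    F[j, ] <- c(rmsOf(componentTrace[i0[1]:(i0[1] + 9L)]),
                rmsOf(componentTrace[i0[2]:(i0[2] + 9L)]),
                rmsOf(componentTrace[i0[3]:(i0[3] + 9L)]))
  }
  F
}

#' Adjudicate a complex session and account the savings
#'
#' Runs [slidingDetect()] on every screened trial. A perturbation trial is
#' a hit only if the decoder fires strictly before the manual control-stick
#' response; a detection after the stick moved, or none at all, is a miss,
#' in which case automation is not engaged and the original reaction time
#' stands (zero savings). No-perturbation trials are scanned over the same
#' span anchored at the virtual onset; any detection is a false alarm,
#' otherwise a correct rejection. The mean response-time difference is
#' averaged over all perturbation trials (misses contribute zero), and
#' altitude savings are the descent rate times the time savings.
#'
#' @param decoder an [LspcDecoder-class].
#' @param componentEpochs component-space [EpochArray-class] of the complex
#'   session (screened), or a trials x 500 activation matrix.
#' @param meta metadata aligned with the activations (needed when a bare
#'   matrix is given).
#' @param componentIndex which component row to use when an [EpochArray-class]
#'   is given (defaults to the decoder's training component via the caller).
#' @param ... passed to [slidingDetect()].
#' @return a [SavingsSummary-class].
#' @export
adjudicateSession <- function(decoder, componentEpochs, meta = NULL,
                              componentIndex = NULL, ...) {
  if (is(componentEpochs, "EpochArray")) {
    stopifnot(!is.null(componentIndex))
    acts <- componentEpochs@data[, componentIndex, , drop = TRUE]
    if (is.null(dim(acts))) acts <- matrix(acts, nrow = 1)
    meta <- componentEpochs@meta
  } else {
    acts <- componentEpochs
    stopifnot(!is.null(meta), nrow(acts) == nrow(meta))
  }
  nTr <- nrow(acts)
  det <- slidingDetectBatch(decoder, acts, ...)
  pert <- grepl("_perturbation$", meta$condition) &
    !grepl("noperturbation", meta$condition)
  rt <- meta$manualRtMs
  outcome <- character(nTr)
  outcome[pert] <- ifelse(!is.na(det[pert]) & det[pert] < rt[pert], "hit", "miss")
  outcome[!pert] <- ifelse(!is.na(det[!pert]), "false_alarm", "correct_rejection")
  hit <- outcome == "hit"
  effective <- ifelse(pert, ifelse(hit, det, rt), NA_real_)
  savings <- ifelse(pert, ifelse(hit, rt - det, 0), NA_real_)
  out <- data.frame(trialIndex = meta$trialIndex, detectionMs = det,
                    manualRtMs = rt, outcome = outcome,
                    effectiveRtMs = effective, savingsMs = savings,
                    stringsAsFactors = FALSE)
  conf <- c(tp = sum(outcome == "hit"), fn = sum(outcome == "miss"),
            fp = sum(outcome == "false_alarm"),
            tn = sum(outcome == "correct_rejection"))
  rtP <- rt[pert]; effP <- effective[pert]; savP <- savings[pert]
  drP <- meta$descentRateMps[pert]
  stats <- list(
    orgMeanMs = mean(rtP), orgSeMs = standardError(rtP),
    bciMeanMs = mean(effP), bciSeMs = standardError(effP),
    diffMeanMs = mean(savP), diffSeMs = standardError(savP),
    descentRateMeanMps = mean(drP), descentRateGreatestMps = max(drP),
    altitudeSavingsMeanM = altitudeSavings(mean(drP), mean(savP)),
    altitudeSavingsGreatestM = altitudeSavings(max(drP), mean(savP)))
  new("SavingsSummary", outcomes = out, confusion = conf, stats = stats)
}

#' Altitude saved by earlier recovery
#'
#' Meters of descent avoided when recovery starts `savingsMs` earlier at a
#' given descent rate: `descentRateMps * savingsMs / 1000`.
#'
#' @param descentRateMps descent rate in m/s (non-negative).
#' @param savingsMs time savings in ms (non-negative).
#' @return altitude savings in meters (report to 0.1 m).
#' @export
altitudeSavings <- function(descentRateMps, savingsMs) {
  if (any(descentRateMps < 0) || any(savingsMs < 0))
    stop("descent rate and savings must be non-negative")
  descentRateMps * savingsMs / 1000
}
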