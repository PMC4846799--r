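# Causal filtering, decimation, epoching and bad-trial screening. The
# filter runs forward-only over the continuous per-trial traces (online
# framing); epochs are cut from the decimated data on the fixed
# [-1000, +1000) ms grid.

#' Causal Butterworth band-pass filter
#'
#' Forward-only (causal) IIR filtering, the online filter of the recording
#' chain: 2--100 Hz by default. The DC component is rejected by the
#' high-pass edge; output length equals input length and nothing before an
#' input sample can influence the output at that sample.
#'
#' @param trace numeric vector, or channels x samples matrix (each row is
#'   filtered independently).
#' @param lowHz,highHz band edges in Hz.
#' @param order total band-pass filter order (even; default 4).
#' @param fs sampling rate in Hz; must exceed `2 * highHz`.
#' @return filtered trace with the same shape as the input.
#' @export
causalBandpass <- function(trace, lowHz = 2, highHz = 100, order = 4, fs = 1000) {
  if (fs <= 2 * highHz)
    stop("sampling rate ", fs, " Hz must exceed twice the upper band edge")
  if (order %% 2 != 0 || order < 2)
    stop("order must be a positive even number (band-pass sections come in pairs)")
  bf <- signal::butter(order / 2, c(lowHz, highHz) / (fs / 2), type = "pass")
  # refuse an unstable design rather than silently reducing the order
  if (any(Mod(polyroot(rev(bf$a))) >= 1 + 1e-8))
    stop("unstable Butterworth design at order ", order, " for fs ", fs,
         " Hz; choose a different order")
  if (is.matrix(trace)) {
    out <- trace
    for (r in seq_len(nrow(trace)))
      out[r, ] <- as.numeric(signal::filter(bf, trace[r, ]))
    out
  } else {
    as.numeric(signal::filter(bf, trace))
  }
}

#' Decimate a band-limited trace
#'
#' Keeps every `fsIn/fsOut`-th sample, starting at the first. The caller
#' must have low-passed the trace below `fsOut / 2` already (the 100 Hz
#' band-pass edge sits below the 125 Hz Nyquist of the 250 Hz target), so
#' no additional anti-aliasing filter is applied.
#'
#' @param trace numeric vector or channels x samples matrix.
#' @param fsIn,fsOut input and output sampling rates; `fsIn` must be an
#'   integer multiple of `fsOut`.
#' @return decimated trace.
#' @export
decimateTrace <- function(trace, fsIn = 1000, fsOut = 250) {
  fac <- fsIn / fsOut
  if (abs(fac - round(fac)) > 1e-9)
    stop("fsIn (", fsIn, ") must be an integer multiple of fsOut (", fsOut, ")")
  fac <- as.integer(round(fac))
  if (is.matrix(trace)) trace[, seq(1, ncol(trace), by = fac), drop = FALSE]
  else trace[seq(1, length(trace), by = fac)]
}

#' Filter, decimate, epoch and screen one session
#'
#' Applies the causal band-pass to every continuous trial trace, decimates
#' 1000 to 250 Hz, cuts the standard \[-1000, +1000) ms epoch around the
#' (virtual) perturbation onset, and screens bad trials: simple-task trials
#' are dropped on `machine_failure` or a reaction time slower than
#' `slowRtCutoffMs`; complex-task trials are dropped only when the plane
#' crashed before the perturbation onset (post-onset crashes stay in the
#' analysis). Every drop is recorded with its reason in the screening log;
#' trials whose onset sits too close to the trace edge for a full epoch are
#' dropped, never padded.
#'
#' @param session a [SessionData-class] at the raw sampling rate.
#' @param lowHz,highHz,order band-pass settings, see [causalBandpass()].
#' @param slowRtCutoffMs simple-task reaction-time cutoff (default 700 ms).
#' @return an [EpochArray-class] in sensor space.
#' @export
segmentAndScreen <- function(session, lowHz = 2, highHz = 100, order = 4,
                             slowRtCutoffMs = 700) {
  stopifnot(is(session, "SessionData"))
  meta <- session@meta
  fs <- session@fs
  fac <- fs / EPOCH_FS
  nTr <- nrow(meta)
  reason <- rep(NA_character_, nTr)
  simple <- meta$task == "simple"
  reason[simple & meta$badFlag == "machine_failure"] <- "machine_failure"
  slow <- simple & ((!is.na(meta$manualRtMs) & meta$manualRtMs > slowRtCutoffMs) |
                      meta$badFlag == "slow_rt")
  reason[slow & is.na(reason)] <- "slow_rt"
  reason[!simple & meta$badFlag == "pre_onset_crash"] <- "pre_onset_crash"

  onsetIdxDec <- round(-session@traceStartMs / 1000 * EPOCH_FS) + 1L
  nDec <- ceiling(dim(session@sensors)[3] / fac)
  lo <- onsetIdxDec - (EPOCH_ONSET_IDX - 1L)
  hi <- onsetIdxDec + (EPOCH_N - EPOCH_ONSET_IDX)
  if (lo < 1L || hi > nDec)
    reason[is.na(reason)] <- "incomplete_epoch"

  keep <- which(is.na(reason))
  nCh <- dim(session@sensors)[2]
  epochs <- array(0, dim = c(length(keep), nCh, EPOCH_N))
  for (j in seq_along(keep)) {
    x <- causalBandpass(session@sensors[keep[j], , ], lowHz, highHz, order, fs)
    x <- decimateTrace(x, fs, EPOCH_FS)
    epochs[j, , ] <- x[, lo:hi]
  }
  log <- data.frame(trialIndex = meta$trialIndex,
                    kept = is.na(reason),
                    reason = ifelse(is.na(reason), "", reason),
                    stringsAsFactors = FALSE)
  new("EpochArray", data = epochs, fs = EPOCH_FS, space = "sensor",
      meta = meta[keep, , drop = FALSE], screeningLog = log)
}

# Concatenate the trials of several epoch arrays (same channel count).
bindEpochs <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is(parts[[1]], "EpochArray"))
    parts <- parts[[1]]
  stopifnot(all(vapply(parts, is, logical(1), "EpochArray")))
  nCh <- unique(vapply(parts, function(p) dim(p@data)[2], numeric(1)))
  if (length(nCh) != 1L) stop("epoch arrays have differing channel counts")
  dat <- array(0, dim = c(sum(vapply(parts, nTrials, numeric(1))), nCh, EPOCH_N))
  at <- 0L
  for (p in parts) {
    if (nTrials(p)) dat[at + seq_len(nTrials(p)), , ] <- p@data
    at <- at + nTrials(p)
  }
  meta <- do.call(rbind, lapply(parts, function(p) p@meta))
  log <- do.call(rbind, lapply(parts, function(p) p@screeningLog))
  rownames(meta) <- NULL
  new("EpochArray", data = dat, fs = EPOCH_FS, space = parts[[1]]@space,
      meta = meta, screeningLog = log)
}
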