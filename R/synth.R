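# Synthetic subject generator. Emulates the recording protocol of the
# flight-perturbation study: three simple-task sessions (two for training,
# one held out) and one complex-task session per subject, 1000 Hz sensor
# traces built as mixing %*% sources + noise, with ground truth retained so
# recovery can be validated.

TRACE_PRE_MS <- 1600   # stored trace starts 1600 ms before onset
TRACE_POST_MS <- 1200  # and ends 1200 ms after

# Condition mix of the simple task: participants chose piloting twice as
# often as passive viewing, and 67% of trials carried a perturbation, giving
# on average 40/20/20/10 trials of fly_pert / fly_nopert / watch_pert /
# watch_nopert out of 90.
SIMPLE_N_TRIALS <- 90L
COMPLEX_N_PERT <- 60L
COMPLEX_N_NOPERT <- 30L
P_FLY <- 2 / 3
P_PERT <- 0.67

#' Random source-to-sensor mixing matrix
#'
#' Columns are smooth pseudo-topographies: each source projects onto the
#' (virtual, planar) sensor array as a difference of two spatial Gaussians,
#' which stands in for the dipolar field patterns of head/sensor geometry.
#' Columns are unit-norm and pairwise correlated below 0.5 in absolute
#' value (sources occupy distinct patches, as cortical generators with
#' separable fields do); the matrix has full column rank.
#'
#' @param nChannels,nSources dimensions; `nChannels >= nSources >= 3`.
#' @param seed integer seed; identical arguments give a bit-identical matrix.
#' @return `nChannels` x `nSources` numeric matrix.
#' @export
makeMixing <- function(nChannels, nSources, seed) {
  if (nSources > nChannels)
    stop("invalid configuration: nSources (", nSources,
         ") exceeds nChannels (", nChannels, ")")
  if (nSources < 3L) stop("invalid configuration: need nSources >= 3")
  withSeed(deriveSeed(seed, "mixing"), {
    side <- ceiling(sqrt(nChannels))
    pos <- cbind((seq_len(nChannels) - 1) %% side,
                 (seq_len(nChannels) - 1) %/% side) / max(1, side - 1)
    drawCol <- function() {
      c1 <- runif(2); c2 <- c1 + rnorm(2, 0, 0.35)
      w1 <- runif(1, 0.15, 0.35); w2 <- runif(1, 0.15, 0.35)
      d1 <- rowSums((pos - rep(c1, each = nChannels))^2)
      d2 <- rowSums((pos - rep(c2, each = nChannels))^2)
      g <- exp(-d1 / (2 * w1^2)) - 0.7 * exp(-d2 / (2 * w2^2)) +
        rnorm(nChannels, 0, 0.05)
      g / sqrt(sum(g^2))
    }
    A <- matrix(0, nChannels, nSources)
    for (j in seq_len(nSources)) {
      for (attempt in seq_len(200)) {
        cand <- drawCol()
        ok <- j == 1L ||
          max(abs(stats::cor(cand, A[, seq_len(j - 1L), drop = FALSE]))) < 0.5
        if (ok) { A[, j] <- cand; break }
        if (attempt == 200) stop("could not draw a sufficiently distinct topography")
      }
    }
    if (qr(A)$rank < nSources) stop("mixing matrix is rank deficient")
    A
  })
}

#' Biphasic evoked-response template
#'
#' A smooth biphasic transient (positive lobe followed by a smaller negative
#' rebound) whose absolute extremum sits at `peakLatencyMs` to within one
#' sample and equals `amplitude` exactly. The waveform starts at the
#' perturbation onset (t = 0); there is no pre-onset support.
#'
#' @param peakLatencyMs peak latency in ms, must lie in (0, 300).
#' @param widthMs width (SD * 2) of the main lobe in ms.
#' @param amplitude peak absolute amplitude; 0 gives an all-zero waveform.
#' @param fs sampling rate in Hz.
#' @param durationMs template length in ms (default 1000).
#' @return numeric vector of `round(durationMs * fs / 1000)` samples; sample
#'   i (1-based) is at time (i - 1) / fs seconds after onset.
#' @export
makeEvokedTemplate <- function(peakLatencyMs, widthMs, amplitude, fs,
                               durationMs = 1000) {
  if (!(peakLatencyMs > 0 && peakLatencyMs < 300))
    stop("invalid configuration: peakLatencyMs must lie in (0, 300)")
  if (widthMs <= 0) stop("invalid configuration: widthMs must be positive")
  if (peakLatencyMs >= durationMs)
    stop("invalid configuration: peak lies beyond the template duration")
  n <- round(durationMs * fs / 1000)
  if (amplitude == 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs * 1000
  s1 <- widthMs / 2
  w <- exp(-(t - peakLatencyMs)^2 / (2 * s1^2)) -
    0.25 * exp(-(t - (peakLatencyMs + 2.5 * widthMs))^2 / (2 * (1.4 * widthMs)^2))
  w <- w * (amplitude / max(abs(w)))
  # snap the extremum onto the nominal sample in case the rebound lobe
  # nudged it off by a sample
  target <- round(peakLatencyMs * fs / 1000) + 1L
  k <- which.max(abs(w))
  if (k != target) {
    shift <- target - k
    w <- if (shift > 0) c(numeric(shift), w[seq_len(n - shift)])
         else c(w[(1 - shift):n], numeric(-shift))
  }
  w
}

# Band-limited noise with a slow lognormal burst envelope; the bursts make
# background sources super-Gaussian, which is the regime Infomax ICA with a
# logistic nonlinearity separates.
burstyNarrowband <- function(n, fs, loHz, hiHz, rmsTarget) {
  bf <- signal::butter(2, c(loHz, hiHz) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, rnorm(n)))
  slow <- as.numeric(stats::filter(rnorm(n), 0.995, method = "recursive"))
  env <- exp(slow / (2 * stats::sd(slow)))
  x <- x * env
  x * (rmsTarget / rmsOf(x))
}

smoothNarrowband <- function(n, fs, loHz, hiHz, rmsTarget) {
  bf <- signal::butter(2, c(loHz, hiHz) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, rnorm(n)))
  x * (rmsTarget / rmsOf(x))
}

blinkTrace <- function(n, fs, ratePerMin) {
  x <- numeric(n)
  nEvents <- rpois(1, ratePerMin / 60 * n / fs)
  if (nEvents == 0) return(x)
  bumpN <- round(0.3 * fs)
  bump <- 6 * (0.5 - 0.5 * cos(2 * pi * seq_len(bumpN) / (bumpN + 1)))
  starts <- sort(sample.int(n, nEvents, replace = TRUE))
  for (s in starts) {
    idx <- s:min(n, s + bumpN - 1L)
    x[idx] <- x[idx] + bump[seq_along(idx)]
  }
  x
}

cardiacTrace <- function(n, fs, rateHz) {
  x <- numeric(n)
  period <- fs / rateHz
  beatN <- round(0.06 * fs)
  tb <- seq_len(beatN) - beatN / 2
  beat <- 3 * (-tb) * exp(-tb^2 / (2 * (beatN / 6)^2))
  beat <- beat / max(abs(beat)) * 3
  t0 <- runif(1, 0, period)
  sq <- seq(t0, n, by = period)
  starts <- round(sq + rnorm(length(sq), 0, 0.02 * period))
  for (s in starts[starts >= 1 & starts <= n]) {
    idx <- s:min(n, s + beatN - 1L)
    x[idx] <- x[idx] + beat[seq_along(idx)]
  }
  x
}

motorRampTrace <- function(n, fs, rtMs, amp, onsetIdx) {
  # readiness-like ramp rising over the 250 ms before the manual response and
  # releasing over 150 ms afterwards
  x <- numeric(n)
  if (amp == 0 || is.na(rtMs)) return(x)
  riseN <- round(0.25 * fs); decayN <- round(0.15 * fs)
  rtIdx <- onsetIdx + round(rtMs / 1000 * fs)
  rise <- 0.5 - 0.5 * cos(pi * seq_len(riseN) / riseN)
  decay <- 0.5 + 0.5 * cos(pi * seq_len(decayN) / decayN)
  shape <- c(rise, decay) * amp
  start <- rtIdx - riseN
  idx <- start:min(n, start + length(shape) - 1L)
  keep <- idx >= 1
  x[idx[keep]] <- shape[seq_along(idx)][keep]
  x
}

# Build sensor traces for one session given per-trial metadata.
buildSessionArray <- function(config, meta, task, seed) {
  nTr <- nrow(meta)
  fs <- config@fsRaw
  n <- round((TRACE_PRE_MS + TRACE_POST_MS) / 1000 * fs)
  onsetIdx <- round(TRACE_PRE_MS / 1000 * fs) + 1L
  nCh <- config@nChannels
  nSrc <- config@nSources
  # the mixing is a property of the subject (head/sensor geometry), shared by
  # all of the subject's sessions so that training-session weights transfer
  A <- makeMixing(nCh, nSrc, config@seed)
  nBg <- nSrc - 3L
  bgBands <- matrix(rep(c(8, 12, 18, 22, 5, 9, 14, 18, 11, 15), length.out = 2 * max(1, nBg)),
                    ncol = 2, byrow = TRUE)
  sensors <- array(0, dim = c(nTr, nCh, n))
  sources <- array(0, dim = c(nTr, nSrc, n))
  withSeed(deriveSeed(seed, "traces"), {
    for (i in seq_len(nTr)) {
      S <- matrix(0, nSrc, n)
      cond <- meta$condition[i]
      pert <- grepl("_perturbation$", cond) && !grepl("noperturbation", cond)
      piloting <- grepl("^(fly|complex)", cond)
      # task source
      if (pert) {
        lat <- min(290, max(190, config@peakLatencyMs +
                              rnorm(1, 0, config@latencyJitterMs)))
        amp <- if (piloting) config@taskAmpFly else
          config@taskAmpFly * config@taskAmpWatch
        # single-trial evoked amplitude varies lognormally around its mean,
        # the dominant source of misses in real recordings
        if (config@amplitudeJitterSd > 0)
          amp <- amp * exp(rnorm(1, -config@amplitudeJitterSd^2 / 2,
                                 config@amplitudeJitterSd))
        tpl <- makeEvokedTemplate(lat, 40, amp, fs, TRACE_POST_MS)
        S[1, onsetIdx:n] <- S[1, onsetIdx:n] + tpl[seq_len(n - onsetIdx + 1L)]
      }
      if (piloting && !is.na(meta$manualRtMs[i]))
        S[1, ] <- S[1, ] + motorRampTrace(n, fs, meta$manualRtMs[i],
                                          config@motorRampAmp * config@taskAmpFly,
                                          onsetIdx)
      if (task == "complex" && config@complexMotorPower > 0)
        S[1, ] <- S[1, ] + smoothNarrowband(n, fs, 4, 12, config@complexMotorPower)
      # artifacts
      S[2, ] <- blinkTrace(n, fs, config@blinkRatePerMin)
      S[3, ] <- cardiacTrace(n, fs, config@cardiacHz)
      # ongoing background
      for (k in seq_len(nBg)) {
        S[3L + k, ] <- burstyNarrowband(n, fs, bgBands[k, 1], bgBands[k, 2],
                                        config@backgroundPower)
        if (task == "complex" && config@complexMotorPower > 0)
          S[3L + k, ] <- S[3L + k, ] +
            smoothNarrowband(n, fs, 4, 12, 0.3 * config@complexMotorPower)
      }
      X <- A %*% S
      X <- X + matrix(rnorm(nCh * n, 0, config@noiseSd), nCh, n)
      if (config@noiseSd > 0) {
        pink <- matrix(rnorm(nCh * n), nCh, n)
        pink <- t(apply(pink, 1, function(r)
          as.numeric(stats::filter(r, 0.98, method = "recursive"))))
        pink <- pink * (0.3 * config@noiseSd / apply(pink, 1, stats::sd))
        X <- X + pink
      }
      sensors[i, , ] <- X
      sources[i, , ] <- S
    }
  })
  list(sensors = sensors, sources = sources, mixing = A)
}

#' Simulate one simple-task session
#'
#' Ninety trials with the study's condition mix (on average 40 active-
#' piloting perturbation, 20 active no-perturbation, 20 passive-viewing
#' perturbation and 10 passive no-perturbation trials; the realized counts
#' vary because the fly/watch choice and the perturbation are drawn per
#' trial). The perturbation onset is uniform in \[2, 4\] s of the trial;
#' no-perturbation trials receive a virtual onset the same way, mirroring
#' the photodiode convention. Active perturbation trials carry the evoked
#' template at the fly amplitude plus a pre-movement motor ramp ending at
#' the manual reaction time; passive perturbation trials carry the reduced
#' watch amplitude and no ramp.
#'
#' @param config a [SubjectConfig-class].
#' @param sessionIndex session number (1-3).
#' @param seed integer seed.
#' @return a [SessionData-class] with ground truth attached.
#' @export
simulateSimpleSession <- function(config, sessionIndex, seed) {
  validObject(config)
  meta <- withSeed(deriveSeed(seed, "meta"), {
    fly <- runif(SIMPLE_N_TRIALS) < P_FLY
    pert <- runif(SIMPLE_N_TRIALS) < P_PERT
    condition <- paste0(ifelse(fly, "fly", "watch"),
                        ifelse(pert, "_perturbation", "_noperturbation"))
    onset <- runif(SIMPLE_N_TRIALS, 2, 4)
    rt <- rep(NA_real_, SIMPLE_N_TRIALS)
    act <- fly & pert
    rt[act] <- rtruncnorm(sum(act), config@rtMeanSimpleMs, config@rtSdMs, 200, 700)
    bad <- rep("ok", SIMPLE_N_TRIALS)
    bad[runif(SIMPLE_N_TRIALS) < 0.015] <- "machine_failure"
    bad[!is.na(rt) & rt > 700] <- "slow_rt"
    dr <- rtruncnorm(SIMPLE_N_TRIALS, config@descentRateMeanMps,
                     config@descentRateSdMps, 20,
                     config@descentRateMeanMps + 6 * config@descentRateSdMps)
    data.frame(sessionId = sprintf("S%d_simple", sessionIndex),
               trialIndex = seq_len(SIMPLE_N_TRIALS), task = "simple",
               condition = condition, perturbationOnsetS = onset,
               manualRtMs = rt, badFlag = bad, descentRateMps = dr,
               stringsAsFactors = FALSE)
  })
  built <- buildSessionArray(config, meta, "simple", deriveSeed(seed, "array"))
  new("SessionData", sensors = built$sensors, fs = config@fsRaw,
      traceStartMs = -TRACE_PRE_MS, meta = meta,
      sessionTag = if (sessionIndex <= 2) "train" else "test_simple",
      groundTruth = list(mixing = built$mixing, taskSourceIndex = 1L,
                         trueLabels = meta$condition,
                         sourceTraces = built$sources),
      seed = as.integer(seed))
}

#' Simulate the complex-task session
#'
#' Exactly 60 perturbation and 30 no-perturbation trials in random order.
#' Every trial is an active-piloting trial and carries continuous
#' visuomotor activity (`complexMotorPower`) in the task and background
#' sources; perturbation trials add the evoked template and motor ramp.
#' Reaction times come from the complex-task distribution, and a small
#' random subset of trials is flagged as crashing before the perturbation
#' onset (those are screened out downstream; post-onset crashes are not
#' simulated because such trials stay in the analysis).
#'
#' @inheritParams simulateSimpleSession
#' @return a [SessionData-class] tagged `test_complex`.
#' @export
simulateComplexSession <- function(config, seed) {
  validObject(config)
  nTr <- COMPLEX_N_PERT + COMPLEX_N_NOPERT
  meta <- withSeed(deriveSeed(seed, "meta"), {
    condition <- sample(c(rep("complex_perturbation", COMPLEX_N_PERT),
                          rep("complex_noperturbation", COMPLEX_N_NOPERT)))
    onset <- runif(nTr, 2, 4)
    rt <- rep(NA_real_, nTr)
    pert <- condition == "complex_perturbation"
    rt[pert] <- rtruncnorm(sum(pert), config@rtMeanComplexMs, config@rtSdMs, 200, 700)
    bad <- rep("ok", nTr)
    bad[runif(nTr) < 0.035] <- "pre_onset_crash"
    dr <- rtruncnorm(nTr, config@descentRateMeanMps, config@descentRateSdMps,
                     20, config@descentRateMeanMps + 6 * config@descentRateSdMps)
    data.frame(sessionId = "S4_complex", trialIndex = seq_len(nTr),
               task = "complex", condition = condition,
               perturbationOnsetS = onset, manualRtMs = rt, badFlag = bad,
               descentRateMps = dr, stringsAsFactors = FALSE)
  })
  built <- buildSessionArray(config, meta, "complex", deriveSeed(seed, "array"))
  new("SessionData", sensors = built$sensors, fs = config@fsRaw,
      traceStartMs = -TRACE_PRE_MS, meta = meta, sessionTag = "test_complex",
      groundTruth = list(mixing = built$mixing, taskSourceIndex = 1L,
                         trueLabels = meta$condition,
                         sourceTraces = built$sources),
      seed = as.integer(seed))
}

#' Simulate a full subject
#'
#' Three simple-task sessions (sessions 1-2 tagged `train`, session 3 tagged
#' `test_simple`) and one complex-task session (`test_complex`), sharing one
#' mixing matrix per subject seed so that weights learned on the training
#' sessions transfer to the held-out ones.
#'
#' @param config a [SubjectConfig-class]; `config@seed` drives everything.
#' @return list with elements `sessions` (list of four [SessionData-class])
#'   and `config`.
#' @export
simulateSubject <- function(config) {
  validObject(config)
  seeds <- vapply(1:4, function(k) deriveSeed(config@seed, "session", k), integer(1))
  # one mixing per subject: sessions share the head/sensor geometry
  sessions <- list(
    simulateSimpleSession(config, 1L, seeds[1]),
    simulateSimpleSession(config, 2L, seeds[2]),
    simulateSimpleSession(config, 3L, seeds[3]),
    simulateComplexSession(config, seeds[4]))
  list(sessions = sessions, config = config)
}
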