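# PCA reduction + Infomax ICA on the two training sessions, frozen-weight
# projection onto held-out sessions, and automated selection of the evoked
# task component.

# Natural-gradient Infomax with a logistic nonlinearity, runica-style
# annealing: the learning rate is reduced whenever the update direction
# swings by more than annealDeg degrees, and iteration stops when the
# relative weight change drops below tol. Z must be whitened
# (components x samples).
infomaxCore <- function(Z, lrate = 0.01, maxSweeps = 128L, tol = 1e-7,
                        annealDeg = 60, annealFactor = 0.85, blockSize = 512L) {
  nc <- nrow(Z); ns <- ncol(Z)
  blockSize <- min(blockSize, ns)
  W <- diag(nc)
  I <- diag(nc)
  oldDW <- NULL
  sweeps <- 0L
  restarts <- 0L
  repeat {
    sweeps <- sweeps + 1L
    Wold <- W
    perm <- sample.int(ns)
    starts <- seq(1L, ns - blockSize + 1L, by = blockSize)
    for (b in starts) {
      xb <- Z[, perm[b:(b + blockSize - 1L)], drop = FALSE]
      u <- W %*% xb
      y <- 1 / (1 + exp(-u))
      dW <- (I * blockSize + (1 - 2 * y) %*% t(u)) %*% W
      W <- W + (lrate / blockSize) * dW
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) break
    }
    if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
      # diverged: restart with a gentler step
      restarts <- restarts + 1L
      if (restarts > 8L) stop("Infomax ICA diverged repeatedly")
      W <- diag(nc); oldDW <- NULL
      lrate <- lrate / 2
      sweeps <- 0L
      next
    }
    dWtot <- W - Wold
    wchange <- sqrt(sum(dWtot^2) / sum(Wold^2))
    if (!is.null(oldDW)) {
      denom <- sqrt(sum(dWtot^2) * sum(oldDW^2))
      angle <- if (denom > 0) acos(max(-1, min(1, sum(dWtot * oldDW) / denom))) * 180 / pi else 0
      if (angle > annealDeg) lrate <- lrate * annealFactor
    }
    oldDW <- dWtot
    if (wchange < tol || sweeps >= maxSweeps) break
  }
  list(W = W, sweeps = sweeps, lrate = lrate)
}

#' Fit the PCA + Infomax unmixing model
#'
#' Concatenates the training epochs (sessions 1-2, all conditions), removes
#' the channel means, reduces with PCA (with whitening) to `nComponents`,
#' and runs natural-gradient Infomax ICA. If the data rank falls below
#' `nComponents` the dimensionality is reduced to the available rank with an
#' explicit warning, never silently. Each row of the combined unmixing is
#' scaled to unit norm. Deterministic given `seed`.
#'
#' @param trainEpochs an [EpochArray-class] in sensor space (or a list of
#'   them, which is concatenated) drawn from the training sessions only.
#' @param nComponents PCA dimensionality (default 64).
#' @param seed integer seed for the ICA sample shuffling.
#' @param maxSweeps,tol Infomax stopping rule: at most `maxSweeps` passes or
#'   a relative weight change below `tol`; with the annealed learning rate
#'   the sweep budget is the practical stop, and the fit quality is
#'   validated against planted ground truth in the test suite.
#' @return an [UnmixingModel-class]; the task component is not yet selected.
#' @export
fitUnmixing <- function(trainEpochs, nComponents = 64, seed = 1L,
                        maxSweeps = 128L, tol = 1e-7) {
  if (is.list(trainEpochs) && !is(trainEpochs, "EpochArray"))
    trainEpochs <- bindEpochs(trainEpochs)
  stopifnot(is(trainEpochs, "EpochArray"), trainEpochs@space == "sensor")
  d <- dim(trainEpochs@data)
  nCh <- d[2]
  # channels x (trials * samples)
  X <- matrix(aperm(trainEpochs@data, c(2, 3, 1)), nrow = nCh)
  mu <- rowMeans(X)
  X <- X - mu
  ns <- ncol(X)
  sv <- svd(X / sqrt(ns), nu = nCh, nv = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-9)
  k <- min(nComponents, nCh, rank)
  if (k < nComponents)
    warning("data rank (", rank, ") below requested nComponents (",
            nComponents, "); reduced to ", k)
  varExpl <- sum(sv$d[seq_len(k)]^2) / sum(sv$d^2)
  # whitening PCA matrix: k x channels
  P <- diag(1 / sv$d[seq_len(k)], k) %*% t(sv$u[, seq_len(k), drop = FALSE])
  Z <- P %*% X
  fit <- withSeed(deriveSeed(seed, "infomax"), infomaxCore(Z, maxSweeps = maxSweeps, tol = tol))
  Wica <- fit$W
  combined <- Wica %*% P
  # unit-norm rows; fold the scaling into the ICA rotation so that
  # combined == ica %*% pca stays exact
  rn <- sqrt(rowSums(combined^2))
  Wica <- Wica / rn
  combined <- combined / rn
  new("UnmixingModel", pcaMatrix = P, icaUnmixing = Wica,
      combinedWeights = combined, channelMean = mu,
      selectedComponent = NA_integer_,
      selectionScores = data.frame(),
      varianceExplained = varExpl,
      sessionsUsed = unique(trainEpochs@meta$sessionId),
      seed = as.integer(seed), sweeps = as.integer(fit$sweeps))
}

#' Project epochs through fixed unmixing weights
#'
#' Computes component activation waveforms as `combinedWeights %*% (sensors
#' - channelMean)`. No refitting happens on held-out sessions; applying the
#' training-session weights to later sessions simulates online use of the
#' decoder.
#'
#' @param model an [UnmixingModel-class].
#' @param epochs sensor-space [EpochArray-class] with matching channel count.
#' @return a component-space [EpochArray-class].
#' @export
componentActivations <- function(model, epochs) {
  stopifnot(is(model, "UnmixingModel"), is(epochs, "EpochArray"))
  d <- dim(epochs@data)
  if (d[2] != ncol(model@combinedWeights))
    stop("channel mismatch: model has ", ncol(model@combinedWeights),
         " channels, epochs have ", d[2])
  X <- matrix(aperm(epochs@data, c(2, 3, 1)), nrow = d[2])
  A <- model@combinedWeights %*% (X - model@channelMean)
  out <- aperm(array(A, dim = c(nrow(A), d[3], d[1])), c(3, 1, 2))
  new("EpochArray", data = out, fs = epochs@fs, space = "component",
      meta = epochs@meta, screeningLog = epochs@screeningLog)
}

#' Select the evoked task component
#'
#' Scores every component by the ratio of the absolute peak of its
#' trial-mean activation in (0, 300\] ms to the RMS of the trial-mean
#' activation in the \[-400, 0) ms baseline, computed over the active-
#' piloting perturbation training trials. The highest-scoring component is
#' selected (ties break to the lower index), its sign is fixed so the
#' evoked peak is positive, and the full score table is stored for audit.
#' This automates the visual inspection step of the original procedure.
#'
#' @param model an [UnmixingModel-class].
#' @param flyPerturbationEpochs sensor-space [EpochArray-class] of the
#'   active-piloting perturbation training trials (at least 10).
#' @return the model with `selectedComponent`, `selectionScores` and the
#'   sign convention filled in.
#' @export
selectTaskComponent <- function(model, flyPerturbationEpochs) {
  stopifnot(is(model, "UnmixingModel"))
  acts <- if (is(flyPerturbationEpochs, "EpochArray") &&
              flyPerturbationEpochs@space == "component")
    flyPerturbationEpochs else componentActivations(model, flyPerturbationEpochs)
  if (nTrials(acts) < 10L)
    stop("need at least 10 active perturbation training trials for selection")
  m <- apply(acts@data, c(2, 3), mean)  # components x samples
  tms <- epochTimes()
  postIdx <- which(tms > 0 & tms <= 300)
  baseIdx <- which(tms >= -400 & tms < 0)
  peakAbs <- apply(abs(m[, postIdx, drop = FALSE]), 1, max)
  baseRms <- apply(m[, baseIdx, drop = FALSE], 1, rmsOf)
  score <- peakAbs / baseRms
  best <- which.max(score)  # which.max already breaks ties low
  if (peakAbs[best] < 2 * baseRms[best])
    stop("no evoked component: no post-onset peak exceeds twice its baseline RMS")
  peakIdx <- postIdx[which.max(abs(m[best, postIdx]))]
  sgn <- sign(m[best, peakIdx])
  if (sgn < 0) {
    model@icaUnmixing[best, ] <- -model@icaUnmixing[best, ]
    model@combinedWeights[best, ] <- -model@combinedWeights[best, ]
  }
  model@selectedComponent <- as.integer(best)
  model@selectionScores <- data.frame(component = seq_along(score),
                                      peakAbs = peakAbs, baselineRms = baseRms,
                                      score = score)
  validObject(model)
  model
}

#' Estimated source maps of an unmixing model
#'
#' Column j is the sensor-space map (topography) of component j, comparable
#' up to sign and scale with a planted mixing-matrix column. Without data
#' this is the pseudo-inverse of the combined weights (the classical ICA
#' inverse map). When sensor epochs are supplied, the map is instead the
#' activation pattern `a_j = C w_j / (w_j' C w_j)` with `C` the sensor
#' covariance — the least-squares regression of the sensors on the
#' component activation, which is the appropriate interpretation of a
#' linear filter on noisy data and is the better-conditioned estimate for
#' weak sources.
#'
#' @param model an [UnmixingModel-class].
#' @param epochs optional sensor-space [EpochArray-class] used to form the
#'   covariance for the pattern estimate.
#' @return channels x components matrix.
#' @export
componentMaps <- function(model, epochs = NULL) {
  stopifnot(is(model, "UnmixingModel"))
  W <- model@combinedWeights
  if (is.null(epochs)) return(t(W) %*% solve(W %*% t(W)))
  stopifnot(is(epochs, "EpochArray"), epochs@space == "sensor")
  d <- dim(epochs@data)
  X <- matrix(aperm(epochs@data, c(2, 3, 1)), nrow = d[2])
  X <- X - rowMeans(X)
  S <- W %*% X
  maps <- X %*% t(S) / ncol(X)
  sweep(maps, 2, rowMeans(S^2), "/")
}
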