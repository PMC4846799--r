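# Peak-anchored RMS features, the passive-trial resampling scheme, and the
# least-squares probabilistic classifier (LSPC) with its closed-form
# regularized solution, plus the 100-decoder train/select procedure.

#' Peak latency of the mean evoked response
#'
#' The time of the absolute peak of the trial-mean component activation,
#' restricted to (0, `maxMs`\] ms after the perturbation onset, returned on
#' the 4 ms epoch sample grid. By protocol this is computed from the
#' active-piloting perturbation trials of the first training session only.
#'
#' @param meanWaveform numeric vector of 500 samples on the standard epoch
#'   grid (see [epochTimes()]).
#' @param maxMs upper bound of the search window (default 300 ms).
#' @return anchor time in ms.
#' @export
findPeakLatency <- function(meanWaveform, maxMs = 300) {
  stopifnot(length(meanWaveform) == EPOCH_N)
  tms <- epochTimes()
  idx <- which(tms > 0 & tms <= maxMs)
  if (!length(idx)) stop("empty peak search window")
  tms[idx[which.max(abs(meanWaveform[idx]))]]
}

#' Three-window RMS feature vector
#'
#' RMS amplitude of the component activation over three contiguous 40 ms
#' windows anchored at `anchorMs`: \[anchor-80, anchor-40), \[anchor-40,
#' anchor) and \[anchor, anchor+40) ms, i.e. 10 samples each at 250 Hz.
#'
#' @param trialActivation numeric vector of 500 samples (one trial of the
#'   selected component).
#' @param anchorMs anchor time in ms (multiple of 4) such that all three
#'   windows lie inside the epoch.
#' @return numeric vector of 3 non-negative RMS values.
#' @export
rmsFeatureBlock <- function(trialActivation, anchorMs) {
  stopifnot(length(trialActivation) == EPOCH_N)
  startsMs <- anchorMs + c(-80, -40, 0)
  if (anchorMs - 80 < -1000 || anchorMs + 40 > 1000)
    stop("feature window [", anchorMs - 80, ", ", anchorMs + 40,
         ") ms falls outside the epoch")
  vapply(startsMs, function(s) {
    i0 <- msToEpochIdx(s)
    rmsOf(trialActivation[i0:(i0 + 9L)])
  }, numeric(1))
}

# Vectorized feature blocks for many trials (rows) at one anchor.
rmsFeaturesMatrix <- function(activations, anchorMs) {
  out <- matrix(0, nrow(activations), 3)
  for (w in 1:3) {
    i0 <- msToEpochIdx(anchorMs + c(-80, -40, 0)[w])
    out[, w] <- sqrt(rowMeans(activations[, i0:(i0 + 9L), drop = FALSE]^2))
  }
  out
}

#' Assemble the training feature table
#'
#' Active perturbation trials contribute one feature vector at the evoked
#' peak anchor (class `intend`); passive perturbation trials contribute
#' three vectors, anchored 120, 60 and 0 ms before onset (class `passive`),
#' tripling the passive rows to roughly 1.5 passive rows per active row.
#' The timing scatter of the passive anchors deliberately increases the
#' temporal noise the classifier must reject, which biases it toward fewer
#' false alarms.
#'
#' @param activations trials x 500 matrix of the selected component's
#'   activation (training sessions), aligned with `meta`.
#' @param meta metadata rows aligned with `activations`.
#' @param anchorMs evoked-peak anchor from [findPeakLatency()].
#' @return data.frame with columns `f1`-`f3`, `label` (`intend`/`passive`),
#'   `trialIndex`, `sessionId`, `anchorMs`; rows whose feature windows do
#'   not fit in the epoch are dropped and listed in `attr(, "dropped")`.
#' @export
assembleTrainingSet <- function(activations, meta, anchorMs) {
  stopifnot(nrow(activations) == nrow(meta))
  fly <- which(meta$condition == "fly_perturbation")
  watch <- which(meta$condition == "watch_perturbation")
  if (!length(fly) || !length(watch))
    stop("cannot train two classes: need both active (fly_perturbation) and ",
         "passive (watch_perturbation) perturbation trials")
  rows <- list(); dropped <- list()
  addRows <- function(idx, a, label) {
    if (a - 80 < -1000 || a + 40 > 1000) {
      dropped[[length(dropped) + 1L]] <<- data.frame(
        trialIndex = meta$trialIndex[idx], anchorMs = a,
        reason = "window outside epoch")
      return(invisible())
    }
    f <- rmsFeaturesMatrix(activations[idx, , drop = FALSE], a)
    rows[[length(rows) + 1L]] <<- data.frame(
      f1 = f[, 1], f2 = f[, 2], f3 = f[, 3], label = label,
      trialIndex = meta$trialIndex[idx], sessionId = meta$sessionId[idx],
      anchorMs = a, stringsAsFactors = FALSE)
  }
  addRows(fly, anchorMs, "intend")
  for (a in c(-120, -60, 0)) addRows(watch, a, "passive")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame()
  out
}

gaussKernelFromD2 <- function(D2, sigma) exp(-D2 / (2 * sigma^2))

sqDistMatrix <- function(X, Y = X) {
  nx <- rowSums(X^2); ny <- rowSums(Y^2)
  d2 <- outer(nx, ny, "+") - 2 * X %*% t(Y)
  pmax(d2, 0)
}

# Closed-form LSPC weight solve for all classes at once:
# theta = (K'K/n + rho I)^-1 K'Y / n, with Y the 0/1 class indicator matrix.
lspcSolve <- function(K, Y, rho) {
  n <- nrow(K)
  A <- crossprod(K) / n + diag(rho, ncol(K))
  solve(A, crossprod(K, Y) / n)
}

lspcPosteriorFromK <- function(K, theta) {
  P <- pmax(K %*% theta, 0)
  s <- rowSums(P)
  zero <- s <= 0
  P[zero, ] <- 1 / ncol(P)
  s[zero] <- 1
  P / s
}

#' Fit a least-squares probabilistic classifier
#'
#' Models the class-posterior probability as a clipped, renormalized linear
#' combination of Gaussian kernels centered on every training point; the
#' per-class weights solve the ridge-regularized least-squares fit to the
#' 0/1 class indicator in closed form. Features are z-normalized with
#' statistics computed from the training rows only. The kernel width and
#' ridge strength are chosen by `nFolds`-fold cross-validated log-loss over
#' the grids; the random fold assignment (driven by `seed`) is the only
#' stochastic ingredient.
#'
#' @param features data.frame from [assembleTrainingSet()] (columns
#'   `f1`-`f3` and `label`), or an n x 3 matrix if `labels` is given.
#' @param labels optional character/factor vector of `intend`/`passive`.
#' @param sigmaGrid kernel widths; default is the median pairwise training
#'   distance times `c(0.25, 0.5, 1, 2, 4)`.
#' @param rhoGrid ridge strengths; default `10^(-3:0)`.
#' @param nFolds cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @param anchorMs anchor provenance stored in the decoder.
#' @return an [LspcDecoder-class].
#' @export
fitLspc <- function(features, labels = NULL, sigmaGrid = NULL,
                    rhoGrid = c(1e-3, 1e-2, 1e-1, 1), nFolds = 5, seed = 1L,
                    anchorMs = NA_real_) {
  if (is.data.frame(features)) {
    labels <- features$label
    if (is.na(anchorMs) && "anchorMs" %in% names(features)) {
      ai <- features$anchorMs[features$label == "intend"]
      if (length(ai)) anchorMs <- ai[1]
    }
    features <- as.matrix(features[, c("f1", "f2", "f3")])
  }
  labels <- as.character(labels)
  classes <- c("intend", "passive")
  if (!all(labels %in% classes)) stop("labels must be 'intend' or 'passive'")
  if (length(unique(labels)) < 2L) stop("need both classes to train")
  n <- nrow(features)
  mu <- colMeans(features)
  sdv <- apply(features, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  D2 <- sqDistMatrix(X)
  if (is.null(sigmaGrid)) {
    medd <- stats::median(sqrt(D2[upper.tri(D2)]))
    if (!is.finite(medd) || medd <= 0) medd <- 1
    sigmaGrid <- medd * c(0.25, 0.5, 1, 2, 4)
  }
  Y <- cbind(intend = as.numeric(labels == "intend"),
             passive = as.numeric(labels == "passive"))
  folds <- withSeed(deriveSeed(seed, "folds"),
                    sample(rep(seq_len(nFolds), length.out = n)))
  eps <- 1e-12
  best <- list(loss = Inf, sigma = NA, rho = NA)
  for (sg in sigmaGrid) {
    Ks <- gaussKernelFromD2(D2, sg)
    for (rho in rhoGrid) {
      lossSum <- 0; ok <- TRUE
      for (f in seq_len(nFolds)) {
        tr <- folds != f
        theta <- tryCatch(lspcSolve(Ks[tr, tr, drop = FALSE],
                                    Y[tr, , drop = FALSE], rho),
                          error = function(e) NULL)
        if (is.null(theta)) { ok <- FALSE; break }
        P <- lspcPosteriorFromK(Ks[!tr, tr, drop = FALSE], theta)
        yi <- ifelse(labels[!tr] == "intend", 1L, 2L)
        lossSum <- lossSum + sum(-log(P[cbind(seq_len(sum(!tr)), yi)] + eps))
      }
      if (ok && lossSum / n < best$loss)
        best <- list(loss = lossSum / n, sigma = sg, rho = rho)
    }
  }
  if (!is.finite(best$loss)) stop("LSPC cross-validation failed on every grid point")
  K <- gaussKernelFromD2(D2, best$sigma)
  rhoUse <- best$rho
  theta <- NULL
  for (rho in rhoGrid[rhoGrid >= best$rho]) {
    theta <- tryCatch(lspcSolve(K, Y, rho), error = function(e) NULL)
    if (!is.null(theta)) { rhoUse <- rho; break }
  }
  if (is.null(theta)) stop("LSPC system singular at every ridge value")
  if (rhoUse != best$rho)
    message("LSPC: system singular at rho = ", best$rho,
            "; increased to ", rhoUse)
  new("LspcDecoder", centers = X, weights = theta, sigma = best$sigma,
      rho = rhoUse, classes = classes, featMean = mu, featSd = sdv,
      anchorMs = as.numeric(anchorMs), foldSeed = as.integer(seed),
      cvLoss = best$loss)
}

#' Class-posterior probabilities from an LSPC decoder
#'
#' @param decoder an [LspcDecoder-class].
#' @param features n x 3 matrix of raw (un-normalized) feature vectors.
#' @return n x 2 matrix of posteriors (columns `intend`, `passive`); rows
#'   are non-negative and sum to one.
#' @export
predictPosterior <- function(decoder, features) {
  stopifnot(is(decoder, "LspcDecoder"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  X <- sweep(sweep(features, 2, decoder@featMean), 2, decoder@featSd, "/")
  K <- gaussKernelFromD2(sqDistMatrix(X, decoder@centers), decoder@sigma)
  P <- lspcPosteriorFromK(K, decoder@weights)
  colnames(P) <- decoder@classes
  P
}

#' Train 100 decoders and select the best on the held-out simple session
#'
#' All decoders share the training feature table; they differ only in the
#' seed of the cross-validation fold assignment that picks the kernel width
#' and ridge strength. Each decoder is scored on the held-out simple-task
#' session (perturbation trials only, active vs. passive, features at the
#' training-derived anchor) by the posterior-mean balanced accuracy, and
#' the best one (ties to the lowest decoder index) is returned together
#' with the per-decoder report. No statistic of the evaluation session
#' enters training.
#'
#' @param trainFeatures feature table from [assembleTrainingSet()].
#' @param evalActivations trials x 500 activation matrix of the held-out
#'   simple session (selected component).
#' @param evalMeta metadata aligned with `evalActivations`.
#' @param anchorMs training-derived anchor, ms.
#' @param nDecoders number of decoders (default 100).
#' @param seed master seed; decoder d uses fold seed derived from (seed, d).
#' @param ... further arguments to [fitLspc()].
#' @return list: `best` ([LspcDecoder-class]), `report` (per-decoder
#'   data.frame), `bestBacc`, `meanBacc`, `bestConfusion`.
#' @export
trainAndSelect <- function(trainFeatures, evalActivations, evalMeta, anchorMs,
                           nDecoders = 100, seed = 1L, ...) {
  evalFly <- which(evalMeta$condition == "fly_perturbation")
  evalWatch <- which(evalMeta$condition == "watch_perturbation")
  if (!length(evalFly) || !length(evalWatch))
    stop("evaluation session lacks one of the two perturbation classes")
  evalX <- rbind(rmsFeaturesMatrix(evalActivations[evalFly, , drop = FALSE], anchorMs),
                 rmsFeaturesMatrix(evalActivations[evalWatch, , drop = FALSE], anchorMs))
  evalY <- c(rep("intend", length(evalFly)), rep("passive", length(evalWatch)))
  report <- data.frame(decoder = seq_len(nDecoders), foldSeed = NA_integer_,
                       sigma = NA_real_, rho = NA_real_, cvLoss = NA_real_,
                       bacc = NA_real_)
  cache <- new.env(parent = emptyenv())
  best <- NULL; bestBacc <- -Inf; bestConf <- NULL
  for (d in seq_len(nDecoders)) {
    fs <- deriveSeed(seed, "decoder", d)
    dec <- fitLspc(trainFeatures, seed = fs, anchorMs = anchorMs, ...)
    key <- paste(dec@sigma, dec@rho)
    if (is.null(cache[[key]])) {
      P <- predictPosterior(dec, evalX)
      pred <- ifelse(P[, "intend"] > 0.5, "intend", "passive")
      conf <- c(tp = sum(pred == "intend" & evalY == "intend"),
                fn = sum(pred == "passive" & evalY == "intend"),
                fp = sum(pred == "intend" & evalY == "passive"),
                tn = sum(pred == "passive" & evalY == "passive"))
      cache[[key]] <- list(bacc = baccPosterior(conf["tp"], conf["fn"],
                                                conf["fp"], conf["tn"])$meanPct,
                           conf = conf)
    }
    ev <- cache[[key]]
    report$foldSeed[d] <- fs
    report$sigma[d] <- dec@sigma
    report$rho[d] <- dec@rho
    report$cvLoss[d] <- dec@cvLoss
    report$bacc[d] <- ev$bacc
    if (ev$bacc > bestBacc) {
      bestBacc <- ev$bacc; best <- dec; bestConf <- ev$conf
    }
  }
  list(best = best, report = report, bestBacc = bestBacc,
       meanBacc = mean(report$bacc), bestConfusion = bestConf)
}
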