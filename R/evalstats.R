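# Performance statistics: beta-posterior balanced accuracy, signal-
# detection indices, the permutation null of the response-time savings, and
# cross-subject generalization.

#' Balanced-accuracy posterior
#'
#' Flat-prior beta posteriors for sensitivity (`Beta(tp+1, fn+1)`) and
#' specificity (`Beta(tn+1, fp+1)`); the balanced accuracy is their
#' average, whose posterior density is obtained by numerical convolution on
#' a fine grid. The posterior mean has the closed form
#' `((tp+1)/(tp+fn+2) + (tn+1)/(tn+fp+2)) / 2`, and the interval is the
#' central 95% of the convolved posterior. `pBelowChance` is the posterior
#' probability that the balanced accuracy is at or below 50%; note this is
#' a posterior tail probability, not a frequentist test p-value.
#'
#' @param tp,fn,fp,tn confusion counts; both classes must be non-empty.
#' @param gridN convolution grid size (default 4096).
#' @return list with `meanPct`, `loPct`, `hiPct` (95% posterior-probability
#'   interval) and `pBelowChance`, percentages on the 0-100 scale.
#' @export
baccPosterior <- function(tp, fn, fp, tn, gridN = 4096L) {
  tp <- unname(tp); fn <- unname(fn); fp <- unname(fp); tn <- unname(tn)
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (tp + fn < 1 || fp + tn < 1)
    stop("both classes must contain at least one trial")
  a1 <- tp + 1; b1 <- fn + 1    # sensitivity posterior
  a2 <- tn + 1; b2 <- fp + 1    # specificity posterior
  meanBacc <- (a1 / (a1 + b1) + a2 / (a2 + b2)) / 2
  h <- 1 / gridN
  x <- (seq_len(gridN) - 0.5) * h
  fS <- dbeta(x, a1, b1)
  fP <- dbeta(x, a2, b2)
  # density of S + P on the grid (support (0, 2)), then bacc = (S + P) / 2
  conv <- convolve(fS, rev(fP), type = "open") * h
  cdf <- cumsum(conv) * h
  cdf <- cdf / cdf[length(cdf)]
  sumGrid <- (seq_along(conv)) * h   # upper edge of each sum bin
  qAt <- function(p) sumGrid[which(cdf >= p)[1]] / 2
  pBelow <- {
    i <- findInterval(1, sumGrid)    # bacc 0.5 <=> sum 1.0
    if (i < 1) 0 else cdf[i]
  }
  list(meanPct = 100 * meanBacc,
       loPct = 100 * qAt(0.025),
       hiPct = 100 * qAt(0.975),
       pBelowChance = pBelow)
}

#' Signal-detection measures
#'
#' Hit rate, false-alarm rate, d-prime and a-prime from confusion counts.
#' d-prime is the difference of standard-normal quantiles of the two rates;
#' when a rate is degenerate (0 or 1) the standard 1/(2N) correction is
#' applied to that rate for the quantile only, and the correction is noted
#' in the `notes` element. a-prime is the nonparametric area measure of
#' Macmillan and Creelman; when hr >= far,
#' `a' = 0.5 + ((hr - far)(1 + hr - far)) / (4 hr (1 - far))`, with the
#' symmetric complement formula otherwise. Unrounded rates are returned.
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return list with `hr`, `far`, `dprime`, `aprime`, `notes`.
#' @export
sdtStats <- function(tp, fn, fp, tn) {
  if (tp + fn < 1 || fp + tn < 1)
    stop("both classes must contain at least one trial")
  hr <- tp / (tp + fn)
  far <- fp / (fp + tn)
  notes <- character()
  hrAdj <- hr; farAdj <- far
  if (hr == 0) { hrAdj <- 1 / (2 * (tp + fn)); notes <- c(notes, "hr = 0 corrected to 1/(2N) for d-prime") }
  if (hr == 1) { hrAdj <- 1 - 1 / (2 * (tp + fn)); notes <- c(notes, "hr = 1 corrected to 1 - 1/(2N) for d-prime") }
  if (far == 0) { farAdj <- 1 / (2 * (fp + tn)); notes <- c(notes, "far = 0 corrected to 1/(2N) for d-prime") }
  if (far == 1) { farAdj <- 1 - 1 / (2 * (fp + tn)); notes <- c(notes, "far = 1 corrected to 1 - 1/(2N) for d-prime") }
  dprime <- qnorm(hrAdj) - qnorm(farAdj)
  aprime <- if (hr >= far) {
    if (hr == 0 && far == 0) 0.5
    else 0.5 + ((hr - far) * (1 + hr - far)) / (4 * hr * (1 - far))
  } else {
    0.5 - ((far - hr) * (1 + far - hr)) / (4 * far * (1 - hr))
  }
  list(hr = hr, far = far, dprime = dprime, aprime = aprime, notes = notes)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact signed-rank p-value for paired samples. Zero differences
#' are dropped first (if every difference is zero the p-value is 1). For up
#' to 24 non-zero differences the null distribution of the positive-rank
#' sum is enumerated exactly over all sign assignments (ties take average
#' ranks), so tied differences are handled exactly as well; larger samples
#' fall back on [stats::wilcox.test()].
#'
#' @param x,y equal-length paired samples.
#' @return the p-value.
#' @export
pairedSignedRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  if (n > 24) return(stats::wilcox.test(d, exact = TRUE, correct = FALSE)$p.value)
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled ranks are integers even with ties
  w2 <- sum(r2[d > 0])
  # exact distribution of the (doubled) positive-rank sum by convolution:
  # each rank contributes 0 or r2[i] with probability 1/2
  counts <- numeric(sum(r2) + 1L)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  total <- sum(counts)
  pLower <- sum(counts[seq_len(w2 + 1L)]) / total
  pUpper <- sum(counts[(w2 + 1L):length(counts)]) / total
  min(1, 2 * min(pLower, pUpper))
}

#' Permutation null of the response-time savings
#'
#' Retrains the decoding chain under random permutations of the
#' active/passive training labels and re-runs the simulated online decoding
#' of the complex session for each. The task component, peak anchor and
#' feature normalization are all recomputed from the permuted labels, so
#' the null decoder has every opportunity the real one had. Only
#' permutations whose false-positive rate on the no-perturbation trials is
#' below `fpCriterion` enter the null distribution (additional permutations
#' are drawn until `nPerm` qualify, up to `5 * nPerm` attempts); this
#' matches the null models to the false-alarm behavior of the true-label
#' decoder. The p-value is the fraction of null savings at least as large
#' as the observed savings, floored at `1/nPerm`.
#'
#' @param trainActs component-space [EpochArray-class] of the training
#'   sessions (all components).
#' @param complexActs component-space [EpochArray-class] of the screened
#'   complex session (all components).
#' @param observedDiffMeanMs observed mean response-time difference of the
#'   true-label decoder, ms.
#' @param nPerm number of qualifying permutations (default 1000).
#' @param fpCriterion false-positive-rate ceiling for a permutation to
#'   qualify (default 0.25).
#' @param seed integer seed.
#' @param nFolds,sigmaGrid,rhoGrid passed to [fitLspc()].
#' @param anchorSessionId session whose active trials define the anchor
#'   (defaults to the first training session present).
#' @return list: `nullDiffsMs`, `p`, `nAttempts`, `fpRates`,
#'   `nSelectionFailures`.
#' @export
permutationTimeSavings <- function(trainActs, complexActs, observedDiffMeanMs,
                                   nPerm = 1000L, fpCriterion = 0.25,
                                   seed = 1L, nFolds = 5,
                                   sigmaGrid = NULL, rhoGrid = c(1e-3, 1e-2, 1e-1, 1),
                                   anchorSessionId = NULL) {
  stopifnot(is(trainActs, "EpochArray"), trainActs@space == "component",
            is(complexActs, "EpochArray"), complexActs@space == "component")
  meta <- trainActs@meta
  pertIdx <- which(meta$condition %in% c("fly_perturbation", "watch_perturbation"))
  labs <- meta$condition[pertIdx]
  if (is.null(anchorSessionId)) anchorSessionId <- meta$sessionId[1]
  nullDiffs <- numeric(0); fpRates <- numeric(0)
  attempts <- 0L; selFail <- 0L
  maxAttempts <- 5L * nPerm
  while (length(nullDiffs) < nPerm) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("permutation cap reached: only ", length(nullDiffs), " of ", nPerm,
           " permutations met the ", fpCriterion * 100,
           "% false-positive criterion after ", maxAttempts, " attempts (",
           selFail, " component-selection failures)")
    permSeed <- deriveSeed(seed, "perm", attempts)
    permLabs <- withSeed(permSeed, sample(labs))
    permMeta <- meta
    permMeta$condition[pertIdx] <- permLabs
    res <- tryCatch(
      fitChainOnLabels(trainActs, permMeta, anchorSessionId,
                       foldSeed = deriveSeed(permSeed, "folds"),
                       nFolds = nFolds, sigmaGrid = sigmaGrid,
                       rhoGrid = rhoGrid),
      error = function(e) NULL)
    if (is.null(res)) { selFail <- selFail + 1L; next }
    summ <- adjudicateSession(res$decoder, complexActs,
                              componentIndex = res$component)
    conf <- confusionCounts(summ)
    fpr <- conf[["fp"]] / (conf[["fp"]] + conf[["tn"]])
    if (fpr >= fpCriterion) { fpRates <- c(fpRates, fpr); next }
    fpRates <- c(fpRates, fpr)
    nullDiffs <- c(nullDiffs, savingsStats(summ)$diffMeanMs)
  }
  p <- max(sum(nullDiffs >= observedDiffMeanMs) / nPerm, 1 / nPerm)
  list(nullDiffsMs = nullDiffs, p = p, nAttempts = attempts,
       fpRates = fpRates, nSelectionFailures = selFail)
}

# Shared by the true-label pipeline and each permutation: pick the task
# component from the labeled active trials, derive the anchor from the
# anchor session, assemble features and fit one LSPC decoder.
fitChainOnLabels <- function(trainActs, meta, anchorSessionId, foldSeed,
                             nFolds = 5, sigmaGrid = NULL,
                             rhoGrid = c(1e-3, 1e-2, 1e-1, 1)) {
  flyIdx <- which(meta$condition == "fly_perturbation")
  if (length(flyIdx) < 10L) stop("fewer than 10 active perturbation trials")
  m <- apply(trainActs@data[flyIdx, , , drop = FALSE], c(2, 3), mean)
  tms <- epochTimes()
  postIdx <- which(tms > 0 & tms <= 300)
  baseIdx <- which(tms >= -400 & tms < 0)
  peakAbs <- apply(abs(m[, postIdx, drop = FALSE]), 1, max)
  baseRms <- apply(m[, baseIdx, drop = FALSE], 1, rmsOf)
  comp <- which.max(peakAbs / baseRms)
  if (peakAbs[comp] < 2 * baseRms[comp])
    stop("no evoked component under this labeling")
  anchorFly <- flyIdx[meta$sessionId[flyIdx] == anchorSessionId]
  if (!length(anchorFly)) anchorFly <- flyIdx
  anchor <- findPeakLatency(apply(trainActs@data[anchorFly, comp, , drop = FALSE], 3, mean))
  feats <- assembleTrainingSet(trainActs@data[, comp, ], meta, anchor)
  decoder <- fitLspc(feats, seed = foldSeed, nFolds = nFolds,
                     sigmaGrid = sigmaGrid, rhoGrid = rhoGrid,
                     anchorMs = anchor)
  list(decoder = decoder, component = comp, anchorMs = anchor)
}

#' Apply a donor subject's decoder to other subjects
#'
#' Tests how well the best subject's classifier transfers: each recipient
#' keeps its own unmixing model, task component and activations, but the
#' donor's feature-normalization statistics and LSPC weights do the
#' classifying. The donor applied to itself reproduces its own results
#' exactly and is excluded from the paired comparison, which contrasts
#' own-model and donor-model per-subject means (savings, balanced accuracy,
#' d-prime, a-prime, hit and false-alarm rate) with the exact paired
#' signed-rank test (p is NA when fewer than 5 recipients are available).
#'
#' @param donorDecoder the donor's [LspcDecoder-class].
#' @param subjects named list; each element needs `complexActs` (component
#'   [EpochArray-class]), `component` (own selected component index) and
#'   `ownSummary` (own-model [SavingsSummary-class]).
#' @param donorId name of the donor element in `subjects`.
#' @param ... passed to [adjudicateSession()].
#' @return list: `perRecipient` (data.frame of measures under both models)
#'   and `comparison` (data.frame measure / ownMean / donorMean / p).
#' @export
generalizeModel <- function(donorDecoder, subjects, donorId, ...) {
  recipients <- setdiff(names(subjects), donorId)
  measures <- c("savingsMs", "bacc", "dprime", "aprime", "hr", "far")
  rows <- list()
  for (id in recipients) {
    s <- subjects[[id]]
    donorSumm <- adjudicateSession(donorDecoder, s$complexActs,
                                   componentIndex = s$component, ...)
    rows[[id]] <- data.frame(
      id = id,
      rbind(summaryMeasures(s$ownSummary, "own"),
            summaryMeasures(donorSumm, "donor")),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  cmp <- do.call(rbind, lapply(measures, function(mm) {
    own <- per[per$model == "own", mm]
    don <- per[per$model == "donor", mm]
    data.frame(measure = mm, ownMean = mean(own), donorMean = mean(don),
               p = if (length(own) >= 5) pairedSignedRank(own, don) else NA_real_)
  }))
  list(perRecipient = per, comparison = cmp)
}

summaryMeasures <- function(summ, model) {
  conf <- confusionCounts(summ)
  sdt <- sdtStats(conf[["tp"]], conf[["fn"]], conf[["fp"]], conf[["tn"]])
  bp <- baccPosterior(conf[["tp"]], conf[["fn"]], conf[["fp"]], conf[["tn"]])
  data.frame(model = model, savingsMs = savingsStats(summ)$diffMeanMs,
             bacc = bp$meanPct, dprime = sdt$dprime, aprime = sdt$aprime,
             hr = sdt$hr, far = sdt$far, stringsAsFactors = FALSE)
}
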