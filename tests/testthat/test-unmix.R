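makeEpochArray <- function(dat, condition = rep("fly_perturbation", dim(dat)[1]),
                           sessionId = "S1_simple") {
  nTr <- dim(dat)[1]
  meta <- data.frame(sessionId = sessionId, trialIndex = seq_len(nTr),
                     task = "simple", condition = condition,
                     perturbationOnsetS = 3, manualRtMs = NA_real_,
                     badFlag = "ok", descentRateMps = 70,
                     stringsAsFactors = FALSE)
  new("EpochArray", data = dat, fs = 250, space = "sensor", meta = meta,
      screeningLog = data.frame(trialIndex = integer(), kept = logical(),
                                reason = character()))
}

identityModel <- function(nCh) {
  new("UnmixingModel", pcaMatrix = diag(nCh), icaUnmixing = diag(nCh),
      combinedWeights = diag(nCh), channelMean = rep(0, nCh),
      selectedComponent = NA_integer_, selectionScores = data.frame(),
      varianceExplained = 1, sessionsUsed = "test", seed = 1L, sweeps = 0L)
}

test_that("component activations are the plain linear projection", {
  set.seed(4)
  X <- array(rnorm(3 * 4 * 500), dim = c(3, 4, 500))
  ep <- makeEpochArray(X)
  # identity weights reproduce the sensors
  actI <- componentActivations(identityModel(4), ep)
  expect_equal(actI@data, X, tolerance = 1e-14)
  # linearity
  mod <- identityModel(4)
  mod@icaUnmixing <- matrix(rnorm(16), 4)
  mod@combinedWeights <- mod@icaUnmixing %*% mod@pcaMatrix
  Y <- array(rnorm(3 * 4 * 500), dim = c(3, 4, 500))
  aXbY <- componentActivations(mod, makeEpochArray(2 * X + 3 * Y))@data
  expect_equal(aXbY,
               2 * componentActivations(mod, makeEpochArray(X))@data +
                 3 * componentActivations(mod, makeEpochArray(Y))@data,
               tolerance = 1e-10)
  expect_error(componentActivations(mod, makeEpochArray(array(0, c(2, 5, 500)))),
               "channel mismatch")
})

test_that("Infomax on noiseless mixtures recovers the planted maps", {
  set.seed(11)
  nSrc <- 4; nCh <- 8; nTr <- 8
  A <- makeMixing(nCh, nSrc, seed = 5)
  # sparse super-Gaussian sources
  S <- matrix(rnorm(nSrc * nTr * 500)^3, nSrc)
  X <- array(0, dim = c(nTr, nCh, 500))
  for (i in seq_len(nTr))
    X[i, , ] <- A %*% S[, ((i - 1) * 500 + 1):(i * 500)]
  mod <- fitUnmixing(makeEpochArray(X), nComponents = 4, seed = 2L)
  maps <- componentMaps(mod)
  # greedy match of recovered maps to planted columns
  cors <- abs(cor(A, maps))
  matched <- numeric(nSrc)
  for (k in seq_len(nSrc)) {
    ij <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    matched[k] <- cors[ij[1], ij[2]]
    cors[ij[1], ] <- -1; cors[, ij[2]] <- -1
  }
  expect_true(all(matched > 0.95))
})

test_that("the ICA fit is deterministic and reports rank reduction", {
  set.seed(12)
  A <- makeMixing(6, 3, seed = 9)
  S <- matrix(rnorm(3 * 4 * 500)^3, 3)
  X <- array(0, dim = c(4, 6, 500))
  for (i in 1:4) X[i, , ] <- A %*% S[, ((i - 1) * 500 + 1):(i * 500)]
  ep <- makeEpochArray(X)
  m1 <- fitUnmixing(ep, nComponents = 3, seed = 7L)
  m2 <- fitUnmixing(ep, nComponents = 3, seed = 7L)
  expect_identical(m1@combinedWeights, m2@combinedWeights)
  # rank-3 data cannot support 6 components; explicit warning, reduced fit
  expect_warning(mR <- fitUnmixing(ep, nComponents = 6, seed = 7L),
                 "rank")
  expect_identical(nrow(mR@combinedWeights), 3L)
})

test_that("combined weights factor exactly through PCA and ICA", {
  ch <- smallChain()
  mod <- fitUnmixing(neuroadapt:::bindEpochs(ch$eps[[1]], ch$eps[[2]]),
                     nComponents = 12, seed = 3L, maxSweeps = 16L)
  expect_equal(mod@icaUnmixing %*% mod@pcaMatrix, mod@combinedWeights,
               tolerance = 1e-10)
  expect_equal(unname(sqrt(rowSums(mod@combinedWeights^2))),
               rep(1, nrow(mod@combinedWeights)), tolerance = 1e-12)
  # projection consistency: applying the model twice gives identical results
  a1 <- componentActivations(mod, ch$eps[[3]])
  a2 <- componentActivations(mod, ch$eps[[3]])
  expect_identical(a1@data, a2@data)
})

test_that("task-component selection finds the planted source and fixes its sign", {
  ch <- smallChain()
  mod <- ch$mod
  expect_identical(selectedComponent(mod), 1L)   # oracle order: task source first
  scores <- selectionScores(mod)
  expect_identical(nrow(scores), 5L)
  expect_identical(which.max(scores$score), 1L)
  # sign convention: selected component's evoked peak is positive
  fly <- which(ch$trainActs@meta$condition == "fly_perturbation")
  m <- apply(ch$trainActs@data[fly, 1, , drop = FALSE], 3, mean)
  post <- epochTimes() > 0 & epochTimes() <= 300
  expect_gt(m[post][which.max(abs(m[post]))], 0)
  # and the selected peak latency is below 300 ms by construction
  expect_lte(findPeakLatency(m), 300)
})

test_that("ongoing oscillations without an evoked response raise the no-component error", {
  # a stationary oscillation has peak / baseline-RMS = sqrt(2), well under
  # the 2x evoked criterion, on every component
  set.seed(21)
  nTr <- 30
  osc <- sin(2 * pi * 10 * (seq_len(500) - 1) / 250)
  dat <- array(0, dim = c(nTr, 3, 500))
  for (i in seq_len(nTr)) for (c in 1:3)
    dat[i, c, ] <- osc * c + rnorm(500, sd = 0.05)
  ep <- makeEpochArray(dat)
  expect_error(selectTaskComponent(identityModel(3), ep), "no evoked component")
})
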