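test_that("the peak anchor is the restricted absolute extremum on the 4 ms grid", {
  w <- numeric(500)
  w[neuroadapt:::msToEpochIdx(232)] <- 1
  expect_identical(findPeakLatency(w), 232)
  # restricted search: a larger peak beyond 300 ms is ignored
  w2 <- numeric(500)
  w2[neuroadapt:::msToEpochIdx(252)] <- -0.5
  w2[neuroadapt:::msToEpochIdx(348)] <- 2
  expect_identical(findPeakLatency(w2), 252)
  # the seven reported per-subject anchors average to 246.3 ms
  anchors <- referenceTables()$peakLatencies$peak_latency_ms
  found <- vapply(anchors, function(a) {
    wv <- numeric(500); wv[neuroadapt:::msToEpochIdx(a)] <- 1
    findPeakLatency(wv)
  }, numeric(1))
  expect_identical(found, as.numeric(anchors))
  expect_equal(round(mean(found), 1), 246.3)
})

test_that("RMS feature blocks cover the three 40 ms windows around the anchor", {
  # constant trace: every RMS equals the constant
  expect_equal(rmsFeatureBlock(rep(-2, 500), 232), rep(2, 3))
  # alternating +-a: RMS = a in every window
  alt <- rep(c(3, -3), 250)
  expect_equal(rmsFeatureBlock(alt, 232), rep(3, 3))
  # window placement: anchor 232 spans [152, 272) ms; samples outside do not matter
  x <- numeric(500)
  x[neuroadapt:::msToEpochIdx(152):(neuroadapt:::msToEpochIdx(272) - 1L)] <- 1
  x[1:100] <- 99
  expect_equal(rmsFeatureBlock(x, 232), rep(1, 3))
  expect_error(rmsFeatureBlock(x, 980), "outside the epoch")
})

test_that("the training set triples passive trials at the pre-onset anchors", {
  set.seed(2)
  nTr <- 120
  acts <- matrix(rnorm(nTr * 500), nTr)
  meta <- data.frame(sessionId = "S1_simple", trialIndex = seq_len(nTr),
                     task = "simple",
                     condition = c(rep("fly_perturbation", 80),
                                   rep("watch_perturbation", 40)),
                     stringsAsFactors = FALSE)
  ft <- assembleTrainingSet(acts, meta, 232)
  expect_identical(nrow(ft), 200L)            # 80 active + 3 x 40 passive
  expect_identical(sum(ft$label == "intend"), 80L)
  expect_identical(sum(ft$label == "passive"), 120L)
  expect_setequal(unique(ft$anchorMs[ft$label == "passive"]), c(-120, -60, 0))
  # each passive trial contributes exactly three rows with its own identity
  passiveCounts <- table(ft$trialIndex[ft$label == "passive"])
  expect_true(all(passiveCounts == 3))
  # cannot train without both classes
  metaNoWatch <- meta; metaNoWatch$condition <- "fly_perturbation"
  expect_error(assembleTrainingSet(acts, metaNoWatch, 232), "two classes")
})

test_that("LSPC separates separable classes and stays calibrated on null data", {
  toy <- toyFeatures(n = 200, sep = 3)
  dec <- fitLspc(toy$X, toy$y, seed = 1L)
  pred <- ifelse(predictPosterior(dec, toy$X)[, "intend"] > 0.5, "intend", "passive")
  conf <- c(tp = sum(pred == "intend" & toy$y == "intend"),
            fn = sum(pred == "passive" & toy$y == "intend"),
            fp = sum(pred == "intend" & toy$y == "passive"),
            tn = sum(pred == "passive" & toy$y == "passive"))
  expect_gt(rawBalancedAccuracy(conf), 0.95)
  # identical class distributions: posterior approximates the class prior
  null <- toyFeatures(n = 200, sep = 0, seed = 3)
  decN <- fitLspc(null$X, null$y, seed = 1L)
  set.seed(5)
  P <- predictPosterior(decN, matrix(rnorm(3000), ncol = 3))
  expect_lt(abs(mean(P[, "intend"]) - 0.5), 0.1)
})

test_that("posteriors are proper probabilities and feature scaling is exact", {
  ch <- smallChain()
  set.seed(9)
  P <- predictPosterior(ch$decoder, matrix(runif(300, 0, 3), ncol = 3))
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 100), tolerance = 1e-12)
  # z-normalization comes from the training rows only and is exact on them
  Xn <- sweep(sweep(as.matrix(ch$feats[, c("f1", "f2", "f3")]), 2,
                    ch$decoder@featMean), 2, ch$decoder@featSd, "/")
  expect_equal(unname(colMeans(Xn)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(Xn, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("closed-form LSPC weights match a brute-force regularized solve", {
  toy <- toyFeatures(n = 80, sep = 1.5, seed = 7)
  dec <- fitLspc(toy$X, toy$y, seed = 2L)
  X <- dec@centers
  D2 <- neuroadapt:::sqDistMatrix(X)
  K <- exp(-D2 / (2 * dec@sigma^2))
  n <- nrow(K)
  Y <- cbind(as.numeric(toy$y == "intend"), as.numeric(toy$y == "passive"))
  # independent oracle: augmented least squares ||K theta - y||^2/n + rho ||theta||^2
  A <- rbind(K / sqrt(n), sqrt(dec@rho) * diag(n))
  bruteForce <- qr.solve(A, rbind(Y / sqrt(n), matrix(0, n, 2)))
  expect_equal(dec@weights, bruteForce, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("decoder training never touches the evaluation session", {
  ch <- smallChain()
  evalMeta <- ch$evalActs@meta
  evalMat <- ch$evalActs@data[, ch$comp, ]
  sel1 <- trainAndSelect(ch$feats, evalMat, evalMeta, ch$anchor,
                         nDecoders = 5, seed = 3L)
  # corrupt the evaluation data: the fitted decoders must be unchanged
  sel2 <- trainAndSelect(ch$feats, evalMat * 10 + 1, evalMeta, ch$anchor,
                         nDecoders = 5, seed = 3L)
  expect_identical(sel1$report[, c("foldSeed", "sigma", "rho", "cvLoss")],
                   sel2$report[, c("foldSeed", "sigma", "rho", "cvLoss")])
  # the best decoder can never score below the mean of the batch
  expect_gte(sel1$bestBacc, sel1$meanBacc)
  # evaluation needs both classes
  badMeta <- evalMeta; badMeta$condition <- "fly_perturbation"
  expect_error(trainAndSelect(ch$feats, evalMat, badMeta, ch$anchor,
                              nDecoders = 2, seed = 1L), "lacks")
})
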