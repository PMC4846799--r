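test_that("mixing matrices are unit-norm, distinct, full rank and reproducible", {
  A <- makeMixing(64, 8, seed = 1)
  expect_equal(dim(A), c(64, 8))
  expect_equal(sqrt(colSums(A^2)), rep(1, 8), tolerance = 1e-12)
  cc <- cor(A)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.8)
  expect_identical(qr(A)$rank, 8L)
  expect_identical(A, makeMixing(64, 8, seed = 1))
  expect_false(identical(A, makeMixing(64, 8, seed = 2)))

  Asq <- makeMixing(8, 8, seed = 2)
  expect_identical(qr(Asq)$rank, 8L)
  expect_error(makeMixing(8, 9, seed = 1), "invalid config")
})

test_that("evoked template peaks at the requested latency with the requested amplitude", {
  w <- makeEvokedTemplate(232, 80, 1.0, 250)
  expect_identical(which.max(abs(w)), 59L)  # 0-based sample 58 = round(0.232 * 250)
  expect_equal(max(abs(w)), 1.0)
  expect_lt(abs(w[1]), 1e-3)   # (numerically) no support at onset
  expect_identical(makeEvokedTemplate(232, 80, 0, 250), numeric(250))
  expect_error(makeEvokedTemplate(310, 80, 1, 250), "invalid config")
  expect_error(makeEvokedTemplate(250, 80, 1, 250, durationMs = 200), "invalid config")
})

test_that("simple sessions have the protocol's trial structure", {
  cfg <- smallConfig()
  s <- simulateSimpleSession(cfg, 1L, seed = 99L)
  meta <- trialMeta(s)
  expect_identical(nrow(meta), 90L)
  nFlyPert <- sum(meta$condition == "fly_perturbation")
  expect_gt(nFlyPert, 28); expect_lt(nFlyPert, 52)   # ~40 +- sampling spread
  expect_true(all(meta$perturbationOnsetS >= 2 & meta$perturbationOnsetS <= 4))
  hasRt <- !is.na(meta$manualRtMs)
  expect_identical(which(hasRt), which(meta$condition == "fly_perturbation"))
  expect_true(all(meta$manualRtMs[hasRt] >= 200 & meta$manualRtMs[hasRt] <= 700))
  # determinism: bit-identical rerun
  s2 <- simulateSimpleSession(cfg, 1L, seed = 99L)
  expect_identical(s@sensors, s2@sensors)
  expect_identical(trialMeta(s2), meta)
})

test_that("equal amplitudes and no motor ramp make fly and watch traces indistinguishable", {
  cfg <- smallConfig(taskAmpWatch = 1, motorRampAmp = 0)
  s <- simulateSimpleSession(cfg, 1L, seed = 5L)
  meta <- trialMeta(s)
  rms <- sqrt(apply(s@sensors^2, 1, mean))
  p <- t.test(rms[meta$condition == "fly_perturbation"],
              rms[meta$condition == "watch_perturbation"])$p.value
  expect_gt(p, 0.01)
})

test_that("recovered evoked amplitude scales linearly with the planted amplitude", {
  amps <- c(1, 2, 4)
  peaks <- vapply(amps, function(a) {
    cfg <- smallConfig(taskAmpFly = a, amplitudeJitterSd = 0, latencyJitterMs = 0)
    s <- simulateSimpleSession(cfg, 1L, seed = 31L)
    ep <- segmentAndScreen(s)
    acts <- componentActivations(oracleUnmixing(s), ep)
    fly <- which(ep@meta$condition == "fly_perturbation")
    m <- apply(acts@data[fly, 1, , drop = FALSE], 3, mean)
    max(abs(m[epochTimes() > 0 & epochTimes() <= 300]))
  }, numeric(1))
  fit <- lm(peaks ~ amps)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(coef(fit)[2], 0)
})

test_that("complex sessions have exactly 60 perturbation and 30 no-perturbation trials", {
  cfg <- smallConfig()
  s <- simulateComplexSession(cfg, seed = 12L)
  meta <- trialMeta(s)
  expect_identical(sum(meta$condition == "complex_perturbation"), 60L)
  expect_identical(sum(meta$condition == "complex_noperturbation"), 30L)
  expect_identical(trialMeta(simulateComplexSession(cfg, seed = 12L)), meta)
})

test_that("zero visuomotor power makes complex pre-onset variance match the simple task", {
  cfg <- smallConfig(complexMotorPower = 0)
  sS <- simulateSimpleSession(cfg, 1L, seed = 8L)
  sC <- simulateComplexSession(cfg, seed = 9L)
  preVar <- function(s) {
    ep <- segmentAndScreen(s)
    pre <- epochTimes() < 0
    mean(apply(ep@data[, , pre, drop = FALSE], 1, var))
  }
  expect_equal(preVar(sC), preVar(sS), tolerance = 0.05)
})

test_that("a subject bundle has the session/tag layout of the recording protocol", {
  sub <- simulateSubject(smallConfig())
  expect_length(sub$sessions, 4L)
  expect_identical(vapply(sub$sessions, sessionTag, character(1)),
                   c("train", "train", "test_simple", "test_complex"))
  totalSimple <- sum(vapply(sub$sessions[1:3], nTrials, numeric(1)))
  expect_identical(totalSimple, 270)
  # same schema, different traces for a different seed
  sub2 <- simulateSubject(smallConfig(seed = 8L))
  expect_identical(names(trialMeta(sub2$sessions[[1]])),
                   names(trialMeta(sub$sessions[[1]])))
  expect_false(identical(sub2$sessions[[1]]@sensors, sub$sessions[[1]]@sensors))
})
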