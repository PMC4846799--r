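# A decoder whose posterior is "intend" iff the middle-window RMS exceeds a
# threshold; built directly so detection-timing tests do not depend on the
# LSPC fit.
thresholdDecoder <- function(tau) {
  centers <- rbind(c(0, 10, 0), c(0, 0, 0))   # one intend, one passive center
  new("LspcDecoder", centers = centers,
      weights = rbind(c(1, 0), c(0, 1)), sigma = 5, rho = 0.1,
      classes = c("intend", "passive"), featMean = c(0, tau / 2, 0),
      featSd = c(1, tau / 20, 1), anchorMs = 232, foldSeed = 1L, cvLoss = 0)
}

test_that("sliding detection fires at window ends, never before 120 ms", {
  dec <- thresholdDecoder(tau = 1)
  # silent trace: no window fires
  expect_identical(slidingDetect(dec, numeric(500)), NA_real_)
  # a block starting right at onset is caught by the earliest window at 120 ms
  x <- numeric(500)
  x[neuroadapt:::msToEpochIdx(0):neuroadapt:::msToEpochIdx(400)] <- 5
  expect_identical(slidingDetect(dec, x), 120)
  # a later block is detected at the first window end whose middle 40 ms
  # window reaches it: block at 400 ms -> windows ending >= 440 ms see it
  x2 <- numeric(500)
  x2[neuroadapt:::msToEpochIdx(400):neuroadapt:::msToEpochIdx(600)] <- 5
  d2 <- slidingDetect(dec, x2)
  expect_gte(d2, 440 - 40); expect_lte(d2, 460)
  expect_error(slidingDetect(dec, numeric(500), spanMs = c(0, 1500)), "span")
})

test_that("shifting a trace by two steps shifts its detection by 16 ms", {
  dec <- thresholdDecoder(tau = 1)
  x <- numeric(500)
  x[neuroadapt:::msToEpochIdx(200):neuroadapt:::msToEpochIdx(320)] <- 4
  d0 <- slidingDetect(dec, x)
  xs <- c(numeric(4), x[1:496])     # +16 ms at 250 Hz
  expect_identical(slidingDetect(dec, xs), d0 + 16)
})

test_that("batched detection matches per-trial detection", {
  ch <- smallChain()
  acts <- ch$complexActs@data[1:12, ch$comp, ]
  batch <- neuroadapt:::slidingDetectBatch(ch$decoder, acts)
  single <- vapply(1:12, function(i) slidingDetect(ch$decoder, acts[i, ]),
                   numeric(1))
  expect_identical(batch, single)
})

test_that("adjudication applies the faster-than-hand rule and conserves trials", {
  ch <- smallChain()
  summ <- adjudicateSession(ch$decoder, ch$complexActs, componentIndex = ch$comp)
  out <- outcomes(summ)
  conf <- confusionCounts(summ)
  meta <- ch$complexActs@meta
  pert <- meta$condition == "complex_perturbation"
  # outcome partition matches the screened trial split exactly
  expect_identical(conf[["tp"]] + conf[["fn"]], sum(pert))
  expect_identical(conf[["fp"]] + conf[["tn"]], sum(!pert))
  # hits are exactly the perturbation trials detected before the stick moved
  isHit <- out$outcome == "hit"
  expect_identical(isHit, !is.na(out$detectionMs) & pert &
                     out$detectionMs < out$manualRtMs)
  # misses keep the original response time and save nothing
  miss <- out$outcome == "miss"
  expect_identical(out$effectiveRtMs[miss], out$manualRtMs[miss])
  expect_true(all(out$savingsMs[miss] == 0))
  # detections never precede the earliest 120 ms window
  expect_true(all(out$detectionMs >= 120, na.rm = TRUE))
  # single-trial arithmetic: savings = manual RT - detection on a hit
  h1 <- which(isHit)[1]
  expect_equal(out$savingsMs[h1], out$manualRtMs[h1] - out$detectionMs[h1])
  # the mean difference is averaged over all perturbation trials
  expect_equal(savingsStats(summ)$diffMeanMs, mean(out$savingsMs[pert]))
})

test_that("a decoder that never fires leaves the manual response times untouched", {
  ch <- smallChain()
  mute <- ch$decoder
  mute@weights[] <- 0   # posterior falls back to uniform: never 'intend'
  summ <- adjudicateSession(mute, ch$complexActs, componentIndex = ch$comp)
  st <- savingsStats(summ)
  expect_identical(st$diffMeanMs, 0)
  expect_equal(st$bciMeanMs, st$orgMeanMs)
  expect_identical(confusionCounts(summ)[["fp"]], 0L)
})

test_that("requiring more consecutive windows never adds false alarms or speeds detection", {
  ch <- smallChain()
  s1 <- adjudicateSession(ch$decoder, ch$complexActs, componentIndex = ch$comp,
                          kConsecutive = 1L)
  s2 <- adjudicateSession(ch$decoder, ch$complexActs, componentIndex = ch$comp,
                          kConsecutive = 2L)
  expect_lte(confusionCounts(s2)[["fp"]], confusionCounts(s1)[["fp"]])
  d1 <- outcomes(s1)$detectionMs; d2 <- outcomes(s2)$detectionMs
  both <- !is.na(d1) & !is.na(d2)
  expect_true(all(d2[both] >= d1[both]))
  expect_gte(min(d2, na.rm = TRUE), min(d1, na.rm = TRUE))
})

test_that("altitude savings equal descent rate times time savings", {
  expect_equal(round(altitudeSavings(75.4, 139), 1), 10.5)
  expect_equal(round(altitudeSavings(69.1, 75), 1), 5.2)
  expect_identical(altitudeSavings(80, 0), 0)
  expect_error(altitudeSavings(-1, 10), "non-negative")
})
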