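# Shared fixtures, built once per test run. The "small" subject uses 12
# channels / 5 sources so the full decoding chain stays fast; the unmixing
# step uses the planted ground truth (the ICA fit has its own tests).

.fx <- new.env(parent = emptyenv())

smallConfig <- function(...) {
  args <- list(nChannels = 12L, nSources = 5L, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(subjectConfig, args)
}

# Complete decoding chain on the small subject, memoised.
smallChain <- function() {
  if (!is.null(.fx$chain)) return(.fx$chain)
  cfg <- smallConfig()
  sub <- simulateSubject(cfg)
  eps <- lapply(sub$sessions, segmentAndScreen)
  mod <- oracleUnmixing(sub$sessions[[1]])
  trainEp <- neuroadapt:::bindEpochs(eps[[1]], eps[[2]])
  mod <- selectTaskComponent(
    mod, neuroadapt:::subsetEpochs(trainEp, which(trainEp@meta$condition == "fly_perturbation")))
  comp <- selectedComponent(mod)
  trainActs <- componentActivations(mod, trainEp)
  s1fly <- which(trainActs@meta$sessionId == "S1_simple" &
                   trainActs@meta$condition == "fly_perturbation")
  anchor <- findPeakLatency(apply(trainActs@data[s1fly, comp, , drop = FALSE], 3, mean))
  feats <- assembleTrainingSet(trainActs@data[, comp, ], trainActs@meta, anchor)
  decoder <- fitLspc(feats, seed = 11L, anchorMs = anchor)
  .fx$chain <- list(cfg = cfg, sessions = sub$sessions, eps = eps, mod = mod,
                    comp = comp, trainActs = trainActs, anchor = anchor,
                    feats = feats, decoder = decoder,
                    evalActs = componentActivations(mod, eps[[3]]),
                    complexActs = componentActivations(mod, eps[[4]]))
  .fx$chain
}

# Two-class 3-d Gaussian toy problem for classifier tests.
toyFeatures <- function(n = 200, sep = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * 3), ncol = 3),
             matrix(rnorm(n / 2 * 3, mean = sep), ncol = 3))
  list(X = X, y = rep(c("intend", "passive"), each = n / 2))
}

rawBalancedAccuracy <- function(conf) {
  (conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]) +
     conf[["tn"]] / (conf[["fp"]] + conf[["tn"]])) / 2
}
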