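#' @name accessors
#' @title Accessors for the core pipeline classes
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param x an object of one of the package classes.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("trialMeta", function(x) standardGeneric("trialMeta"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("sessionTag", function(x) standardGeneric("sessionTag"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("screeningLog", function(x) standardGeneric("screeningLog"))
#' @rdname accessors
#' @export
setGeneric("combinedWeights", function(x) standardGeneric("combinedWeights"))
#' @rdname accessors
#' @export
setGeneric("selectedComponent", function(x) standardGeneric("selectedComponent"))
#' @rdname accessors
#' @export
setGeneric("selectionScores", function(x) standardGeneric("selectionScores"))
#' @rdname accessors
#' @export
setGeneric("anchorMs", function(x) standardGeneric("anchorMs"))
#' @rdname accessors
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("savingsStats", function(x) standardGeneric("savingsStats"))

#' @rdname accessors
setMethod("trialMeta", "SessionData", function(x) x@meta)
#' @rdname accessors
setMethod("trialMeta", "EpochArray", function(x) x@meta)
#' @rdname accessors
setMethod("samplingRate", "SessionData", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "EpochArray", function(x) x@fs)
#' @rdname accessors
setMethod("nTrials", "SessionData", function(x) dim(x@sensors)[1])
#' @rdname accessors
setMethod("nTrials", "EpochArray", function(x) dim(x@data)[1])
#' @rdname accessors
setMethod("sessionTag", "SessionData", function(x) x@sessionTag)
#' @rdname accessors
setMethod("groundTruth", "SessionData", function(x)
  if (length(x@groundTruth)) x@groundTruth else NULL)
#' @rdname accessors
setMethod("epochData", "EpochArray", function(x) x@data)
#' @rdname accessors
setMethod("screeningLog", "EpochArray", function(x) x@screeningLog)
#' @rdname accessors
setMethod("combinedWeights", "UnmixingModel", function(x) x@combinedWeights)
#' @rdname accessors
setMethod("selectedComponent", "UnmixingModel", function(x) x@selectedComponent)
#' @rdname accessors
setMethod("selectionScores", "UnmixingModel", function(x) x@selectionScores)
#' @rdname accessors
setMethod("anchorMs", "LspcDecoder", function(x) x@anchorMs)
#' @rdname accessors
setMethod("outcomes", "SavingsSummary", function(x) x@outcomes)
#' @rdname accessors
setMethod("confusionCounts", "SavingsSummary", function(x) x@confusion)
#' @rdname accessors
setMethod("savingsStats", "SavingsSummary", function(x) x@stats)

setMethod("show", "SubjectConfig", function(object) {
  cat("SubjectConfig:", object@nChannels, "channels,", object@nSources,
      "sources, fs", object@fsRaw, "Hz\n")
  cat("  evoked: fly", object@taskAmpFly, "/ watch fraction",
      object@taskAmpWatch, ", peak", object@peakLatencyMs, "ms\n")
  cat("  RT means (simple/complex):", object@rtMeanSimpleMs, "/",
      object@rtMeanComplexMs, "ms; seed", object@seed, "\n")
})

setMethod("show", "SessionData", function(object) {
  d <- dim(object@sensors)
  cat("SessionData [", object@sessionTag, "]: ", d[1], " trials x ", d[2],
      " channels x ", d[3], " samples @ ", object@fs, " Hz\n", sep = "")
  cat("  conditions:", paste(names(table(object@meta$condition)),
                             table(object@meta$condition), collapse = ", "), "\n")
})

setMethod("show", "EpochArray", function(object) {
  d <- dim(object@data)
  cat("EpochArray (", object@space, " space): ", d[1], " trials x ", d[2],
      " x ", d[3], " samples @ ", object@fs, " Hz\n", sep = "")
  dropped <- sum(!object@screeningLog$kept)
  if (nrow(object@screeningLog))
    cat("  screening: ", sum(object@screeningLog$kept), " kept, ",
        dropped, " dropped\n", sep = "")
})

setMethod("show", "UnmixingModel", function(object) {
  cat("UnmixingModel:", nrow(object@combinedWeights), "components x",
      ncol(object@combinedWeights), "channels (", object@sweeps, "ICA sweeps )\n")
  cat("  selected task component:",
      ifelse(is.na(object@selectedComponent), "<none>",
             object@selectedComponent), "\n")
})

setMethod("show", "LspcDecoder", function(object) {
  cat("LspcDecoder:", nrow(object@centers), "kernel centers, sigma",
      signif(object@sigma, 3), ", rho", object@rho, "\n")
  cat("  anchor", object@anchorMs, "ms; classes",
      paste(object@classes, collapse = "/"), "\n")
})

setMethod("show", "SavingsSummary", function(object) {
  cc <- object@confusion
  cat("SavingsSummary: tp", cc[["tp"]], "fn", cc[["fn"]], "fp", cc[["fp"]],
      "tn", cc[["tn"]], "\n")
  st <- object@stats
  cat(sprintf("  RT %.1f -> %.1f ms (savings %.1f ms)\n",
              st$orgMeanMs, st$bciMeanMs, st$diffMeanMs))
})
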