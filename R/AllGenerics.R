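# Generics and accessors. Slot access from user code should go through these.

#' @rdname EpochSet-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochInfo", function(x) standardGeneric("epochInfo"))

#' @rdname EpochSet-class
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname SyntheticSession-class
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname SyntheticSession-class
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname SyntheticSession-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname TrainedBci-class
#' @export
setGeneric("feedbackChannel", function(x) standardGeneric("feedbackChannel"))

#' @rdname TrainedBci-class
#' @export
setGeneric("loocvAccuracies", function(x) standardGeneric("loocvAccuracies"))

#' @rdname SessionResult-class
#' @export
setGeneric("channelAccuracies", function(x) standardGeneric("channelAccuracies"))

#' @rdname SessionResult-class
#' @export
setGeneric("trialLog", function(x) standardGeneric("trialLog"))

#' @describeIn EpochSet-class the epoch array (channels x samples x epochs).
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @describeIn EpochSet-class the per-epoch metadata data.frame.
#' @export
setMethod("epochInfo", "EpochSet", function(x) x@info)

#' @describeIn EpochSet-class number of epochs.
#' @export
setMethod("nEpochs", "EpochSet", function(x) nrow(x@info))

#' @describeIn SyntheticSession-class the continuous channels x samples matrix.
#' @export
setMethod("signalMatrix", "SyntheticSession", function(x) x@signal)

#' @describeIn SyntheticSession-class the stimulus event table.
#' @export
setMethod("eventTable", "SyntheticSession", function(x) x@events)

#' @describeIn SyntheticSession-class the generator's ground-truth list.
#' @export
setMethod("groundTruth", "SyntheticSession", function(x) x@groundTruth)

#' @describeIn TrainedBci-class label of the selected feedback channel.
#' @export
setMethod("feedbackChannel", "TrainedBci", function(x) x@feedbackChannel)

#' @describeIn TrainedBci-class named LOOCV accuracies of the five channels.
#' @export
setMethod("loocvAccuracies", "TrainedBci", function(x)
  vapply(x@channels, function(m) m@loocvAccuracy, numeric(1)))

#' @describeIn SessionResult-class named per-channel online accuracies (%).
#' @export
setMethod("channelAccuracies", "SessionResult", function(x)
  x@perChannelAccuracy)

#' @describeIn SessionResult-class the per-trial log data.frame.
#' @export
setMethod("trialLog", "SessionResult", function(x) x@trials)

setMethod("show", "ProtocolConfig", function(object) {
  cat("ProtocolConfig:", object@samplingRate, "Hz,",
      object@nTrainingBlocks, "training blocks,",
      object@nTestTrials, "test trials\n")
  cat("  isi", object@isi, "ms | epoch [", object@epochWindow[1], ",",
      object@epochWindow[2], "] ms (", epochSamples(object), "samples ) | ",
      "band", object@filterBand[1], "-", object@filterBand[2], "Hz\n")
  cat("  reject +/-", object@eegRejectThreshold, "uV EEG, +/-",
      object@eogRejectThreshold, "uV Fp1 | downsample x",
      object@downsampleFactor, "->", nFeatureSamples(object),
      "samples | alpha", object@alpha, "\n")
})

setMethod("show", "SyntheticSession", function(object) {
  cat("SyntheticSession:", nrow(object@signal), "channels x",
      ncol(object@signal), "samples (",
      round(ncol(object@signal) / object@samplingRate, 1), "s ),",
      nrow(object@events), "stimulus events\n")
  cat("  montage:", object@montage,
      "| attention gain:", object@groundTruth$attentionGain,
      "| corrupted epochs:", length(object@groundTruth$corrupted), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[3], "epochs x", d[1], "channels x", d[2], "samples;",
      sum(object@info$accepted), "accepted\n")
  if (nrow(object@info)) {
    print(table(condition = object@info$condition,
                accepted = object@info$accepted))
  }
})

setMethod("show", "TrainedBci", function(object) {
  accs <- loocvAccuracies(object)
  cat("TrainedBci: feedback channel", object@feedbackChannel, "\n")
  for (ch in names(accs)) {
    m <- object@channels[[ch]]
    cat(sprintf("  %-4s loocv %.3f | |iD| %d | |iV| %d\n", ch, accs[[ch]],
                length(m@indexSet@iD), length(m@indexSet@iV)))
  }
})

setMethod("show", "SessionResult", function(object) {
  cat("SessionResult:", nrow(object@trials), "trials\n")
  print(round(object@perChannelAccuracy, 1))
  cat(sprintf("  feedback %s: %.1f%% | max all %.1f%% | subset1 %.1f%% | subset2 %.1f%%\n",
              object@feedbackChannel, object@feedbackAccuracy, object@maxAll,
              object@maxSubset1, object@maxSubset2))
  cat(sprintf("  ITR %.2f bits/min at %.1f s per decision\n",
              object@itr, object@meanDecisionTime))
})

setMethod("show", "GrandAverage", function(object) {
  cat("GrandAverage over conditions:",
      paste(names(object@waveforms), collapse = ", "), "\n")
  print(object@divergence)
})
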