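# Model module: per-channel RBF-SVM training with a median-distance kernel
# scale, leave-one-out cross-validation and feedback-channel selection.

#' Train one channel's RBF-SVM attention classifier
#'
#' The kernel scale is set by the parameter-free median heuristic -- the
#' median pairwise Euclidean distance among the training vectors, computed
#' once on the full set -- giving `gamma = 1 / (2 * scale^2)`; the
#' regularization constant is fixed at 1. Features are left unstandardized:
#' all amplitudes share uV units. Performance is estimated by plain
#' leave-one-out cross-validation (refit on n-1, classify the held-out
#' vector).
#'
#' @param vectors list with `x`, `y`, `channel` from
#'   [buildFeatureVectors()], or a matrix (then supply `y` and `channel`).
#' @param y,channel used when `vectors` is a bare matrix.
#' @param indexSet optional [FeatureIndexSet-class] stored with the model.
#' @return a [ChannelModel-class].
#' @examples
#' x <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 5, 0.1), 10))
#' m <- trainChannel(list(x = x,
#'                        y = factor(rep(c("AD", "AV"), each = 10)),
#'                        channel = "Ci"))
#' m@loocvAccuracy  # 1
#' @export
trainChannel <- function(vectors, y = NULL, channel = NULL,
                         indexSet = NULL) {
  if (is.list(vectors) && !is.null(vectors$x)) {
    x <- vectors$x
    y <- vectors$y
    channel <- vectors$channel
  } else {
    x <- vectors
  }
  y <- factor(y, levels = c("AD", "AV"))
  counts <- table(y)
  if (any(counts < 2)) stop("need at least 2 vectors per class")
  if (counts[1] != counts[2]) stop("class counts must be equal")
  n <- nrow(x)
  ks <- median(dist(x))
  if (!is.finite(ks) || ks <= 0) ks <- 1
  gamma <- 1 / (2 * ks^2)
  fitSvm <- function(xi, yi) {
    e1071::svm(xi, yi, type = "C-classification", kernel = "radial",
               gamma = gamma, cost = 1, scale = FALSE)
  }
  correct <- vapply(seq_len(n), function(i) {
    fit <- fitSvm(x[-i, , drop = FALSE], y[-i])
    as.character(predict(fit, x[i, , drop = FALSE])) == as.character(y[i])
  }, logical(1))
  fit <- fitSvm(x, y)
  if (is.null(indexSet)) {
    indexSet <- new("FeatureIndexSet", channel = channel %||% "?",
                    iD = integer(), iV = integer(),
                    pD = numeric(), pV = numeric(),
                    fallbackD = FALSE, fallbackV = FALSE)
  }
  new("ChannelModel", channel = channel %||% indexSet@channel, fit = fit,
      kernelScale = ks, cost = 1, indexSet = indexSet,
      loocvAccuracy = mean(correct), nVectors = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a feature vector with a trained channel model
#'
#' @param model a [ChannelModel-class].
#' @param vec numeric feature vector of the trained length.
#' @return `"AD"` or `"AV"`.
#' @export
predictChannel <- function(model, vec) {
  as.character(predict(model@fit, matrix(vec, nrow = 1)))
}

#' Select the feedback channel from five trained channel models
#'
#' The channel with the highest LOOCV accuracy becomes the feedback source.
#' Ties are broken deterministically by ipsilesional priority
#' Ci > CPi > Pi > Cz > Cc.
#'
#' @param models named list of five [ChannelModel-class] objects.
#' @param config a [ProtocolConfig-class] stored with the result.
#' @param trainingInfo optional diagnostics list.
#' @return a [TrainedBci-class].
#' @export
selectFeedbackChannel <- function(models, config = protocolConfig(),
                                  trainingInfo = list()) {
  stopifnot(length(models) == length(bciEegChannels()))
  if (is.null(names(models))) {
    names(models) <- vapply(models, function(m) m@channel, "")
  }
  models <- models[bciEegChannels()]
  accs <- vapply(models, function(m) m@loocvAccuracy, numeric(1))
  best <- names(models)[which.max(accs)]  # which.max keeps priority order
  new("TrainedBci", channels = models, feedbackChannel = best,
      config = config, trainingInfo = trainingInfo)
}

#' Train the full five-channel BCI from a training recording
#'
#' Runs the complete training pipeline: causal band-pass filtering,
#' epoching with baseline correction, amplitude-threshold rejection,
#' condition clustering and balancing, sub-averaging with decimation,
#' per-channel index screening, feature-vector construction, per-channel
#' SVM training with LOOCV, and feedback-channel selection.
#'
#' @param x a [SyntheticSession-class], or a channels x samples matrix.
#' @param events event data.frame (ignored when `x` is a session).
#' @param config a [ProtocolConfig-class] (ignored when `x` is a session).
#' @param filtered set TRUE when `x` is already band-pass filtered.
#' @return a [TrainedBci-class].
#' @export
trainBci <- function(x, events = NULL, config = NULL, filtered = FALSE) {
  if (is(x, "SyntheticSession")) {
    events <- x@events
    config <- x@config
    x <- x@signal
  }
  if (!filtered) x <- bandpassFilter(x, config)
  training <- events[events$phase == "training", , drop = FALSE]
  epochs <- rejectArtifacts(segmentEpochs(x, training, config))
  balanced <- clusterAndBalance(epochs)
  subavgs <- makeSubaverages(balanced, config)
  models <- lapply(bciEegChannels(), function(ch) {
    idx <- screenIndices(subavgs, ch, config)
    trainChannel(buildFeatureVectors(subavgs, idx), indexSet = idx)
  })
  names(models) <- bciEegChannels()
  info <- list(
    clusterSizes = attr(balanced, "clusterSizes"),
    balancedSize = nEpochs(balanced) / 4,
    nSubaverages = subavgs@nGroups,
    nRejected = sum(!epochs@info$accepted))
  selectFeedbackChannel(models, config, info)
}

#' Persist and restore a trained BCI
#'
#' The archive is a self-describing serialized object holding the kernel
#' parameters, support data, screened index sets and configuration; a
#' reloaded model reproduces predictions exactly.
#'
#' @param trained a [TrainedBci-class].
#' @param path file path.
#' @return `readTrainedBci()` returns the [TrainedBci-class].
#' @export
saveTrainedBci <- function(trained, path) {
  stopifnot(is(trained, "TrainedBci"))
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname saveTrainedBci
#' @export
readTrainedBci <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "TrainedBci"))
  obj
}
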