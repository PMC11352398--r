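# Online module: the simulated test loop (accumulate 10 artifact-free epochs
# per location, average, extract the stored indices, classify per channel,
# emit feedback), plus the session accuracy and Wolpaw ITR closed forms.

#' Run one online classification trial
#'
#' Consumes the trial's epochs in delivery order, accumulating accepted
#' epochs per stimulated location until `cleanEpochsPerLocation` (10) are
#' collected for both. The two location averages are then cropped,
#' decimated, the channel's stored indices extracted, and the flattened
#' vector `c(avgD[iD], avgV[iV])` classified by every channel model; the
#' feedback prediction is the selected channel's. If the epoch stream ends
#' before both quotas are met the trial is aborted with status
#' `"budget_exhausted"` and excluded from tallies.
#'
#' Online feature extraction reuses the training-path code (same causal
#' filter, same baseline correction, same rejection thresholds, same
#' decimation), so identical epochs produce bit-identical features.
#'
#' @param epochs an [EpochSet-class] holding this trial's epochs (already
#'   filtered, baseline-corrected and passed through [rejectArtifacts()]).
#' @param trained a [TrainedBci-class].
#' @param config a [ProtocolConfig-class]; defaults to the trained model's.
#' @return list with `trial_id`, `target`, `predictions` (named per
#'   channel), `feedback_prediction`, `stimuli_delivered`,
#'   `epochs_rejected`, `status` (`"complete"` or `"budget_exhausted"`).
#' @export
runTrial <- function(epochs, trained, config = trained@config) {
  info <- epochs@info
  ord <- order(info$onset_sample)
  quota <- config@cleanEpochsPerLocation
  got <- list(D = integer(), V = integer())
  delivered <- 0L
  rejected <- 0L
  for (j in ord) {
    delivered <- delivered + 1L
    loc <- info$location[j]
    if (!info$accepted[j]) {
      rejected <- rejected + 1L
    } else if (length(got[[loc]]) < quota) {
      got[[loc]] <- c(got[[loc]], j)
    }
    if (length(got$D) == quota && length(got$V) == quota) break
  }
  target <- info$attended_location[1]
  trialId <- info$unit_id[1]
  if (length(got$D) < quota || length(got$V) < quota) {
    return(list(trial_id = trialId, target = target,
                predictions = NULL, feedback_prediction = NA_character_,
                stimuli_delivered = delivered, epochs_rejected = rejected,
                status = "budget_exhausted"))
  }
  avgOf <- function(idx) {
    .decimatePostStimulus(
      rowMeans(epochs@data[, , idx, drop = FALSE], dims = 2), config)
  }
  avgD <- avgOf(got$D)
  avgV <- avgOf(got$V)
  preds <- vapply(trained@channels, function(m) {
    vec <- c(avgD[m@channel, m@indexSet@iD], avgV[m@channel, m@indexSet@iV])
    predictChannel(m, vec)
  }, "")
  list(trial_id = trialId, target = target, predictions = preds,
       feedback_prediction = preds[[trained@feedbackChannel]],
       stimuli_delivered = delivered, epochs_rejected = rejected,
       status = "complete")
}

#' Run the full online test phase of a session
#'
#' Filters the continuous recording (causal, identical to training),
#' segments and screens the test-phase epochs, runs each trial with
#' [runTrial()], tallies per-channel true/false positives over completed
#' trials, and assembles a [SessionResult-class] with per-channel
#' accuracies, subset maxima, the feedback-channel accuracy and the Wolpaw
#' ITR at the session's mean decision time (stimuli delivered x 700 ms).
#'
#' @param x a [SyntheticSession-class] or channels x samples matrix.
#' @param trained a [TrainedBci-class].
#' @param events,config used when `x` is a matrix.
#' @param filtered set TRUE when `x` is already band-pass filtered.
#' @return a [SessionResult-class].
#' @export
runTestPhase <- function(x, trained, events = NULL, config = NULL,
                         filtered = FALSE) {
  if (is(x, "SyntheticSession")) {
    events <- x@events
    config <- x@config
    x <- x@signal
  }
  if (is.null(config)) config <- trained@config
  if (!filtered) x <- bandpassFilter(x, config)
  test <- events[events$phase == "test", , drop = FALSE]
  epochs <- rejectArtifacts(segmentEpochs(x, test, config))
  chs <- names(trained@channels)
  outcomes <- lapply(unique(test$unit_id), function(id) {
    runTrial(.subsetEpochs(epochs, which(epochs@info$unit_id == id)),
             trained, config)
  })
  logDf <- do.call(rbind, lapply(outcomes, function(o) {
    row <- data.frame(trial_id = o$trial_id, target = o$target,
                      feedback_prediction = o$feedback_prediction,
                      stimuli_delivered = o$stimuli_delivered,
                      epochs_rejected = o$epochs_rejected,
                      status = o$status, stringsAsFactors = FALSE)
    for (ch in chs) {
      row[[paste0("pred_", ch)]] <-
        if (is.null(o$predictions)) NA_character_ else o$predictions[[ch]]
    }
    row
  }))
  complete <- logDf$status == "complete"
  tallies <- lapply(chs, function(ch) {
    pred <- logDf[[paste0("pred_", ch)]][complete]
    target <- logDf$target[complete]
    c(TP_AD = sum(target == "D" & pred == "AD"),
      TP_AV = sum(target == "V" & pred == "AV"),
      FP_AD = sum(target == "D" & pred == "AV"),
      FP_AV = sum(target == "V" & pred == "AD"))
  })
  names(tallies) <- chs
  accs <- vapply(tallies, computeAccuracy, numeric(1))
  fb <- trained@feedbackChannel
  meanT <- mean(logDf$stimuli_delivered[complete]) * config@isi / 1000
  itr <- computeItr(2, meanT, accs[[fb]] / 100)
  s1 <- intersect(c("Ci", "CPi", "Pi"), chs)
  s2 <- intersect(c("Cz", "Cc"), chs)
  new("SessionResult",
      perChannelAccuracy = accs, feedbackChannel = fb,
      feedbackAccuracy = accs[[fb]], maxAll = max(accs),
      maxSubset1 = max(accs[s1]), maxSubset2 = max(accs[s2]),
      itr = itr, meanDecisionTime = meanT, trials = logDf,
      tallies = tallies)
}

#' Online classification accuracy from a trial tally
#'
#' `100 * (TP_AD + TP_AV) / (TP_AD + TP_AV + FP_AD + FP_AV)`, where TP(AD)
#' counts correctly classified attended-D trials and FP(AD) attended-D
#' trials misclassified as AV (and symmetrically for AV).
#'
#' @param tally named numeric vector or list with `TP_AD`, `TP_AV`,
#'   `FP_AD`, `FP_AV`.
#' @return accuracy in percent.
#' @examples
#' computeAccuracy(c(TP_AD = 10, TP_AV = 7, FP_AD = 0, FP_AV = 3))  # 85
#' @export
computeAccuracy <- function(tally) {
  tally <- as.list(tally)
  tp <- tally$TP_AD + tally$TP_AV
  denom <- tp + tally$FP_AD + tally$FP_AV
  if (denom == 0) stop("accuracy undefined: no classified trials")
  100 * tp / denom
}

#' Wolpaw information transfer rate
#'
#' Bits per decision
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`, with the
#' conventions `B = log2(N)` at `P = 1` and `0 * log2(0) = 0`, scaled to
#' bits per minute by `60 / secondsPerDecision`. At the protocol's 14 s
#' decision time (20 epochs x 700 ms) and perfect binary accuracy this is
#' 4.29 bits/min.
#'
#' @param nTargets number of targets N (>= 2).
#' @param secondsPerDecision seconds per classification decision.
#' @param accuracy P, fraction in [0, 1].
#' @return bits per minute.
#' @examples
#' computeItr(2, 14, 1)    # 4.2857...
#' computeItr(2, 14, 0.5)  # 0
#' @export
computeItr <- function(nTargets, secondsPerDecision, accuracy) {
  stopifnot(nTargets >= 2, accuracy >= 0, accuracy <= 1,
            secondsPerDecision > 0)
  p <- accuracy
  xlog <- function(v) if (v > 0) v * log2(v) else 0
  bits <- log2(nTargets) + xlog(p) + xlog(1 - p) -
    (1 - p) * log2(nTargets - 1)
  60 * bits / secondsPerDecision
}
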