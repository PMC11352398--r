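# S4 class definitions. Constructors, accessors and methods live in the
# per-module files (protocol.R, synthdata.R, preprocess.R, ...).

#' ProtocolConfig: acquisition and protocol constants
#'
#' Holds every constant of the two-phase protocol: sampling rate, stimulus
#' timing, block/trial counts, epoch windows, filter band, artifact-rejection
#' thresholds, downsampling factor and the screening significance level.
#' Create with [protocolConfig()].
#'
#' @slot samplingRate samples per second (default 1200).
#' @slot isi inter-stimulus onset-to-onset interval in ms (default 700).
#' @slot stimPeriod scheduled per-stimulus period in ms used for duration
#'   accounting (default 750), so that a 30-stimulus block occupies 22.5 s.
#' @slot blocksPerTask training blocks per attention task (default 15).
#' @slot nTrainingBlocks total training blocks; must equal `2 * blocksPerTask`.
#' @slot stimuliPerLocationPerBlock stimuli per location per block (default 15).
#' @slot trialsPerTarget online test trials per target location (default 10).
#' @slot nTestTrials total test trials; must equal `2 * trialsPerTarget`.
#' @slot cleanEpochsPerLocation artifact-free epochs required per location to
#'   complete an online trial (default 10).
#' @slot maxStimuliPerTrial stimulus budget per online trial (default 30).
#' @slot interBlockPause pause between blocks/trials in seconds (default 5).
#' @slot leadIn seconds of artifact-free recording inserted before the first
#'   stimulus so the causal filter transient is excluded from epoching
#'   (default 5).
#' @slot epochWindow epoch window in ms relative to stimulus onset,
#'   default `c(-100, 600)` (840 samples at 1200 Hz).
#' @slot baselineWindow baseline window in ms, default `c(-100, 0)`.
#' @slot filterBand band-pass corner frequencies in Hz, default `c(0.1, 25)`.
#' @slot filterOrder Butterworth section order (default 4).
#' @slot eegRejectThreshold rejection threshold in uV on the five
#'   somatosensory channels (default 50).
#' @slot eogRejectThreshold rejection threshold in uV on Fp1 (default 80).
#' @slot downsampleFactor decimation stride applied to averaged sERPs
#'   (default 8, giving 90 post-stimulus samples).
#' @slot alpha screening significance level (default 0.05).
#' @slot subaverageSize epochs per sub-average used for screening (default 10).
#' @export
setClass("ProtocolConfig", representation(
  samplingRate = "numeric",
  isi = "numeric",
  stimPeriod = "numeric",
  blocksPerTask = "numeric",
  nTrainingBlocks = "numeric",
  stimuliPerLocationPerBlock = "numeric",
  trialsPerTarget = "numeric",
  nTestTrials = "numeric",
  cleanEpochsPerLocation = "numeric",
  maxStimuliPerTrial = "numeric",
  interBlockPause = "numeric",
  leadIn = "numeric",
  epochWindow = "numeric",
  baselineWindow = "numeric",
  filterBand = "numeric",
  filterOrder = "numeric",
  eegRejectThreshold = "numeric",
  eogRejectThreshold = "numeric",
  downsampleFactor = "numeric",
  alpha = "numeric",
  subaverageSize = "numeric"
))

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  pos <- c("samplingRate", "isi", "stimPeriod", "blocksPerTask",
           "stimuliPerLocationPerBlock", "trialsPerTarget",
           "cleanEpochsPerLocation", "maxStimuliPerTrial", "filterOrder",
           "downsampleFactor", "subaverageSize")
  for (s in pos) {
    if (slot(object, s) <= 0) msg <- c(msg, paste0(s, " must be positive"))
  }
  if (object@nTrainingBlocks != 2 * object@blocksPerTask)
    msg <- c(msg, "nTrainingBlocks must equal 2 * blocksPerTask")
  if (object@nTestTrials != 2 * object@trialsPerTarget)
    msg <- c(msg, "nTestTrials must equal 2 * trialsPerTarget")
  if (length(object@epochWindow) != 2 || diff(object@epochWindow) <= 0)
    msg <- c(msg, "epochWindow must be an increasing ms pair")
  if (length(object@baselineWindow) != 2 || diff(object@baselineWindow) <= 0)
    msg <- c(msg, "baselineWindow must be an increasing ms pair")
  if (length(object@filterBand) != 2 || diff(object@filterBand) <= 0)
    msg <- c(msg, "filterBand must be an increasing Hz pair")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  es <- diff(object@epochWindow) / 1000 * object@samplingRate
  if (abs(es - round(es)) > 1e-9)
    msg <- c(msg, "epoch window must span an integer number of samples")
  post <- object@epochWindow[2] / 1000 * object@samplingRate
  if (post %% object@downsampleFactor != 0)
    msg <- c(msg, "post-stimulus samples must be divisible by downsampleFactor")
  if (object@maxStimuliPerTrial < 2 * object@cleanEpochsPerLocation)
    msg <- c(msg, "maxStimuliPerTrial must allow 2 * cleanEpochsPerLocation")
  if (length(msg)) msg else TRUE
})

#' SerpTemplate: stimulus-locked sERP waveform for one location
#'
#' A per-location template over the post-stimulus window (0..600 ms), with a
#' per-channel gain vector, an early window where attention has no effect and
#' a late window whose amplitude is multiplied by `attentionGain` when the
#' stimulated location is attended. Create with [serpTemplate()] or
#' [defaultTemplates()].
#'
#' @slot location `"D"` or `"V"`.
#' @slot waveform numeric vector over the post-stimulus window at
#'   `samplingRate` (zero outside 0..600 ms by construction).
#' @slot samplingRate samples per second.
#' @slot channelGains named numeric multipliers per channel
#'   (largest on Ci/CPi/Pi; 0 on Fp1 by default).
#' @slot earlyWindow ms pair where attention has no effect (default 0-150).
#' @slot lateWindow ms pair where attention scales amplitude (default 150-600).
#' @slot attentionGain multiplicative factor >= 1 applied to the late window
#'   when the stimulated location is attended.
#' @export
setClass("SerpTemplate", representation(
  location = "character",
  waveform = "numeric",
  samplingRate = "numeric",
  channelGains = "numeric",
  earlyWindow = "numeric",
  lateWindow = "numeric",
  attentionGain = "numeric"
))

setValidity("SerpTemplate", function(object) {
  msg <- character()
  if (!object@location %in% c("D", "V"))
    msg <- c(msg, "location must be \"D\" or \"V\"")
  if (object@attentionGain < 1)
    msg <- c(msg, "attentionGain must be >= 1")
  if (is.null(names(object@channelGains)))
    msg <- c(msg, "channelGains must be named by channel")
  if (length(object@lateWindow) != 2 || diff(object@lateWindow) <= 0)
    msg <- c(msg, "lateWindow must be an increasing ms pair")
  if (length(msg)) msg else TRUE
})

#' NoiseModel: background noise and artifact generator parameters
#'
#' Background EEG is an order-2 autoregressive process (low-pass character);
#' ocular artifacts (blinks) are injected on Fp1 and slow drift excursions on
#' the somatosensory channels. Injected artifact amplitudes exceed the
#' rejection thresholds by construction, so they are rejectable downstream.
#' Create with [noiseModel()].
#'
#' @slot backgroundSd stationary standard deviation of the background process
#'   in uV (default 5).
#' @slot arCoefficients AR(2) coefficients (default `c(1.0, -0.3)`).
#' @slot blinkRate blink events per minute on Fp1 (default 1.2).
#' @slot blinkAmplitude blink peak amplitude in uV, must exceed the 80 uV
#'   Fp1 threshold (default 300).
#' @slot blinkDuration blink duration in seconds (default 0.15).
#' @slot driftRate drift events per minute on EEG channels (default 0.8).
#' @slot driftAmplitude drift peak amplitude in uV, must exceed the 50 uV
#'   EEG threshold (default 150).
#' @slot driftDuration drift duration in seconds (default 0.4).
#' @export
setClass("NoiseModel", representation(
  backgroundSd = "numeric",
  arCoefficients = "numeric",
  blinkRate = "numeric",
  blinkAmplitude = "numeric",
  blinkDuration = "numeric",
  driftRate = "numeric",
  driftAmplitude = "numeric",
  driftDuration = "numeric"
))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@blinkAmplitude <= 80)
    msg <- c(msg, "blinkAmplitude must exceed the 80 uV Fp1 threshold")
  if (object@driftAmplitude <= 50)
    msg <- c(msg, "driftAmplitude must exceed the 50 uV EEG threshold")
  if (object@backgroundSd < 0) msg <- c(msg, "backgroundSd must be >= 0")
  if (length(object@arCoefficients) != 2)
    msg <- c(msg, "arCoefficients must have length 2")
  if (length(msg)) msg else TRUE
})

#' SyntheticSession: a generated continuous recording plus ground truth
#'
#' Continuous multi-channel signal (uV), the stimulus event table and the
#' generator's ground truth (artifact positions, artifact-corrupted epoch
#' indices, attention gain). Create with [generateSession()].
#'
#' @slot signal channels x samples matrix in uV, rownames are channel labels.
#' @slot samplingRate samples per second.
#' @slot events stimulus event table (see [scheduleSession()]).
#' @slot config the [ProtocolConfig-class] used.
#' @slot montage `"right_impaired"` or `"left_impaired"`.
#' @slot groundTruth list with elements `corrupted` (event indices whose epoch
#'   window overlaps an injected above-threshold artifact core), `artifacts`
#'   (data.frame of injected artifacts), `attentionGain`, `templates`.
#' @export
setClass("SyntheticSession", representation(
  signal = "matrix",
  samplingRate = "numeric",
  events = "data.frame",
  config = "ProtocolConfig",
  montage = "character",
  groundTruth = "list"
))

setValidity("SyntheticSession", function(object) {
  msg <- character()
  if (is.null(rownames(object@signal)))
    msg <- c(msg, "signal must have channel rownames")
  if (nrow(object@events)) {
    needed <- max(object@events$onset_sample) +
      object@config@epochWindow[2] / 1000 * object@samplingRate
    if (ncol(object@signal) < needed)
      msg <- c(msg, "signal must cover the last event onset + epoch window")
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: stimulus-locked EEG segments with metadata
#'
#' Baseline-corrected epochs as a channels x samples x epochs array plus a
#' metadata data.frame (stimulated/attended location, condition, phase,
#' unit id, accepted flag and rejection reason). Created by [segmentEpochs()].
#'
#' @slot data channels x epochSamples x nEpochs array, uV.
#' @slot info data.frame with one row per epoch.
#' @slot samplingRate samples per second.
#' @slot config the [ProtocolConfig-class] used for segmentation.
#' @export
setClass("EpochSet", representation(
  data = "array",
  info = "data.frame",
  samplingRate = "numeric",
  config = "ProtocolConfig"
))

setValidity("EpochSet", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3)
    msg <- c(msg, "data must be a 3-dimensional array")
  else if (dim(object@data)[3] != nrow(object@info))
    msg <- c(msg, "third array dimension must match nrow(info)")
  if (length(msg)) msg else TRUE
})

#' SubAverageSet: per-condition 10-epoch sub-averages, downsampled
#'
#' Chronological, non-overlapping groups of `subaverageSize` epochs per
#' condition are averaged, cropped to the post-stimulus window and decimated
#' to 90 samples. Created by [makeSubaverages()].
#'
#' @slot data named list over conditions (ADSD, ADSV, AVSD, AVSV) of
#'   channels x 90 x nGroups arrays.
#' @slot nGroups sub-averages per condition.
#' @slot times post-stimulus sample times in ms (length 90 at defaults).
#' @slot config the [ProtocolConfig-class] used.
#' @export
setClass("SubAverageSet", representation(
  data = "list",
  nGroups = "numeric",
  times = "numeric",
  config = "ProtocolConfig"
))

#' FeatureIndexSet: screened time indices for one channel
#'
#' Time indices (1-based, over the 90 downsampled post-stimulus samples)
#' where the rank-sum screening found a significant attention effect, per
#' stimulated location: `iD` from ADSD vs AVSD and `iV` from AVSV vs ADSV.
#' If no index passes for a location, the single minimum-p index is retained
#' and the corresponding fallback flag set. Created by [screenIndices()].
#'
#' @slot channel channel label.
#' @slot iD sorted significant indices for stimulated-D epochs.
#' @slot iV sorted significant indices for stimulated-V epochs.
#' @slot pD per-index p-values, ADSD vs AVSD.
#' @slot pV per-index p-values, AVSV vs ADSV.
#' @slot fallbackD,fallbackV TRUE when the fallback (minimum-p) index was used.
#' @export
setClass("FeatureIndexSet", representation(
  channel = "character",
  iD = "integer",
  iV = "integer",
  pD = "numeric",
  pV = "numeric",
  fallbackD = "logical",
  fallbackV = "logical"
))

setValidity("FeatureIndexSet", function(object) {
  msg <- character()
  if (is.unsorted(object@iD, strictly = TRUE) && length(object@iD) > 1)
    msg <- c(msg, "iD must be strictly sorted")
  if (is.unsorted(object@iV, strictly = TRUE) && length(object@iV) > 1)
    msg <- c(msg, "iV must be strictly sorted")
  if (length(msg)) msg else TRUE
})

#' ChannelModel: one channel's trained attention classifier
#'
#' An RBF-kernel SVM over the channel's flattened feature vectors, with the
#' kernel scale set to the median pairwise Euclidean distance among training
#' vectors, regularization constant 1, and a leave-one-out cross-validation
#' accuracy estimate. Created by [trainChannel()].
#'
#' @slot channel channel label.
#' @slot fit the fitted `e1071::svm` object.
#' @slot kernelScale median pairwise distance used as the RBF scale.
#' @slot cost regularization constant (1).
#' @slot indexSet the channel's [FeatureIndexSet-class].
#' @slot loocvAccuracy leave-one-out accuracy in [0, 1].
#' @slot nVectors number of training vectors.
#' @export
setClass("ChannelModel", representation(
  channel = "character",
  fit = "ANY",
  kernelScale = "numeric",
  cost = "numeric",
  indexSet = "ANY",
  loocvAccuracy = "numeric",
  nVectors = "numeric"
))

setValidity("ChannelModel", function(object) {
  if (object@loocvAccuracy < 0 || object@loocvAccuracy > 1)
    "loocvAccuracy must lie in [0, 1]" else TRUE
})

#' TrainedBci: the five per-channel classifiers plus the feedback channel
#'
#' Created by [trainBci()] or [selectFeedbackChannel()]. The feedback channel
#' is the one with maximal LOOCV accuracy; ties are broken by ipsilesional
#' priority Ci > CPi > Pi > Cz > Cc.
#'
#' @slot channels named list of five [ChannelModel-class] objects.
#' @slot feedbackChannel label of the selected feedback channel.
#' @slot config the [ProtocolConfig-class] used in training.
#' @slot trainingInfo list of diagnostics (cluster sizes, rejection counts,
#'   sub-average counts).
#' @export
setClass("TrainedBci", representation(
  channels = "list",
  feedbackChannel = "character",
  config = "ProtocolConfig",
  trainingInfo = "list"
))

setValidity("TrainedBci", function(object) {
  msg <- character()
  if (!object@feedbackChannel %in% names(object@channels))
    msg <- c(msg, "feedbackChannel must name one of the trained channels")
  accs <- vapply(object@channels, function(m) m@loocvAccuracy, numeric(1))
  if (accs[object@feedbackChannel] < max(accs) - 1e-12)
    msg <- c(msg, "feedbackChannel must have maximal LOOCV accuracy")
  if (length(msg)) msg else TRUE
})

#' SessionResult: online test-phase tallies and accuracies
#'
#' Per-channel online accuracies (percent), subset maxima, feedback-channel
#' accuracy, Wolpaw information transfer rate at the session's mean decision
#' time, and the per-trial log. Created by [runTestPhase()].
#'
#' @slot perChannelAccuracy named percent accuracies for the five channels.
#' @slot feedbackChannel label of the feedback channel used.
#' @slot feedbackAccuracy percent accuracy of the feedback channel.
#' @slot maxAll maximum accuracy over all channels.
#' @slot maxSubset1 maximum over the ipsilesional subset (Ci, CPi, Pi).
#' @slot maxSubset2 maximum over the central/contralesional subset (Cz, Cc).
#' @slot itr information transfer rate, bits per minute.
#' @slot meanDecisionTime mean seconds per completed trial decision.
#' @slot trials per-trial log data.frame.
#' @slot tallies named list of per-channel TP/FP tallies.
#' @export
setClass("SessionResult", representation(
  perChannelAccuracy = "numeric",
  feedbackChannel = "character",
  feedbackAccuracy = "numeric",
  maxAll = "numeric",
  maxSubset1 = "numeric",
  maxSubset2 = "numeric",
  itr = "numeric",
  meanDecisionTime = "numeric",
  trials = "data.frame",
  tallies = "list"
))

setValidity("SessionResult", function(object) {
  msg <- character()
  if (length(object@perChannelAccuracy) &&
      (object@maxSubset1 > object@maxAll + 1e-9 ||
       object@maxSubset2 > object@maxAll + 1e-9))
    msg <- c(msg, "subset maxima cannot exceed the overall maximum")
  if (length(msg)) msg else TRUE
})

#' GrandAverage: condition-mean sERP waveforms and divergence onsets
#'
#' Mean waveforms per condition and channel over all accepted epochs
#' (-100..600 ms), and the earliest time at which the attended and unattended
#' waveforms for the same stimulated location diverge beyond a criterion for
#' at least five consecutive samples. Created by [grandAverage()].
#'
#' @slot waveforms named list over conditions of channels x samples matrices.
#' @slot times sample times in ms.
#' @slot divergence data.frame with location, channel, criterion and
#'   `onset_ms` (NA when no divergence is found).
#' @slot nEpochs named epoch counts per condition.
#' @export
setClass("GrandAverage", representation(
  waveforms = "list",
  times = "numeric",
  divergence = "data.frame",
  nEpochs = "numeric"
))
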