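# Protocol module: the two-phase experimental design and stimulus scheduling.
#
# Timing convention: onset-to-onset spacing within a block/trial uses `isi`
# (700 ms); scheduled block/trial DURATION accounting uses `stimPeriod`
# (750 ms), so a 30-stimulus block occupies 22.5 s and a 20-30 stimulus trial
# 15-22.5 s. Sample indices are 0-based; an epoch spans the half-open window
# [onset - 120, onset + 720) samples at defaults.

#' Construct a protocol configuration
#'
#' All arguments default to the study protocol: 1200 Hz sampling, 700 ms ISI,
#' 30 training blocks of 30 stimuli (15 per location), 20 online test trials
#' requiring 10 clean epochs per location from a budget of 30 stimuli,
#' 0.1-25 Hz band-pass, -100..600 ms epochs, +/-50 uV (EEG) and +/-80 uV
#' (Fp1) rejection thresholds, decimation by 8 and screening at alpha 0.05.
#'
#' @param samplingRate samples per second.
#' @param isi inter-stimulus onset interval, ms.
#' @param stimPeriod scheduled per-stimulus period for duration accounting, ms.
#' @param blocksPerTask training blocks per attention task.
#' @param nTrainingBlocks total training blocks (`2 * blocksPerTask`).
#' @param stimuliPerLocationPerBlock stimuli per location per block.
#' @param trialsPerTarget online trials per target location.
#' @param nTestTrials total online trials (`2 * trialsPerTarget`).
#' @param cleanEpochsPerLocation clean epochs needed per location per trial.
#' @param maxStimuliPerTrial per-trial stimulus budget.
#' @param interBlockPause pause between blocks/trials, seconds.
#' @param leadIn artifact-free lead-in before the first stimulus, seconds.
#' @param epochWindow,baselineWindow ms pairs relative to stimulus onset.
#' @param filterBand band-pass corners, Hz.
#' @param filterOrder Butterworth section order.
#' @param eegRejectThreshold,eogRejectThreshold rejection thresholds, uV.
#' @param downsampleFactor decimation stride for averaged sERPs.
#' @param alpha screening significance level.
#' @param subaverageSize epochs per sub-average.
#' @return a validated [ProtocolConfig-class] object.
#' @examples
#' cfg <- protocolConfig()
#' epochSamples(cfg)      # 840
#' nFeatureSamples(cfg)   # 90
#' blockDuration(cfg)     # 22.5 s
#' @export
protocolConfig <- function(samplingRate = 1200,
                           isi = 700,
                           stimPeriod = 750,
                           blocksPerTask = 15,
                           nTrainingBlocks = 2 * blocksPerTask,
                           stimuliPerLocationPerBlock = 15,
                           trialsPerTarget = 10,
                           nTestTrials = 2 * trialsPerTarget,
                           cleanEpochsPerLocation = 10,
                           maxStimuliPerTrial = 30,
                           interBlockPause = 5,
                           leadIn = 5,
                           epochWindow = c(-100, 600),
                           baselineWindow = c(-100, 0),
                           filterBand = c(0.1, 25),
                           filterOrder = 4,
                           eegRejectThreshold = 50,
                           eogRejectThreshold = 80,
                           downsampleFactor = 8,
                           alpha = 0.05,
                           subaverageSize = 10) {
  new("ProtocolConfig",
      samplingRate = samplingRate, isi = isi, stimPeriod = stimPeriod,
      blocksPerTask = blocksPerTask, nTrainingBlocks = nTrainingBlocks,
      stimuliPerLocationPerBlock = stimuliPerLocationPerBlock,
      trialsPerTarget = trialsPerTarget, nTestTrials = nTestTrials,
      cleanEpochsPerLocation = cleanEpochsPerLocation,
      maxStimuliPerTrial = maxStimuliPerTrial,
      interBlockPause = interBlockPause, leadIn = leadIn,
      epochWindow = epochWindow, baselineWindow = baselineWindow,
      filterBand = filterBand, filterOrder = filterOrder,
      eegRejectThreshold = eegRejectThreshold,
      eogRejectThreshold = eogRejectThreshold,
      downsampleFactor = downsampleFactor, alpha = alpha,
      subaverageSize = subaverageSize)
}

#' Derived sample-count arithmetic
#'
#' @param config a [ProtocolConfig-class].
#' @return `epochSamples()`: samples per epoch (840 at defaults);
#'   `baselineSamples()`: pre-stimulus samples (120); `postStimulusSamples()`:
#'   post-stimulus samples (720); `nFeatureSamples()`: post-stimulus samples
#'   after decimation (90); `isiSamples()`: onset-to-onset spacing in samples
#'   (840).
#' @export
epochSamples <- function(config) {
  as.integer(round(diff(config@epochWindow) / 1000 * config@samplingRate))
}

#' @rdname epochSamples
#' @export
baselineSamples <- function(config) {
  as.integer(round(diff(config@baselineWindow) / 1000 * config@samplingRate))
}

#' @rdname epochSamples
#' @export
postStimulusSamples <- function(config) {
  as.integer(round(config@epochWindow[2] / 1000 * config@samplingRate))
}

#' @rdname epochSamples
#' @export
nFeatureSamples <- function(config) {
  as.integer(postStimulusSamples(config) / config@downsampleFactor)
}

#' @rdname epochSamples
#' @export
isiSamples <- function(config) {
  as.integer(round(config@isi / 1000 * config@samplingRate))
}

#' Scheduled block duration in seconds
#'
#' Duration accounting uses the scheduled per-stimulus period (750 ms), so a
#' default 30-stimulus block occupies 22.5 s and a 20-stimulus online trial
#' 15 s.
#'
#' @param config a [ProtocolConfig-class].
#' @param nStimuli number of stimuli; defaults to a full training block.
#' @return seconds.
#' @export
blockDuration <- function(config,
                          nStimuli = 2 * config@stimuliPerLocationPerBlock) {
  nStimuli * config@stimPeriod / 1000
}

#' Total scheduled training-phase duration in seconds
#'
#' `nTrainingBlocks` blocks plus the `interBlockPause` gaps between them.
#'
#' @param config a [ProtocolConfig-class].
#' @export
trainingPhaseDuration <- function(config) {
  n <- config@nTrainingBlocks
  n * blockDuration(config) + (n - 1) * config@interBlockPause
}

# Start sample (0-based) of training block k (1-based).
.blockStartSample <- function(config, k) {
  fs <- config@samplingRate
  per <- blockDuration(config) + config@interBlockPause
  as.integer(round(config@leadIn * fs + (k - 1) * per * fs))
}

# Start sample (0-based) of test trial k (1-based). The test phase begins one
# pause after the end of the last training block; each trial reserves its full
# stimulus budget (30 x 750 ms at defaults) plus a pause.
.trialStartSample <- function(config, k) {
  fs <- config@samplingRate
  trainingEnd <- config@leadIn + trainingPhaseDuration(config)
  per <- blockDuration(config, config@maxStimuliPerTrial) +
    config@interBlockPause
  as.integer(round((trainingEnd + config@interBlockPause) * fs +
                     (k - 1) * per * fs))
}

.eventRow <- function(onset, location, attended, phase, unit, seqIndex) {
  data.frame(onset_sample = as.integer(onset), location = location,
             attended_location = attended, phase = phase,
             unit_id = as.integer(unit), seq_index = as.integer(seqIndex),
             stringsAsFactors = FALSE)
}

#' Schedule one training block
#'
#' Delivers `2 * stimuliPerLocationPerBlock` stimuli in a uniformly shuffled
#' balanced order over locations D and V, spaced `isi` apart, all carrying the
#' block's attended location.
#'
#' @param config a [ProtocolConfig-class].
#' @param attended attended location, `"D"` or `"V"`.
#' @param blockId block index (1-based).
#' @param startSample 0-based onset sample of the first stimulus.
#' @param seed optional integer seed for a reproducible shuffle.
#' @return a data.frame of stimulus events with columns `onset_sample`
#'   (0-based), `location`, `attended_location`, `phase`, `unit_id`,
#'   `seq_index`.
#' @examples
#' b <- scheduleBlock(protocolConfig(), "V", 1, 6000, seed = 1)
#' table(b$location)             # 15 D, 15 V
#' unique(diff(b$onset_sample))  # 840 samples = 700 ms
#' @export
scheduleBlock <- function(config, attended, blockId, startSample,
                          seed = NULL) {
  stopifnot(attended %in% c("D", "V"))
  .withSeed(seed, function() {
    n <- config@stimuliPerLocationPerBlock
    locs <- sample(rep(c("D", "V"), each = n))
    onsets <- startSample + (seq_len(2 * n) - 1L) * isiSamples(config)
    .eventRow(onsets, locs, attended, "training", blockId, seq_len(2 * n))
  })
}

# Locations for one online trial: a balanced randomized base of
# 2 * cleanEpochsPerLocation stimuli followed by extension slots that are
# assigned adaptively at generation/run time (placeholder: alternating D/V).
.scheduleTrialSlots <- function(config, target, trialId, startSample) {
  base <- sample(rep(c("D", "V"), each = config@cleanEpochsPerLocation))
  nExtra <- config@maxStimuliPerTrial - length(base)
  extra <- rep(c("D", "V"), length.out = nExtra)
  locs <- c(base, extra)
  onsets <- startSample + (seq_along(locs) - 1L) * isiSamples(config)
  .eventRow(onsets, locs, target, "test", trialId, seq_along(locs))
}

#' Schedule a full two-phase session
#'
#' Training blocks alternate the attended location starting from
#' `firstTarget`; test-phase targets are a seeded shuffle of the balanced
#' `trialsPerTarget + trialsPerTarget` multiset. Blocks and trials are
#' separated by `interBlockPause` seconds; the first stimulus follows a
#' `leadIn` period that absorbs the causal filter transient. Test trials are
#' scheduled with their full stimulus budget (`maxStimuliPerTrial` slots);
#' extension slots beyond the balanced base carry placeholder alternating
#' locations that [generateSession()] reassigns adaptively to the location
#' still lacking clean epochs.
#'
#' @param config a [ProtocolConfig-class].
#' @param firstTarget attended location of block 1 (`"D"` or `"V"`).
#' @param seed optional integer seed.
#' @return event data.frame (see [scheduleBlock()]) covering both phases,
#'   sorted by onset.
#' @export
scheduleSession <- function(config, firstTarget = "D", seed = NULL) {
  stopifnot(firstTarget %in% c("D", "V"))
  .withSeed(seed, function() {
    other <- setdiff(c("D", "V"), firstTarget)
    blockTargets <- rep(c(firstTarget, other),
                        length.out = config@nTrainingBlocks)
    training <- do.call(rbind, lapply(seq_len(config@nTrainingBlocks),
      function(k) {
        scheduleBlock(config, blockTargets[k], k, .blockStartSample(config, k))
      }))
    trialTargets <- sample(rep(c("D", "V"), each = config@trialsPerTarget))
    test <- do.call(rbind, lapply(seq_len(config@nTestTrials), function(k) {
      .scheduleTrialSlots(config, trialTargets[k],
                          k, .trialStartSample(config, k))
    }))
    rbind(training, test)
  })
}

#' Read and write stimulus event tables as TSV
#'
#' Tab-delimited with a header row and columns `onset_sample` (0-based
#' integer), `location`, `attended_location`, `phase`, `unit_id`,
#' `seq_index`. Tables round-trip bit-identically.
#'
#' @param events an event data.frame.
#' @param path file path.
#' @return `readEventTable()` returns the event data.frame.
#' @export
writeEventTable <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  read.delim(path, colClasses = c(
    onset_sample = "integer", location = "character",
    attended_location = "character", phase = "character",
    unit_id = "integer", seq_index = "integer"))
}
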