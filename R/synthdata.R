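# Synthetic-session generator: continuous EEG with stimulus-locked sERP
# templates whose late (post-150 ms) components are amplitude-enhanced under
# attention, AR(2) background noise, blinks on Fp1 and drift artifacts on the
# somatosensory channels. Every downstream stage is testable against the
# retained ground truth.

#' Construct an sERP template
#'
#' @param location `"D"` or `"V"`.
#' @param waveform numeric vector over the post-stimulus window (0..600 ms)
#'   at `samplingRate`; implicitly zero outside that window.
#' @param samplingRate samples per second.
#' @param channelGains named per-channel multipliers.
#' @param earlyWindow,lateWindow ms pairs; attention multiplies the late
#'   window only.
#' @param attentionGain multiplicative late-window factor (>= 1) applied when
#'   the stimulated location is attended.
#' @return a [SerpTemplate-class].
#' @export
serpTemplate <- function(location, waveform, samplingRate,
                         channelGains,
                         earlyWindow = c(0, 150),
                         lateWindow = c(150, 600),
                         attentionGain = 2) {
  new("SerpTemplate", location = location, waveform = waveform,
      samplingRate = samplingRate, channelGains = channelGains,
      earlyWindow = earlyWindow, lateWindow = lateWindow,
      attentionGain = attentionGain)
}

#' Default sERP templates for locations D and V
#'
#' Smooth biphasic waveforms (gamma-envelope sinusoids
#' `A (t/tau) exp(1 - t/tau) sin(2 pi f t)`) peaking between 100 and 250 ms,
#' with distinct frequency and envelope per location and per-channel gains
#' largest over the ipsilesional sites (Ci > CPi > Pi > Cz > Cc; zero on
#' Fp1). Amplitudes are a few microvolts, the magnitude typical of transient
#' somatosensory responses.
#'
#' @param config a [ProtocolConfig-class].
#' @param attentionGain late-window attention factor (>= 1) for both
#'   templates.
#' @param channelGains named per-channel multipliers; set `Cz`/`Cc` to zero
#'   to load only ipsilesional channels.
#' @return named list with elements `D` and `V`.
#' @examples
#' tpl <- defaultTemplates(protocolConfig())
#' sum(tpl$D@waveform^2) > 0
#' @export
defaultTemplates <- function(config, attentionGain = 2,
                             channelGains = c(Ci = 1, CPi = 0.9, Pi = 0.75,
                                              Cz = 0.5, Cc = 0.35, Fp1 = 0)) {
  fs <- config@samplingRate
  n <- postStimulusSamples(config)
  t <- (seq_len(n) - 1) / fs
  mk <- function(location, amp, freq, tau) {
    env <- (t / tau) * exp(1 - t / tau)
    serpTemplate(location, amp * env * sin(2 * pi * freq * t), fs,
                 channelGains, attentionGain = attentionGain)
  }
  list(D = mk("D", amp = 6.0, freq = 2.2, tau = 0.16),
       V = mk("V", amp = 5.5, freq = 2.6, tau = 0.14))
}

#' Construct a noise/artifact model
#'
#' @param backgroundSd stationary SD of the AR(2) background process, uV.
#' @param arCoefficients AR(2) coefficients giving the process its low-pass
#'   character.
#' @param blinkRate,blinkAmplitude,blinkDuration blink events per minute on
#'   Fp1, peak uV (> 80) and duration in seconds.
#' @param driftRate,driftAmplitude,driftDuration slow drift events per minute
#'   on a random somatosensory channel, peak uV (> 50) and duration in
#'   seconds.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(backgroundSd = 5,
                       arCoefficients = c(1.0, -0.3),
                       blinkRate = 1.2, blinkAmplitude = 300,
                       blinkDuration = 0.15,
                       driftRate = 0.8, driftAmplitude = 150,
                       driftDuration = 0.4) {
  new("NoiseModel", backgroundSd = backgroundSd,
      arCoefficients = arCoefficients,
      blinkRate = blinkRate, blinkAmplitude = blinkAmplitude,
      blinkDuration = blinkDuration,
      driftRate = driftRate, driftAmplitude = driftAmplitude,
      driftDuration = driftDuration)
}

# Stationary variance of an AR(2) process with unit innovation variance.
.ar2VarianceFactor <- function(a) {
  v <- (1 - a[2]) / ((1 + a[2]) * ((1 - a[2])^2 - a[1]^2))
  if (!is.finite(v) || v <= 0) {
    stop("arCoefficients do not define a stationary AR(2) process")
  }
  v
}

# Per-sample attention multiplier over the post-stimulus window: 1 in the
# early window, `gain` in the late window, joined by a 20 ms raised-cosine
# ramp starting at the late-window edge to avoid a step discontinuity.
.attentionScale <- function(template, nPost) {
  fs <- template@samplingRate
  g <- template@attentionGain
  scale <- rep(1, nPost)
  if (g == 1) return(scale)
  startIdx <- floor(template@lateWindow[1] / 1000 * fs) + 1
  rampLen <- max(1L, as.integer(round(0.020 * fs)))
  rampEnd <- min(nPost, startIdx + rampLen - 1L)
  if (startIdx <= nPost) {
    idx <- startIdx:rampEnd
    frac <- (idx - startIdx) / rampLen
    scale[idx] <- 1 + (g - 1) * (1 - cos(pi * frac)) / 2
    if (rampEnd < nPost) scale[(rampEnd + 1L):nPost] <- g
  }
  scale
}

# Hann bump of given length.
.hannBump <- function(n) sin(pi * (seq_len(n) - 1) / (n - 1))^2

# Draw artifact events (blinks on Fp1, drifts on a random EEG channel) over
# [0, nSamples). Returns a data.frame with the above-threshold "core"
# interval of each artifact, used for ground-truth epoch flagging.
.drawArtifacts <- function(noise, nSamples, fs, channels) {
  minutes <- nSamples / fs / 60
  rows <- list()
  addEvents <- function(type, rate, amp, dur, thr, chPool, signed) {
    count <- rpois(1, rate * minutes)
    for (i in seq_len(count)) {
      len <- max(3L, as.integer(round(dur * fs)))
      start <- as.integer(floor(runif(1, 0, max(1, nSamples - len))))
      ch <- if (length(chPool) == 1) chPool else sample(chPool, 1)
      sgn <- if (signed) sample(c(-1, 1), 1) else 1
      bump <- .hannBump(len)
      core <- which(amp * bump >= thr)
      rows[[length(rows) + 1L]] <<- data.frame(
        type = type, channel = ch, sign = sgn,
        start_sample = start, end_sample = start + len - 1L,
        core_start = start + min(core) - 1L,
        core_end = start + max(core) - 1L,
        amplitude = amp, stringsAsFactors = FALSE)
    }
  }
  eeg <- setdiff(channels, "Fp1")
  addEvents("blink", noise@blinkRate, noise@blinkAmplitude,
            noise@blinkDuration, 80, "Fp1", signed = FALSE)
  addEvents("drift", noise@driftRate, noise@driftAmplitude,
            noise@driftDuration, 50, eeg, signed = TRUE)
  if (!length(rows)) {
    return(data.frame(type = character(), channel = character(),
                      sign = numeric(), start_sample = integer(),
                      end_sample = integer(), core_start = integer(),
                      core_end = integer(), amplitude = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Event indices whose epoch window overlaps an artifact. With `core = TRUE`
# only the above-threshold core interval counts (epochs guaranteed
# rejectable); with `core = FALSE` the full artifact extent plus `pad`
# samples counts -- the conservative flag the delivery simulation uses,
# since filter ringing can push epochs near an artifact fringe over
# threshold.
.flagCorrupted <- function(events, artifacts, config, core = TRUE,
                           pad = 0L) {
  if (!nrow(artifacts) || !nrow(events)) return(integer())
  winStart <- events$onset_sample - baselineSamples(config)
  winEnd <- events$onset_sample + postStimulusSamples(config) - 1L
  aStart <- (if (core) artifacts$core_start else artifacts$start_sample) - pad
  aEnd <- (if (core) artifacts$core_end else artifacts$end_sample) + pad
  hit <- vapply(seq_len(nrow(events)), function(i) {
    any(aStart <= winEnd[i] & aEnd >= winStart[i])
  }, logical(1))
  which(hit)
}

# Re-run the online delivery policy at generation time: process each test
# trial's slots in order, assign extension slots to the location still
# lacking clean epochs (ground-truth artifact flags stand in for online
# rejection), and truncate the trial at quota completion or budget
# exhaustion. Training events pass through unchanged.
.adaptTestPhase <- function(events, artifacts, config) {
  isTest <- events$phase == "test"
  if (!any(isTest)) return(events)
  out <- list(events[!isTest, , drop = FALSE])
  nBase <- 2L * config@cleanEpochsPerLocation
  for (trial in unique(events$unit_id[isTest])) {
    slots <- events[isTest & events$unit_id == trial, , drop = FALSE]
    slots <- slots[order(slots$onset_sample), , drop = FALSE]
    pad <- as.integer(round(0.3 * config@samplingRate))
    corrupt <- seq_len(nrow(slots)) %in%
      .flagCorrupted(slots, artifacts, config, core = FALSE, pad = pad)
    need <- c(D = config@cleanEpochsPerLocation,
              V = config@cleanEpochsPerLocation)
    delivered <- 0L
    for (j in seq_len(nrow(slots))) {
      if (sum(need) == 0L) break
      loc <- if (j <= nBase) slots$location[j]
             else if (need[["D"]] >= need[["V"]] && need[["D"]] > 0L) "D"
             else "V"
      slots$location[j] <- loc
      delivered <- j
      if (!corrupt[j] && need[[loc]] > 0L) need[[loc]] <- need[[loc]] - 1L
    }
    out[[length(out) + 1L]] <- slots[seq_len(delivered), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  res <- res[order(res$onset_sample), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Generate a synthetic continuous session
#'
#' Schedules a session ([scheduleSession()]), synthesizes AR(2) background
#' noise, injects blink and drift artifacts, adds each stimulus event's
#' location template at its onset -- scaled by the template's
#' `attentionGain` over the late window if and only if the stimulated
#' location is attended -- and retains ground truth (artifact table,
#' artifact-corrupted epoch indices). Test-trial extension stimuli are
#' assigned to the location still lacking clean epochs, using the generator's
#' own artifact flags, so the delivered stream matches the online
#' collection policy it will feed.
#'
#' @param config a [ProtocolConfig-class].
#' @param templates named list of `D` and `V` [SerpTemplate-class]s.
#' @param noise a [NoiseModel-class].
#' @param montage `"right_impaired"` or `"left_impaired"` (metadata only;
#'   the signal uses generalized channel labels).
#' @param firstTarget attended location of the first block; `NULL` randomizes.
#' @param phase `"both"`, `"training"` or `"test"`; single-phase sessions are
#'   rebased so the recording starts with the lead-in.
#' @param seed optional integer seed; generation is bit-reproducible.
#' @return a [SyntheticSession-class].
#' @examples
#' cfg <- protocolConfig(blocksPerTask = 2, stimuliPerLocationPerBlock = 5,
#'                       trialsPerTarget = 2, cleanEpochsPerLocation = 3,
#'                       maxStimuliPerTrial = 8, subaverageSize = 2)
#' s <- generateSession(cfg, seed = 1)
#' dim(signalMatrix(s))
#' @export
generateSession <- function(config = protocolConfig(),
                            templates = defaultTemplates(config),
                            noise = noiseModel(),
                            montage = c("right_impaired", "left_impaired"),
                            firstTarget = NULL,
                            phase = c("both", "training", "test"),
                            seed = NULL) {
  montage <- match.arg(montage)
  phase <- match.arg(phase)
  for (tpl in templates) {
    if (tpl@samplingRate != config@samplingRate) {
      stop("template sampling rate does not match the configuration")
    }
  }
  .withSeed(seed, function() {
    fs <- config@samplingRate
    if (is.null(firstTarget)) firstTarget <- sample(c("D", "V"), 1)
    events <- scheduleSession(config, firstTarget)
    if (phase != "both") {
      events <- events[events$phase == phase, , drop = FALSE]
      offset <- min(events$onset_sample) -
        as.integer(round(config@leadIn * fs))
      events$onset_sample <- events$onset_sample - offset
      rownames(events) <- NULL
    }
    channels <- names(templates$D@channelGains)
    nSamples <- max(events$onset_sample) + postStimulusSamples(config) +
      as.integer(fs)

    artifacts <- .drawArtifacts(noise, nSamples, fs, channels)
    events <- .adaptTestPhase(events, artifacts, config)

    sig <- matrix(0, nrow = length(channels), ncol = nSamples,
                  dimnames = list(channels, NULL))
    if (noise@backgroundSd > 0) {
      innovSd <- noise@backgroundSd /
        sqrt(.ar2VarianceFactor(noise@arCoefficients))
      innov <- matrix(rnorm(length(channels) * nSamples, sd = innovSd),
                      nrow = length(channels))
      sig[, ] <- .iirFilterMatrix(innov, 1, c(1, -noise@arCoefficients))
    }
    for (i in seq_len(nrow(artifacts))) {
      a <- artifacts[i, ]
      len <- a$end_sample - a$start_sample + 1L
      cols <- (a$start_sample + 1L):(a$end_sample + 1L)
      sig[a$channel, cols] <- sig[a$channel, cols] +
        a$sign * a$amplitude * .hannBump(len)
    }

    nPost <- postStimulusSamples(config)
    contrib <- list()
    for (loc in c("D", "V")) {
      tpl <- templates[[loc]]
      gains <- tpl@channelGains[channels]
      contrib[[paste0(loc, ".att")]] <-
        outer(gains, tpl@waveform * .attentionScale(tpl, nPost))
      contrib[[paste0(loc, ".una")]] <- outer(gains, tpl@waveform)
    }
    for (i in seq_len(nrow(events))) {
      key <- paste0(events$location[i],
                    if (events$location[i] == events$attended_location[i])
                      ".att" else ".una")
      cols <- (events$onset_sample[i] + 1L):(events$onset_sample[i] + nPost)
      sig[, cols] <- sig[, cols] + contrib[[key]]
    }

    gt <- list(
      corrupted = .flagCorrupted(events, artifacts, config),
      artifacts = artifacts,
      attentionGain = c(D = templates$D@attentionGain,
                        V = templates$V@attentionGain),
      channelGains = templates$D@channelGains,
      templates = templates,
      firstTarget = firstTarget)
    new("SyntheticSession", signal = sig, samplingRate = fs,
        events = events, config = config, montage = montage,
        groundTruth = gt)
  })
}
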