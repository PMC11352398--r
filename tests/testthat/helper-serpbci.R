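# Shared test helpers: a scaled-down protocol for fast unit tests, canned
# noise models, constructed epoch sets, and a memoized mini session.

miniConfig <- function(...) {
  protocolConfig(blocksPerTask = 2, stimuliPerLocationPerBlock = 6,
                 trialsPerTarget = 2, cleanEpochsPerLocation = 3,
                 maxStimuliPerTrial = 10, subaverageSize = 2, ...)
}

noiselessModel <- function(backgroundSd = 0) {
  noiseModel(backgroundSd = backgroundSd, blinkRate = 0, driftRate = 0)
}

# An EpochSet built directly from metadata, with optional data array
# (defaults to all-zero epochs).
syntheticEpochSet <- function(config, stimulated, attended,
                              data = NULL, accepted = TRUE,
                              phase = "training", unit = 1L,
                              onsets = NULL) {
  n <- length(stimulated)
  channels <- bciChannels()
  len <- epochSamples(config)
  if (is.null(data)) {
    data <- array(0, dim = c(length(channels), len, n),
                  dimnames = list(channels, NULL, NULL))
  }
  if (is.null(onsets)) onsets <- seq_len(n) * isiSamples(config) + 6000L
  info <- data.frame(
    onset_sample = as.integer(onsets), location = stimulated,
    attended_location = rep_len(attended, n),
    phase = rep_len(phase, n), unit_id = as.integer(rep_len(unit, n)),
    seq_index = seq_len(n),
    condition = paste0("A", rep_len(attended, n), "S", stimulated),
    accepted = rep_len(accepted, n),
    reject_reason = NA_character_, stringsAsFactors = FALSE)
  new("EpochSet", data = data, info = info,
      samplingRate = config@samplingRate, config = config)
}

# Memoized mini end-to-end runs so several test files can share one.
.sessionCache <- new.env(parent = emptyenv())

miniRun <- function(gain = 2, seed = 1, backgroundSd = 2) {
  key <- paste(gain, seed, backgroundSd, sep = "_")
  if (is.null(.sessionCache[[key]])) {
    cfg <- miniConfig()
    .sessionCache[[key]] <- runSession(
      cfg, defaultTemplates(cfg, attentionGain = gain),
      noiseModel(backgroundSd = backgroundSd), seed = seed)
  }
  .sessionCache[[key]]
}

# Independent brute-force oracle for the signed-rank test: enumerate all 2^n
# sign assignments of the midranked absolute differences.
enumSignedRank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}

# Independent brute-force oracle for the rank-sum test: enumerate all
# assignments of pooled midranks to group x.
enumRankSum <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (length(r) + 1) / 2
  combos <- utils::combn(length(r), nx)
  Ws <- colSums(matrix(r[combos], nrow = nx))
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}
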