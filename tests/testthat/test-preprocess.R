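# Filtering, epoching, baseline correction, artifact rejection and cluster
# balancing.

test_that("band-pass meets its frequency-response oracles", {
  cfg <- protocolConfig()
  fs <- cfg@samplingRate
  t <- (0:(30 * fs - 1)) / fs
  rms <- function(v) sqrt(mean(v^2))
  settle <- (10 * fs):(30 * fs)   # skip the causal transient
  # 50 Hz stop-band: > 20 dB attenuation
  s50 <- sin(2 * pi * 50 * t)
  expect_lt(20 * log10(rms(bandpassFilter(s50, cfg)[settle]) / rms(s50)),
            -20)
  # 10 Hz pass-band: within 3 dB
  s10 <- sin(2 * pi * 10 * t)
  expect_gt(20 * log10(rms(bandpassFilter(s10, cfg)[settle]) / rms(s10)),
            -3)
  # DC is removed in steady state
  dc <- rep(100, 60 * fs)
  out <- bandpassFilter(dc, cfg)
  expect_lt(abs(mean(out[(50 * fs):(60 * fs)])), 1)
})

test_that("filtering rejects non-finite input and is deterministic", {
  cfg <- protocolConfig()
  expect_error(bandpassFilter(c(1, NA, 3), cfg), "non-finite")
  x <- matrix(rnorm(6 * 5000), 6, dimnames = list(bciChannels(), NULL))
  expect_identical(bandpassFilter(x, cfg), bandpassFilter(x, cfg))
})

test_that("epochs have the prescribed window and zero baseline mean", {
  cfg <- protocolConfig()
  x <- matrix(rnorm(6 * 30000), 6, dimnames = list(bciChannels(), NULL))
  ev <- data.frame(onset_sample = c(5000L, 10000L), location = c("D", "V"),
                   attended_location = "D", phase = "training",
                   unit_id = 1L, seq_index = 1:2)
  ep <- segmentEpochs(x, ev, cfg)
  expect_equal(dim(epochData(ep)), c(6, 840, 2))
  bl <- apply(epochData(ep)[, 1:120, , drop = FALSE], c(1, 3), mean)
  expect_true(all(abs(bl) < 1e-9))
  # a constant channel becomes all-zero after baseline correction
  x2 <- x
  x2["Pi", ] <- 7
  ep2 <- segmentEpochs(x2, ev, cfg)
  expect_true(all(ep2@data["Pi", , ] == 0))
  # window content matches the half-open [onset-120, onset+720) convention
  expect_equal(epochData(ep)["Ci", , 1],
               x["Ci", 4881:5720] - mean(x["Ci", 4881:5000]))
})

test_that("events too close to the recording edge are rejected", {
  cfg <- protocolConfig()
  x <- matrix(0, 6, 2000, dimnames = list(bciChannels(), NULL))
  ev <- data.frame(onset_sample = c(50L, 1000L), location = "D",
                   attended_location = "D", phase = "training",
                   unit_id = 1L, seq_index = 1:2)
  ep <- segmentEpochs(x, ev, cfg)
  expect_equal(epochInfo(ep)$accepted, c(FALSE, TRUE))
  expect_equal(epochInfo(ep)$reject_reason[1], "edge")
})

test_that("amplitude thresholds are applied per channel group", {
  cfg <- protocolConfig()
  mk <- function(ch, val) {
    ep <- syntheticEpochSet(cfg, "D", "D")
    d <- ep@data
    d[ch, 400, 1] <- val
    initialize(ep, data = d)
  }
  expect_false(epochInfo(rejectArtifacts(mk("Pi", 60)))$accepted)
  expect_equal(epochInfo(rejectArtifacts(mk("Pi", 60)))$reject_reason,
               "eeg_amplitude")
  expect_true(epochInfo(rejectArtifacts(mk("Fp1", 70)))$accepted)
  expect_false(epochInfo(rejectArtifacts(mk("Fp1", 90)))$accepted)
  expect_equal(epochInfo(rejectArtifacts(mk("Fp1", 90)))$reject_reason,
               "eog_amplitude")
  # exact threshold values are accepted (closed interval)
  expect_true(epochInfo(rejectArtifacts(mk("Pi", 50)))$accepted)
})

test_that("rejection matches a brute-force re-scan of every sample", {
  cfg <- protocolConfig()
  set.seed(31)
  n <- 40
  data <- array(rnorm(6 * 840 * n, sd = 13), dim = c(6, 840, n),
                dimnames = list(bciChannels(), NULL, NULL))
  ep <- syntheticEpochSet(cfg, rep(c("D", "V"), n / 2), "D", data = data)
  flags <- epochInfo(rejectArtifacts(ep))$accepted
  brute <- vapply(seq_len(n), function(i) {
    ok <- TRUE
    for (ch in bciChannels()) {
      thr <- if (ch == "Fp1") 80 else 50
      for (s in seq_len(840)) {
        if (abs(data[ch, s, i]) > thr) ok <- FALSE
      }
    }
    ok
  }, logical(1))
  expect_identical(flags, brute)
  expect_true(any(!flags))   # the draw actually exercises both outcomes
  expect_true(any(flags))
})

test_that("raising thresholds never rejects more epochs", {
  set.seed(32)
  n <- 60
  data <- array(rnorm(6 * 840 * n, sd = 30), dim = c(6, 840, n),
                dimnames = list(bciChannels(), NULL, NULL))
  accepted <- lapply(c(40, 50, 70, 100), function(thr) {
    cfg <- protocolConfig(eegRejectThreshold = thr,
                          eogRejectThreshold = thr + 30)
    which(epochInfo(rejectArtifacts(
      syntheticEpochSet(cfg, rep("D", n), "D", data = data)))$accepted)
  })
  for (k in seq_len(length(accepted) - 1)) {
    expect_true(all(accepted[[k]] %in% accepted[[k + 1]]))
  }
})

test_that("cluster balancing trims the chronologically last epochs", {
  cfg <- protocolConfig()
  sizes <- c(ADSD = 9, ADSV = 7, AVSD = 8, AVSV = 6)
  stim <- c(rep("D", 9), rep("V", 7), rep("D", 8), rep("V", 6))
  att <- c(rep("D", 16), rep("V", 14))
  ep <- syntheticEpochSet(cfg, stim, "D")
  ep@info$attended_location <- att
  ep@info$condition <- paste0("A", att, "S", stim)
  bal <- clusterAndBalance(ep)
  tab <- table(epochInfo(bal)$condition)
  expect_true(all(tab == 6))
  expect_equal(attr(bal, "clusterSizes"),
               c(ADSD = 9, ADSV = 7, AVSD = 8, AVSV = 6))
  # retained ADSD epochs are the 6 earliest of the 9
  adsdOnsets <- epochInfo(bal)$onset_sample[epochInfo(bal)$condition ==
                                              "ADSD"]
  allAdsd <- ep@info$onset_sample[ep@info$condition == "ADSD"]
  expect_equal(sort(adsdOnsets), sort(allAdsd)[1:6])
})

test_that("balanced input passes through unchanged and empties error", {
  cfg <- protocolConfig()
  stim <- rep(c("D", "V", "D", "V"), each = 5)
  att <- rep(c("D", "D", "V", "V"), each = 5)
  ep <- syntheticEpochSet(cfg, stim, "D")
  ep@info$attended_location <- att
  ep@info$condition <- paste0("A", att, "S", stim)
  bal <- clusterAndBalance(ep)
  expect_equal(nEpochs(bal), 20)
  # drop one whole condition
  ep2 <- serpBCI:::.subsetEpochs(ep, which(ep@info$condition != "AVSV"))
  expect_error(clusterAndBalance(ep2), "insufficient data")
})

test_that("a noiseless default-protocol session yields 225 per cluster", {
  cfg <- protocolConfig()
  s <- generateSession(cfg, defaultTemplates(cfg), noiselessModel(),
                       phase = "training", seed = 2)
  ep <- rejectArtifacts(segmentEpochs(s))
  bal <- clusterAndBalance(ep)
  expect_equal(unname(attr(bal, "clusterSizes")), rep(225, 4),
               ignore_attr = TRUE)
})
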