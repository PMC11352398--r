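# Synthetic generator: template construction, attention modulation,
# artifact injection with ground truth, reproducibility, EDF round trip.

test_that("default templates are biphasic, lateralized and causal", {
  cfg <- protocolConfig()
  tpl <- defaultTemplates(cfg)
  for (loc in c("D", "V")) {
    w <- tpl[[loc]]@waveform
    expect_length(w, postStimulusSamples(cfg))
    expect_true(all(is.finite(w)))
    peak <- which.max(abs(w)) / cfg@samplingRate * 1000
    expect_gt(peak, 0)
    expect_lt(peak, 600)
    g <- tpl[[loc]]@channelGains
    expect_gt(sum((w * g[["Ci"]])^2), sum((w * g[["Cc"]])^2))
    expect_equal(g[["Fp1"]], 0)
  }
  expect_false(isTRUE(all.equal(tpl$D@waveform, tpl$V@waveform)))
})

test_that("with gain 1 and no noise, attention leaves epochs identical", {
  cfg <- miniConfig()
  s <- generateSession(cfg, defaultTemplates(cfg, attentionGain = 1),
                       noiselessModel(), phase = "training", seed = 3)
  ep <- segmentEpochs(signalMatrix(s), eventTable(s), cfg)  # raw signal
  info <- epochInfo(ep)
  adsd <- which(info$condition == "ADSD")[1]
  avsd <- which(info$condition == "AVSD")[1]
  expect_equal(epochData(ep)[, , adsd], epochData(ep)[, , avsd])
  adsv <- which(info$condition == "ADSV")[1]
  avsv <- which(info$condition == "AVSV")[1]
  expect_equal(epochData(ep)[, , adsv], epochData(ep)[, , avsv])
})

test_that("attention gain scales only the late window, with a short taper", {
  cfg <- miniConfig()
  tpl <- defaultTemplates(cfg, attentionGain = 2)
  s <- generateSession(cfg, tpl, noiselessModel(), phase = "training",
                       seed = 3)
  ep <- segmentEpochs(signalMatrix(s), eventTable(s), cfg)
  info <- epochInfo(ep)
  att <- epochData(ep)[, , which(info$condition == "ADSD")[1]]
  una <- epochData(ep)[, , which(info$condition == "AVSD")[1]]
  pre <- baselineSamples(cfg)
  diffw <- (att - una)["Ci", ]
  postIdx <- seq_len(postStimulusSamples(cfg))     # post-stimulus samples
  t_ms <- (postIdx - 1) / cfg@samplingRate * 1000
  diffPost <- diffw[pre + postIdx]
  # no effect before the 150 ms late-window edge
  expect_true(all(abs(diffPost[t_ms < 150]) < 1e-9))
  # past the 20 ms taper the difference equals (gain - 1) x template
  w <- tpl$D@waveform * tpl$D@channelGains[["Ci"]]
  full <- t_ms >= 171
  expect_gt(max(abs(diffPost[full])), 0.5)
  expect_equal(diffPost[full], (2 - 1) * w[full], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("injected blinks exceed the Fp1 threshold and are flagged", {
  cfg <- miniConfig()
  s <- generateSession(cfg, defaultTemplates(cfg),
                       noiseModel(backgroundSd = 1, blinkRate = 20,
                                  driftRate = 0),
                       phase = "training", seed = 8)
  gt <- groundTruth(s)
  blinks <- gt$artifacts[gt$artifacts$type == "blink", ]
  expect_gt(nrow(blinks), 0)
  sig <- signalMatrix(s)
  for (i in seq_len(nrow(blinks))) {
    core <- (blinks$core_start[i]:blinks$core_end[i]) + 1
    expect_gt(max(abs(sig["Fp1", core])), 80)
  }
  # every epoch overlapping a blink core is flagged corrupted
  ev <- eventTable(s)
  winStart <- ev$onset_sample - baselineSamples(cfg)
  winEnd <- ev$onset_sample + postStimulusSamples(cfg) - 1
  overlaps <- vapply(seq_len(nrow(ev)), function(i) {
    any(blinks$core_start <= winEnd[i] & blinks$core_end >= winStart[i])
  }, logical(1))
  expect_true(all(which(overlaps) %in% gt$corrupted))
})

test_that("seeded generation is bit-reproducible", {
  cfg <- miniConfig()
  a <- generateSession(cfg, seed = 21)
  b <- generateSession(cfg, seed = 21)
  expect_identical(signalMatrix(a), signalMatrix(b))
  expect_identical(eventTable(a), eventTable(b))
  expect_identical(groundTruth(a)$corrupted, groundTruth(b)$corrupted)
})

test_that("template sampling-rate mismatch is an error", {
  cfg <- miniConfig()
  bad <- defaultTemplates(protocolConfig(samplingRate = 600,
                                         blocksPerTask = 2,
                                         stimuliPerLocationPerBlock = 6,
                                         trialsPerTarget = 2,
                                         cleanEpochsPerLocation = 3,
                                         maxStimuliPerTrial = 10))
  expect_error(generateSession(cfg, bad), "sampling rate")
})

test_that("signals round-trip through EDF within quantization error", {
  cfg <- miniConfig()
  s <- generateSession(cfg, phase = "training", seed = 4)
  path <- tempfile(fileext = ".edf")
  writeEdf(s, path)
  back <- readEdf(path)
  expect_identical(back$labels, rownames(signalMatrix(s)))
  expect_equal(back$samplingRate, cfg@samplingRate)
  orig <- signalMatrix(s)
  n <- ncol(orig)
  tol <- max(abs(orig)) / 32767 * 1.01
  expect_lt(max(abs(back$signal[, seq_len(n)] - orig)), tol)
})
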