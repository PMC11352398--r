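# Sub-averaging, decimation, rank-sum screening and feature-vector layout.

test_that("sub-averaging partitions chronologically and discards leftovers", {
  cfg <- protocolConfig(subaverageSize = 10)
  # 23 epochs per condition -> 2 sub-averages, 3 discarded
  stim <- rep(rep(c("D", "V"), each = 23), 2)
  att <- rep(c("D", "V"), each = 46)
  ep <- syntheticEpochSet(cfg, stim, "D")
  ep@info$attended_location <- att
  ep@info$condition <- paste0("A", att, "S", stim)
  sa <- makeSubaverages(ep, cfg)
  expect_equal(sa@nGroups, 2)
  expect_equal(dim(sa@data$ADSD), c(6, 90, 2))
  expect_equal(floor(218 / 10), 21)  # the full-protocol count
})

test_that("identical epochs average to any single epoch's decimation", {
  cfg <- protocolConfig(subaverageSize = 5)
  one <- matrix(rnorm(6 * 840), 6, dimnames = list(bciChannels(), NULL))
  data <- array(rep(one, 20), dim = c(6, 840, 20),
                dimnames = list(bciChannels(), NULL, NULL))
  stim <- rep(c("D", "V", "D", "V"), each = 5)
  att <- rep(c("D", "D", "V", "V"), each = 5)
  ep <- syntheticEpochSet(cfg, stim, "D", data = data)
  ep@info$attended_location <- att
  ep@info$condition <- paste0("A", att, "S", stim)
  sa <- makeSubaverages(ep, cfg)
  expect_equal(sa@data$ADSD[, , 1], one[, seq(121, 840, by = 8)],
               ignore_attr = TRUE)
})

test_that("decimation keeps every 8th post-stimulus sample from onset", {
  cfg <- protocolConfig(subaverageSize = 2)
  data <- array(0, dim = c(6, 840, 8),
                dimnames = list(bciChannels(), NULL, NULL))
  for (i in 1:8) data[, 121:840, i] <- matrix(rep(0:719, each = 6), 6)
  stim <- rep(c("D", "V", "D", "V"), each = 2)
  att <- rep(c("D", "D", "V", "V"), each = 2)
  ep <- syntheticEpochSet(cfg, stim, "D", data = data)
  ep@info$attended_location <- att
  ep@info$condition <- paste0("A", att, "S", stim)
  sa <- makeSubaverages(ep, cfg)
  expect_equal(sa@data$ADSD["Ci", , 1], seq(0, 712, by = 8))
  expect_equal(sa@times, seq(0, 712, by = 8) / 1200 * 1000)
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rankSumTest(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(rankSumTest(c(1, 2), c(1, 2)), 1)
  # independent oracle: brute-force enumeration, including ties
  set.seed(7)
  for (rep in 1:25) {
    x <- sample(1:6, sample(2:6, 1), replace = TRUE)
    y <- sample(1:6, sample(2:6, 1), replace = TRUE)
    expect_equal(rankSumTest(x, y), enumRankSum(x, y), tolerance = 1e-12)
  }
  # tie-free exact path agrees with wilcox.test's exact p-value
  for (rep in 1:25) {
    x <- rnorm(sample(3:8, 1))
    y <- rnorm(sample(3:8, 1))
    expect_equal(rankSumTest(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large-sample path matches wilcox.test's corrected normal", {
  set.seed(8)
  for (rep in 1:20) {
    x <- round(rnorm(15, sd = 2), 1)   # rounding induces ties
    y <- round(rnorm(12, sd = 2), 1)
    expect_equal(rankSumTest(x, y),
                 suppressWarnings(
                   stats::wilcox.test(x, y, exact = FALSE,
                                      correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("rank-sum type-I error is near nominal under the null", {
  set.seed(9)
  p <- vapply(1:10000, function(i) rankSumTest(rnorm(10), rnorm(10)),
              numeric(1))
  expect_gt(mean(p < 0.05), 0.04)
  expect_lt(mean(p < 0.05), 0.06)
})

test_that("screening finds only late-window indices in a noiseless session", {
  cfg <- miniConfig()
  s <- generateSession(cfg, defaultTemplates(cfg, attentionGain = 2),
                       noiselessModel(), phase = "training", seed = 5)
  ep <- rejectArtifacts(segmentEpochs(s))
  sa <- makeSubaverages(clusterAndBalance(ep), cfg)
  for (ch in c("Ci", "CPi", "Pi")) {
    idx <- screenIndices(sa, ch, cfg)
    expect_false(idx@fallbackD || idx@fallbackV)
    times <- sa@times
    expect_true(all(times[idx@iD] >= 150))
    expect_true(all(times[idx@iV] >= 150))
    expect_gt(length(idx@iD), 0)
  }
})

test_that("alpha = 0 triggers the single-index fallback", {
  cfg <- miniConfig(alpha = 0)
  s <- generateSession(cfg, defaultTemplates(cfg, attentionGain = 2),
                       noiselessModel(), phase = "training", seed = 5)
  ep <- rejectArtifacts(segmentEpochs(s))
  sa <- makeSubaverages(clusterAndBalance(ep), cfg)
  idx <- screenIndices(sa, "Ci", cfg)
  expect_true(idx@fallbackD && idx@fallbackV)
  expect_length(idx@iD, 1)
  expect_length(idx@iV, 1)
})

test_that("feature vectors follow the [SD(iD), SV(iV)] layout", {
  cfg <- miniConfig()
  s <- generateSession(cfg, defaultTemplates(cfg, attentionGain = 2),
                       noiseModel(backgroundSd = 2), phase = "training",
                       seed = 6)
  ep <- rejectArtifacts(segmentEpochs(s))
  sa <- makeSubaverages(clusterAndBalance(ep), cfg)
  idx <- screenIndices(sa, "Ci", cfg)
  fv <- buildFeatureVectors(sa, idx)
  k <- sa@nGroups
  expect_equal(dim(fv$x), c(2 * k, length(idx@iD) + length(idx@iV)))
  expect_equal(as.vector(table(fv$y)), c(k, k))
  # row k is AD group k: ADSD at iD then ADSV at iV
  g <- 2
  expect_equal(fv$x[g, ], c(sa@data$ADSD["Ci", idx@iD, g],
                            sa@data$ADSV["Ci", idx@iV, g]),
               ignore_attr = TRUE)
  expect_equal(fv$x[k + g, ], c(sa@data$AVSD["Ci", idx@iD, g],
                                sa@data$AVSV["Ci", idx@iV, g]),
               ignore_attr = TRUE)
  # an empty iD is allowed: vectors then hold only stimulated-V amplitudes
  idx2 <- new("FeatureIndexSet", channel = "Ci", iD = integer(),
              iV = idx@iV, pD = idx@pD, pV = idx@pV,
              fallbackD = TRUE, fallbackV = FALSE)
  fv2 <- buildFeatureVectors(sa, idx2)
  expect_equal(ncol(fv2$x), length(idx@iV))
  expect_equal(fv2$x[g, ], sa@data$ADSV["Ci", idx@iV, g],
               ignore_attr = TRUE)
})
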