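# Online trial loop accounting, accuracy and ITR closed forms.

# A TrainedBci over the default protocol whose channels all use the first
# decimated index of each location, trained on a trivially separable toy
# problem (positive pair -> AD, negative pair -> AV).
stubTrainedBci <- function(config = protocolConfig()) {
  models <- lapply(bciEegChannels(), function(ch) {
    idx <- new("FeatureIndexSet", channel = ch, iD = 1L, iV = 1L,
               pD = 0.01, pV = 0.01, fallbackD = FALSE, fallbackV = FALSE)
    x <- rbind(c(1, 1), c(1.1, 0.9), c(-1, -1), c(-0.9, -1.1))
    trainChannel(list(x = x, y = factor(c("AD", "AD", "AV", "AV")),
                      channel = ch), indexSet = idx)
  })
  names(models) <- bciEegChannels()
  selectFeedbackChannel(models, config)
}

# Trial epoch stream with given locations/accepted flags; all-positive or
# all-negative constant epochs so the stub classifier predicts AD / AV.
trialStream <- function(config, locations, accepted, value = 1,
                        target = "D") {
  n <- length(locations)
  data <- array(value, dim = c(6, epochSamples(config), n),
                dimnames = list(bciChannels(), NULL, NULL))
  ep <- syntheticEpochSet(config, locations, target, data = data,
                          phase = "test", unit = 1L)
  ep@info$accepted <- accepted
  ep
}

test_that("an artifact-free trial completes after exactly 20 stimuli", {
  cfg <- protocolConfig()
  trained <- stubTrainedBci(cfg)
  locs <- rep(c("D", "V"), 10)
  out <- runTrial(trialStream(cfg, locs, rep(TRUE, 20)), trained, cfg)
  expect_equal(out$status, "complete")
  expect_equal(out$stimuli_delivered, 20)
  expect_equal(out$epochs_rejected, 0)
  expect_equal(out$feedback_prediction, "AD")  # positive constant epochs
  expect_length(out$predictions, 5)
})

test_that("three rejected epochs cost exactly three extra stimuli", {
  cfg <- protocolConfig()
  trained <- stubTrainedBci(cfg)
  base <- rep(c("D", "V"), 10)
  accepted <- rep(TRUE, 23)
  accepted[c(3, 7, 12)] <- FALSE          # 2 D and 1 V rejected
  extension <- c("D", "D", "V")           # deficit-matched delivery
  out <- runTrial(trialStream(cfg, c(base, extension), accepted),
                  trained, cfg)
  expect_equal(out$status, "complete")
  expect_equal(out$stimuli_delivered, 23)
  expect_equal(out$epochs_rejected, 3)
})

test_that("an exhausted stimulus budget aborts the trial", {
  cfg <- protocolConfig()
  trained <- stubTrainedBci(cfg)
  locs <- rep(c("D", "V"), 15)
  accepted <- rep(TRUE, 30)
  accepted[seq(1, 29, by = 2)] <- FALSE   # every D epoch rejected
  out <- runTrial(trialStream(cfg, locs, accepted), trained, cfg)
  expect_equal(out$status, "budget_exhausted")
  expect_equal(out$stimuli_delivered, 30)
  expect_null(out$predictions)
})

test_that("the online feature vector is the stored-index average", {
  cfg <- protocolConfig()
  trained <- stubTrainedBci(cfg)
  set.seed(41)
  n <- 20
  data <- array(rnorm(6 * 840 * n), dim = c(6, 840, n),
                dimnames = list(bciChannels(), NULL, NULL))
  locs <- rep(c("D", "V"), 10)
  ep <- syntheticEpochSet(cfg, locs, "V", data = data, phase = "test")
  out <- runTrial(ep, trained, cfg)
  dec <- function(idx) {
    rowMeans(data[, , idx, drop = FALSE], dims = 2)[, seq(121, 840, by = 8)]
  }
  avgD <- dec(which(locs == "D"))
  avgV <- dec(which(locs == "V"))
  for (ch in bciEegChannels()) {
    m <- trained@channels[[ch]]
    vec <- c(avgD[match(ch, bciChannels()), m@indexSet@iD],
             avgV[match(ch, bciChannels()), m@indexSet@iV])
    expect_identical(out$predictions[[ch]], predictChannel(m, vec))
  }
})

test_that("accuracy follows the TP/FP tally formula", {
  expect_equal(computeAccuracy(c(TP_AD = 10, TP_AV = 10,
                                 FP_AD = 0, FP_AV = 0)), 100)
  expect_equal(computeAccuracy(c(TP_AD = 10, TP_AV = 7,
                                 FP_AD = 0, FP_AV = 3)), 85)
  expect_equal(computeAccuracy(c(TP_AD = 5, TP_AV = 5,
                                 FP_AD = 5, FP_AV = 5)), 50)
  expect_error(computeAccuracy(c(TP_AD = 0, TP_AV = 0,
                                 FP_AD = 0, FP_AV = 0)), "undefined")
})

test_that("the Wolpaw ITR matches its closed form", {
  expect_equal(computeItr(2, 14, 1), 60 / 14, tolerance = 1e-12)
  expect_equal(round(computeItr(2, 14, 1), 2), 4.29)
  expect_equal(computeItr(2, 14, 0.5), 0, tolerance = 1e-12)
  p <- 0.85
  expect_equal(computeItr(2, 14, p),
               60 / 14 * (1 + p * log2(p) + (1 - p) * log2(1 - p)),
               tolerance = 1e-12)
  # four targets, generic closed form
  p <- 0.7
  expect_equal(computeItr(4, 10, p),
               6 * (2 + p * log2(p) + (1 - p) * log2((1 - p) / 3)),
               tolerance = 1e-12)
})

test_that("a full mini test phase logs every trial with 5% grid accuracy", {
  r <- miniRun()
  lg <- trialLog(r$result)
  cfg <- miniConfig()
  expect_equal(nrow(lg), cfg@nTestTrials)
  step <- 100 / sum(lg$status == "complete")
  for (acc in channelAccuracies(r$result)) {
    expect_lt(min(abs(acc - step * 0:100)), 1e-9)
  }
  expect_true(all(lg$stimuli_delivered >=
                    2 * cfg@cleanEpochsPerLocation |
                    lg$status != "complete"))
})
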