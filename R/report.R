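# Report module: cohort accuracy summaries (medians and quartiles, subset
# comparison by signed-rank test) and grand-average waveforms with
# divergence-onset estimation.
#
# Quartile convention: quantile type 2 (inverse empirical CDF with averaging
# at discontinuities). This is the convention under which the published
# ten-patient cohort summary cells are reproduced exactly, and it is fixed
# package-wide.

#' Read a cohort accuracy table
#'
#' CSV with one row per patient/session and columns `patient_id`,
#' `impaired_side`, `amplitude_D`, `amplitude_V`, and per-channel online
#' accuracies `Ci`, `CPi`, `Pi`, `Cz`, `Cc` in percent. The package ships
#' the ten-patient clinical feasibility cohort as
#' `inst/extdata/cohort_online_accuracy.csv`.
#'
#' @param path CSV path; defaults to the shipped cohort table.
#' @return data.frame.
#' @export
readCohortTable <- function(path = system.file("extdata",
                                               "cohort_online_accuracy.csv",
                                               package = "serpBCI")) {
  read.csv(path, stringsAsFactors = FALSE)
}

# Row-wise maxima over all channels and the two channel subsets.
.augmentCohort <- function(table) {
  chans <- bciEegChannels()
  stopifnot(all(chans %in% names(table)))
  table$max_all <- do.call(pmax, table[chans])
  table$max_subset1 <- do.call(pmax, table[c("Ci", "CPi", "Pi")])
  table$max_subset2 <- do.call(pmax, table[c("Cz", "Cc")])
  table
}

#' Summarize a cohort accuracy table
#'
#' Recomputes the row-wise maxima over all channels and over the two
#' channel subsets (subset 1: Ci, CPi, Pi; subset 2: Cz, Cc), then reports
#' the median and (Q1, Q3) of every accuracy column using the fixed
#' type-2 quartile convention.
#'
#' @param table data.frame as returned by [readCohortTable()].
#' @return list with `summary` (data.frame: column, median, q1, q3) and
#'   `table` (the input augmented with the three maxima columns).
#' @examples
#' s <- summarizeCohort(readCohortTable())
#' subset(s$summary, column == "max_all")  # median 85 (75-90)
#' @export
summarizeCohort <- function(table) {
  if (!nrow(table)) stop("empty cohort table")
  table <- .augmentCohort(table)
  cols <- c(bciEegChannels(), "max_all", "max_subset1", "max_subset2")
  qs <- t(vapply(cols, function(cc) {
    quantile(table[[cc]], c(0.5, 0.25, 0.75), type = 2, names = FALSE)
  }, numeric(3)))
  summary <- data.frame(column = cols, median = qs[, 1], q1 = qs[, 2],
                        q3 = qs[, 3], row.names = NULL,
                        stringsAsFactors = FALSE)
  list(summary = summary, table = table)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; absolute differences are midranked. For up
#' to 25 non-zero pairs the null distribution of the positive-rank sum is
#' computed exactly (by convolution over the possible sign assignments,
#' which remains exact under ties); beyond that a normal approximation with
#' tie correction and 0.5 continuity correction is used.
#'
#' @param x numeric differences, or the first paired sample when `y` given.
#' @param y optional second paired sample.
#' @return list with `statistic` (positive-rank sum W+), `p.value` and `n`
#'   (non-zero pairs).
#' @examples
#' signedRankTest(1:6)$p.value  # exact: 2/64
#' @export
signedRankTest <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p.value = 1, n = 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of 2*W+ over doubled midranks via convolution
    R2 <- as.integer(round(2 * r))
    probs <- c(1, rep(0, sum(R2)))
    for (ri in R2) {
      shifted <- c(rep(0, ri), probs[seq_len(length(probs) - ri)])
      probs <- (probs + shifted) / 2
    }
    support <- seq_along(probs) - 1L
    mu2 <- sum(R2) / 2
    w2 <- round(2 * W)
    p <- sum(probs[abs(support - mu2) >= abs(w2 - mu2) - 1e-9])
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
  }
  list(statistic = W, p.value = min(1, p), n = n)
}

#' Compare the two channel-subset maxima across a cohort
#'
#' Pairs each row's maximum accuracy over the ipsilesional subset
#' (Ci, CPi, Pi) with its maximum over the central/contralesional subset
#' (Cz, Cc) and applies the two-sided Wilcoxon signed-rank test.
#'
#' @param table cohort data.frame as for [summarizeCohort()].
#' @return list with `statistic`, `p.value`, `n` and the paired maxima.
#' @export
compareSubsets <- function(table) {
  if (nrow(table) < 6) stop("need at least 6 paired rows")
  table <- .augmentCohort(table)
  res <- signedRankTest(table$max_subset1, table$max_subset2)
  res$subset1 <- table$max_subset1
  res$subset2 <- table$max_subset2
  res
}

#' Grand-average sERP waveforms and attention divergence onset
#'
#' Averages all accepted epochs per condition and channel over the full
#' epoch window, then estimates, per stimulated location and channel, the
#' earliest post-stimulus time at which the attended and unattended
#' waveforms differ by more than a criterion for at least 5 consecutive
#' samples. The default criterion is 3 times the baseline-period standard
#' deviation of the difference waveform.
#'
#' @param epochs an [EpochSet-class] (accepted epochs are used).
#' @param criterion absolute uV threshold; `NULL` for the 3-SD default.
#' @param minRun consecutive supra-threshold samples required (default 5).
#' @return a [GrandAverage-class].
#' @export
grandAverage <- function(epochs, criterion = NULL, minRun = 5L) {
  config <- epochs@config
  info <- epochs@info
  keep <- which(info$accepted)
  conditions <- c("ADSD", "ADSV", "AVSD", "AVSV")
  waves <- list()
  counts <- numeric(length(conditions))
  names(counts) <- conditions
  for (cc in conditions) {
    idx <- keep[info$condition[keep] == cc]
    counts[cc] <- length(idx)
    if (length(idx)) {
      waves[[cc]] <- rowMeans(epochs@data[, , idx, drop = FALSE], dims = 2)
    }
  }
  fs <- config@samplingRate
  pre <- baselineSamples(config)
  times <- (seq_len(epochSamples(config)) - pre - 1) / fs * 1000
  pairs <- list(D = c("ADSD", "AVSD"), V = c("AVSV", "ADSV"))
  rows <- list()
  for (loc in names(pairs)) {
    att <- waves[[pairs[[loc]][1]]]
    una <- waves[[pairs[[loc]][2]]]
    if (is.null(att) || is.null(una)) next
    for (ch in rownames(att)) {
      diffw <- att[ch, ] - una[ch, ]
      crit <- if (is.null(criterion)) 3 * sd(diffw[seq_len(pre)])
              else criterion
      post <- (pre + 1L):length(diffw)
      above <- abs(diffw[post]) > crit
      onset <- NA_real_
      run <- rle(above)
      ends <- cumsum(run$lengths)
      hit <- which(run$values & run$lengths >= minRun)
      if (length(hit)) {
        start <- ends[hit[1]] - run$lengths[hit[1]] + 1L
        onset <- (start - 1) / fs * 1000
      }
      rows[[length(rows) + 1L]] <- data.frame(
        location = loc, channel = ch, criterion = crit, onset_ms = onset,
        stringsAsFactors = FALSE)
    }
  }
  new("GrandAverage", waveforms = waves, times = times,
      divergence = if (length(rows)) do.call(rbind, rows) else
        data.frame(location = character(), channel = character(),
                   criterion = numeric(), onset_ms = numeric()),
      nEpochs = counts)
}
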