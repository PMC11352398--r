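# Feature module: 10-epoch sub-averaging with x8 decimation, per-time-index
# Wilcoxon rank-sum screening of attended vs unattended sub-averages, and
# flattened two-location feature vectors.

#' Form per-condition sub-averages, cropped and decimated
#'
#' Each balanced condition cluster is partitioned chronologically into
#' consecutive, non-overlapping groups of `subaverageSize` epochs (leftovers
#' discarded); each group is averaged per channel, cropped to the 720
#' post-stimulus samples and decimated by keeping every
#' `downsampleFactor`-th sample starting at stimulus onset, yielding 90
#' values per channel at defaults.
#'
#' @param epochs a balanced [EpochSet-class] from [clusterAndBalance()].
#' @param config a [ProtocolConfig-class]; defaults to the set's own.
#' @return a [SubAverageSet-class].
#' @export
makeSubaverages <- function(epochs, config = epochs@config) {
  info <- epochs@info
  conditions <- c("ADSD", "ADSV", "AVSD", "AVSV")
  sizes <- table(factor(info$condition, levels = conditions))
  if (length(unique(as.integer(sizes))) != 1) {
    stop("clusters must be balanced before sub-averaging")
  }
  gSize <- as.integer(config@subaverageSize)
  nGroups <- as.integer(sizes[1]) %/% gSize
  if (nGroups < 1) {
    stop("cluster size ", sizes[1], " is smaller than one sub-average (",
         gSize, " epochs)")
  }
  nCh <- dim(epochs@data)[1]
  nKeep <- nFeatureSamples(config)
  out <- list()
  for (cc in conditions) {
    idx <- which(info$condition == cc)
    idx <- idx[order(info$onset_sample[idx])]
    arr <- array(0, dim = c(nCh, nKeep, nGroups),
                 dimnames = list(dimnames(epochs@data)[[1]], NULL, NULL))
    for (k in seq_len(nGroups)) {
      grp <- idx[((k - 1L) * gSize + 1L):(k * gSize)]
      avg <- rowMeans(epochs@data[, , grp, drop = FALSE], dims = 2)
      arr[, , k] <- .decimatePostStimulus(avg, config)
    }
    out[[cc]] <- arr
  }
  times <- (seq_len(nKeep) - 1) * config@downsampleFactor /
    config@samplingRate * 1000
  new("SubAverageSet", data = out, nGroups = nGroups, times = times,
      config = config)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Ties are midranked. When both group sizes are at most 8 the p-value is
#' computed by exact enumeration of all group assignments of the pooled
#' midranks (two-sided via symmetric deviations of the rank sum from its
#' mean); for larger groups a normal approximation with tie correction and
#' 0.5 continuity correction is used. Degenerate input (all pooled values
#' equal) returns p = 1.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return two-sided p-value.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
#' @export
rankSumTest <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  if (max(pooled) == min(pooled)) return(1)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  if (max(nx, ny) <= 8) {
    combos <- combn(nx + ny, nx)
    Ws <- colSums(matrix(r[combos], nrow = nx))
    return(mean(abs(Ws - mu) >= abs(W - mu) - 1e-9))
  }
  N <- nx + ny
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Screen time indices for attention-sensitive sERP amplitudes
#'
#' For each of the 90 downsampled post-stimulus indices, the sub-average
#' amplitudes of the attended and unattended condition for the same
#' stimulated location are compared with [rankSumTest()]: index set `iD`
#' collects indices with ADSD vs AVSD p < alpha, and `iV` indices with
#' AVSV vs ADSV p < alpha. No multiplicity correction is applied (the raw
#' p < 0.05 rule is part of the method). If a location yields no significant
#' index, the single minimum-p index is retained and flagged as a fallback
#' so the classifier still receives a non-empty vector.
#'
#' @param subaverages a [SubAverageSet-class].
#' @param channel channel label.
#' @param config a [ProtocolConfig-class]; defaults to the set's own.
#' @return a [FeatureIndexSet-class] for the channel.
#' @export
screenIndices <- function(subaverages, channel,
                          config = subaverages@config) {
  stopifnot(subaverages@nGroups >= 2)
  d <- subaverages@data
  nIdx <- dim(d[[1]])[2]
  pOf <- function(att, una) {
    vapply(seq_len(nIdx), function(t) {
      rankSumTest(d[[att]][channel, t, ], d[[una]][channel, t, ])
    }, numeric(1))
  }
  pD <- pOf("ADSD", "AVSD")
  pV <- pOf("AVSV", "ADSV")
  pick <- function(p) {
    i <- which(p < config@alpha)
    if (length(i)) list(idx = as.integer(i), fallback = FALSE)
    else list(idx = as.integer(which.min(p)), fallback = TRUE)
  }
  dSel <- pick(pD)
  vSel <- pick(pV)
  new("FeatureIndexSet", channel = channel,
      iD = dSel$idx, iV = vSel$idx, pD = pD, pV = pV,
      fallbackD = dSel$fallback, fallbackV = vSel$fallback)
}

#' Build flattened two-location feature vectors for one channel
#'
#' Sub-averages are paired by group index k: the class-AD vector is
#' `c(ADSD_k[iD], ADSV_k[iV])` and the class-AV vector
#' `c(AVSD_k[iD], AVSV_k[iV])` -- i.e. stimulated-D amplitudes at the
#' screened D indices followed by stimulated-V amplitudes at the screened V
#' indices, under a single attention task.
#'
#' @param subaverages a [SubAverageSet-class].
#' @param indexSet the channel's [FeatureIndexSet-class].
#' @param channel channel label; defaults to the index set's channel.
#' @return list with `x` (2k x (|iD|+|iV|) matrix), `y` (factor with levels
#'   AD/AV) and `channel`.
#' @export
buildFeatureVectors <- function(subaverages, indexSet,
                                channel = indexSet@channel) {
  d <- subaverages@data
  counts <- vapply(d, function(a) dim(a)[3], numeric(1))
  if (length(unique(counts)) != 1) {
    stop("sub-average counts differ across conditions")
  }
  k <- counts[[1]]
  iD <- indexSet@iD
  iV <- indexSet@iV
  rowOf <- function(sd, sv, g) {
    c(d[[sd]][channel, iD, g], d[[sv]][channel, iV, g])
  }
  p <- length(iD) + length(iV)
  xAD <- matrix(unlist(lapply(seq_len(k), function(g)
    rowOf("ADSD", "ADSV", g))), nrow = k, ncol = p, byrow = TRUE)
  xAV <- matrix(unlist(lapply(seq_len(k), function(g)
    rowOf("AVSD", "AVSV", g))), nrow = k, ncol = p, byrow = TRUE)
  list(x = rbind(xAD, xAV),
       y = factor(rep(c("AD", "AV"), each = k), levels = c("AD", "AV")),
       channel = channel)
}
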