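# Preprocessing: causal band-pass filtering, epoching with baseline
# correction, amplitude-threshold artifact rejection and condition-cluster
# balancing. The identical causal path is used for training and online data,
# so train and test feature distributions match.

# Cached filter design for a configuration. The band-pass is realized as a
# cascade of a 4th-order Butterworth high-pass (lower corner) and a 4th-order
# low-pass (upper corner): a direct band-pass design with a 0.1 Hz corner at
# fs = 1200 places all eight poles so close to the unit circle that the
# recursion diverges in double precision, while the cascade is stable and
# meets the band edges.
.designFilter <- function(config) {
  nyq <- config@samplingRate / 2
  list(hp = signal::butter(config@filterOrder, config@filterBand[1] / nyq,
                           type = "high"),
       lp = signal::butter(config@filterOrder, config@filterBand[2] / nyq,
                           type = "low"))
}

#' Causal Butterworth band-pass filter
#'
#' Applies a causal (forward-only) 4th-order Butterworth high-pass at the
#' lower corner followed by a 4th-order low-pass at the upper corner
#' (0.1 and 25 Hz at defaults), identically for training and online data.
#' Zero-phase filtering is deliberately not used: the online phase must be
#' causal, and using one filter mode everywhere keeps the train and test
#' distributions identical.
#'
#' @param x numeric vector or channels x samples matrix; must be finite.
#' @param config a [ProtocolConfig-class].
#' @return filtered signal of the same shape.
#' @export
bandpassFilter <- function(x, config) {
  .assertFinite(x, "input signal")
  flt <- .designFilter(config)
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  out <- .iirFilterMatrix(.iirFilterMatrix(x, flt$hp$b, flt$hp$a),
                          flt$lp$b, flt$lp$a)
  dimnames(out) <- dimnames(x)
  if (vec) as.numeric(out) else out
}

.conditionOf <- function(attended, stimulated) {
  paste0("A", attended, "S", stimulated)
}

#' Segment a continuous recording into baseline-corrected epochs
#'
#' One epoch per stimulus event over the half-open window
#' `[onset - 120, onset + 720)` samples at defaults (-100..600 ms). Each
#' epoch is baseline-corrected by subtracting the per-channel mean of the
#' 120 pre-stimulus samples. Events too close to the recording edge are
#' flagged rejected with reason `"edge"`.
#'
#' @param x filtered channels x samples matrix with channel rownames, or a
#'   [SyntheticSession-class] (whose raw signal is then filtered first).
#' @param events event data.frame; taken from the session when `x` is one.
#' @param config a [ProtocolConfig-class]; ditto.
#' @return an [EpochSet-class].
#' @export
segmentEpochs <- function(x, events = NULL, config = NULL) {
  if (is(x, "SyntheticSession")) {
    if (is.null(events)) events <- x@events
    if (is.null(config)) config <- x@config
    x <- bandpassFilter(x@signal, config)
  }
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  nCh <- nrow(x)
  pre <- baselineSamples(config)
  len <- epochSamples(config)
  nEv <- nrow(events)
  first <- events$onset_sample - pre            # 0-based window start
  lastExcl <- events$onset_sample + postStimulusSamples(config)
  edge <- first < 0L | lastExcl > ncol(x)
  arr <- array(0, dim = c(nCh, len, nEv),
               dimnames = list(rownames(x), NULL, NULL))
  ok <- which(!edge)
  if (length(ok)) {
    cols <- as.vector(t(outer(first[ok] + 1L, 0:(len - 1L), "+")))
    sub <- array(x[, cols], dim = c(nCh, len, length(ok)))
    bl <- colMeans(aperm(sub[, seq_len(pre), , drop = FALSE], c(2, 1, 3)),
                   dims = 1)                       # nCh x nOk channel means
    sub <- sub - array(bl[, rep(seq_len(length(ok)), each = len)],
                       dim = dim(sub))
    arr[, , ok] <- sub
  }
  info <- events
  info$condition <- .conditionOf(events$attended_location, events$location)
  info$accepted <- !edge
  info$reject_reason <- ifelse(edge, "edge", NA_character_)
  rownames(info) <- NULL
  new("EpochSet", data = arr, info = info,
      samplingRate = config@samplingRate, config = config)
}

#' Amplitude-threshold artifact rejection
#'
#' An epoch is accepted if and only if every baseline-corrected sample on
#' all five somatosensory channels lies within +/-`eegRejectThreshold`
#' (50 uV) AND every Fp1 sample lies within +/-`eogRejectThreshold` (80 uV).
#' Epochs already rejected (e.g. at the recording edge) stay rejected.
#'
#' @param epochs an [EpochSet-class] of baseline-corrected epochs.
#' @param config a [ProtocolConfig-class]; defaults to the set's own.
#' @return the [EpochSet-class] with updated `accepted`/`reject_reason`.
#' @export
rejectArtifacts <- function(epochs, config = epochs@config) {
  arr <- epochs@data
  info <- epochs@info
  eegCh <- intersect(bciEegChannels(), dimnames(arr)[[1]])
  n <- dim(arr)[3]
  if (n) {
    eegMax <- apply(abs(arr[eegCh, , , drop = FALSE]), 3, max)
    eegBad <- eegMax > config@eegRejectThreshold
    eogBad <- rep(FALSE, n)
    if ("Fp1" %in% dimnames(arr)[[1]]) {
      eogMax <- apply(abs(arr["Fp1", , , drop = FALSE]), 3, max)
      eogBad <- eogMax > config@eogRejectThreshold
    }
    newBad <- info$accepted & (eegBad | eogBad)
    info$reject_reason[newBad] <- ifelse(eegBad[newBad], "eeg_amplitude",
                                         "eog_amplitude")
    info$accepted <- info$accepted & !(eegBad | eogBad)
  }
  initialize(epochs, info = info)
}

# Subset an EpochSet by epoch index, keeping metadata aligned.
.subsetEpochs <- function(epochs, idx) {
  info <- epochs@info[idx, , drop = FALSE]
  rownames(info) <- NULL
  initialize(epochs, data = epochs@data[, , idx, drop = FALSE], info = info)
}

#' Assign epochs to condition clusters and balance cluster sizes
#'
#' Accepted training-phase epochs are assigned to the four attended x
#' stimulated conditions (ADSD, ADSV, AVSD, AVSV); larger clusters are then
#' trimmed to the minimum cluster size by dropping their chronologically
#' last epochs, so that every condition contributes equally downstream.
#'
#' @param epochs an [EpochSet-class] after [rejectArtifacts()].
#' @return a balanced [EpochSet-class] containing only the retained epochs,
#'   ordered by onset, with a `clusterSizes` attribute giving the sizes
#'   before balancing.
#' @export
clusterAndBalance <- function(epochs) {
  info <- epochs@info
  keep <- info$accepted & info$phase == "training"
  conditions <- c("ADSD", "ADSV", "AVSD", "AVSV")
  sizes <- vapply(conditions,
                  function(cc) sum(keep & info$condition == cc), numeric(1))
  if (any(sizes == 0)) {
    stop("insufficient data: empty condition cluster (",
         paste(conditions[sizes == 0], collapse = ", "), ")")
  }
  minSize <- min(sizes)
  retain <- integer()
  for (cc in conditions) {
    idx <- which(keep & info$condition == cc)
    idx <- idx[order(info$onset_sample[idx])]
    retain <- c(retain, idx[seq_len(minSize)])
  }
  retain <- sort(retain)
  out <- .subsetEpochs(epochs, retain)
  attr(out, "clusterSizes") <- sizes
  out
}
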