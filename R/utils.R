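# Internal helpers shared across modules.

# Evaluate fun() under a temporary RNG seed, restoring the caller's stream.
.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  fun()
}

# Polynomial rolling hash of a character scalar, returned as hex. Used to
# stamp run manifests with a configuration fingerprint without extra
# dependencies (not cryptographic).
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Decimate the post-stimulus part of a channels x epochSamples matrix:
# keep every `downsampleFactor`-th sample starting at stimulus onset.
.decimatePostStimulus <- function(mat, config) {
  pre <- baselineSamples(config)
  post <- postStimulusSamples(config)
  keep <- seq(pre + 1L, pre + post, by = as.integer(config@downsampleFactor))
  mat[, keep, drop = FALSE]
}

.assertFinite <- function(x, what = "signal") {
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}
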