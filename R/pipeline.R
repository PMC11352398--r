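# Pipeline plumbing: configuration files, run manifests, and the
# simulate / train / test / run-session entry points that tie the modules
# together. A thin command-line wrapper over these functions is installed at
# inst/cli/serpbci.R.

.configFieldNames <- function() {
  setdiff(slotNames("ProtocolConfig"), character())
}

#' Read and write protocol configurations as YAML
#'
#' The file mirrors the [ProtocolConfig-class] slot names; any subset of
#' fields may be given and overrides the defaults. Unknown fields are an
#' error naming the offending field.
#'
#' @param path YAML file path.
#' @param config a [ProtocolConfig-class].
#' @return `readProtocolConfig()` returns a validated
#'   [ProtocolConfig-class].
#' @export
readProtocolConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- .configFieldNames()
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  }
  do.call(protocolConfig, vals)
}

#' @rdname readProtocolConfig
#' @export
writeProtocolConfig <- function(config, path) {
  vals <- lapply(.configFieldNames(), function(s) slot(config, s))
  names(vals) <- .configFieldNames()
  yaml::write_yaml(vals, path)
  invisible(path)
}

# A run manifest stamped onto every artifact set: configuration fingerprint,
# seed, versions, paths and timestamp. Identical manifests (up to timestamp)
# imply identical outputs.
.runManifest <- function(config, seed, paths = list()) {
  vals <- lapply(.configFieldNames(), function(s) slot(config, s))
  names(vals) <- .configFieldNames()
  list(config_hash = .fnv1a(paste(names(vals), vapply(vals, paste,
                                                      collapse = ",", ""),
                                  sep = "=", collapse = ";")),
       config = vals,
       seed = seed,
       package_version = as.character(packageVersion("serpBCI")),
       r_version = as.character(getRversion()),
       paths = paths,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Simulate a session and write its artifacts
#'
#' Generates a synthetic two-phase session and writes the continuous EDF
#' recording, the stimulus event TSV, the ground-truth JSON sidecar and a
#' run manifest into `outDir`.
#'
#' @param outDir output directory (created if missing).
#' @param seed integer seed.
#' @param configPath optional YAML configuration (defaults otherwise).
#' @param config a [ProtocolConfig-class]; overrides `configPath`.
#' @param montage `"right_impaired"` or `"left_impaired"`.
#' @param attentionGain late-window attention gain of the default templates.
#' @param noise a [NoiseModel-class].
#' @return invisibly, a named list of written paths.
#' @export
cmdSimulate <- function(outDir, seed = 1, configPath = NULL, config = NULL,
                        montage = "right_impaired", attentionGain = 2,
                        noise = noiseModel()) {
  if (is.null(config)) {
    config <- if (is.null(configPath)) protocolConfig()
              else readProtocolConfig(configPath)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  session <- generateSession(config,
                             defaultTemplates(config, attentionGain),
                             noise, montage = montage, seed = seed)
  paths <- list(
    edf = file.path(outDir, "session.edf"),
    events = file.path(outDir, "events.tsv"),
    ground_truth = file.path(outDir, "ground_truth.json"),
    manifest = file.path(outDir, "manifest.json"))
  writeEdf(session, paths$edf)
  writeEventTable(session@events, paths$events)
  gt <- session@groundTruth
  jsonlite::write_json(
    list(corrupted_events = gt$corrupted, artifacts = gt$artifacts,
         attention_gain = gt$attentionGain,
         channel_gains = as.list(gt$channelGains),
         first_target = gt$firstTarget, montage = session@montage),
    paths$ground_truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.runManifest(config, seed, paths), paths$manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Train the BCI from recorded artifacts
#'
#' Reads a continuous EDF and its event TSV, trains the five per-channel
#' classifiers and writes the model archive plus a JSON training report
#' (per-channel index counts, LOOCV accuracies, selected feedback channel).
#'
#' @param eegPath EDF path.
#' @param eventsPath event TSV path.
#' @param modelPath output path for the model archive.
#' @param configPath optional YAML configuration.
#' @param config a [ProtocolConfig-class]; overrides `configPath`.
#' @return invisibly, the [TrainedBci-class].
#' @export
cmdTrain <- function(eegPath, eventsPath, modelPath, configPath = NULL,
                     config = NULL) {
  if (is.null(config)) {
    config <- if (is.null(configPath)) protocolConfig()
              else readProtocolConfig(configPath)
  }
  edf <- readEdf(eegPath)
  events <- readEventTable(eventsPath)
  trained <- trainBci(edf$signal, events, config)
  saveTrainedBci(trained, modelPath)
  report <- list(
    feedback_channel = trained@feedbackChannel,
    channels = lapply(trained@channels, function(m) {
      list(loocv_accuracy = m@loocvAccuracy,
           n_iD = length(m@indexSet@iD), n_iV = length(m@indexSet@iV),
           fallback_D = m@indexSet@fallbackD,
           fallback_V = m@indexSet@fallbackV)
    }),
    training_info = trained@trainingInfo)
  jsonlite::write_json(report, paste0(modelPath, ".report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(trained)
}

#' Run the online test phase from recorded artifacts
#'
#' Reads the EDF, events and model archive, replays the online loop, and
#' writes the per-trial log TSV and the session-result JSON (per-channel
#' accuracies, subset maxima, feedback accuracy, ITR at the session's mean
#' decision time).
#'
#' @param eegPath EDF path.
#' @param eventsPath event TSV path.
#' @param modelPath model archive from [cmdTrain()].
#' @param outDir output directory.
#' @return invisibly, the [SessionResult-class].
#' @export
cmdTest <- function(eegPath, eventsPath, modelPath, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  edf <- readEdf(eegPath)
  events <- readEventTable(eventsPath)
  trained <- readTrainedBci(modelPath)
  result <- runTestPhase(edf$signal, trained, events, trained@config)
  write.table(result@trials, file.path(outDir, "trial_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(per_channel_accuracy = as.list(result@perChannelAccuracy),
         feedback_channel = result@feedbackChannel,
         feedback_accuracy = result@feedbackAccuracy,
         max_all = result@maxAll, max_subset1 = result@maxSubset1,
         max_subset2 = result@maxSubset2, itr_bits_per_min = result@itr,
         mean_decision_time_s = result@meanDecisionTime),
    file.path(outDir, "session_result.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(result)
}

#' Run a complete simulated session in memory
#'
#' Generates a two-phase synthetic session, trains the BCI on the training
#' phase and replays the online test phase, filtering the continuous
#' recording once so training and online paths see identical causal
#' filtering.
#'
#' @param config a [ProtocolConfig-class].
#' @param templates `D`/`V` [SerpTemplate-class] list.
#' @param noise a [NoiseModel-class].
#' @param montage montage label.
#' @param seed integer seed.
#' @return list with `session`, `trained` and `result`.
#' @examples
#' \donttest{
#' r <- runSession(seed = 1)
#' channelAccuracies(r$result)
#' }
#' @export
runSession <- function(config = protocolConfig(),
                       templates = defaultTemplates(config),
                       noise = noiseModel(),
                       montage = "right_impaired",
                       seed = NULL) {
  session <- generateSession(config, templates, noise, montage = montage,
                             seed = seed)
  filtered <- bandpassFilter(session@signal, config)
  trained <- trainBci(filtered, session@events, config, filtered = TRUE)
  result <- runTestPhase(filtered, trained, session@events, config,
                         filtered = TRUE)
  list(session = session, trained = trained, result = result)
}
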