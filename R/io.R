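# Recording container read/write and CSV export.
#
# The on-disk container is a directory holding:
#   traces.csv        electrodes x samples, one column per electrode, full
#                     double precision (%.17g) so the round trip is
#                     bit-identical
#   meta.json         fs, epoch geometry, seed, design/stimulus/illumination
#   ground_truth.json per-pulse simulated fiber tables (absent for imported
#                     data)

.designToList <- function(d) list(
  channelLength = d@channelLength, crossSection = d@crossSection,
  nElectrodes = d@nElectrodes, pitch = d@pitch,
  electrodePositions = d@electrodePositions,
  stimToEntrance = d@stimToEntrance)

.designFromList <- function(l) new(
  "MicrochannelDesign", channelLength = l$channelLength,
  crossSection = as.numeric(l$crossSection),
  nElectrodes = as.integer(l$nElectrodes), pitch = l$pitch,
  electrodePositions = as.numeric(l$electrodePositions),
  stimToEntrance = l$stimToEntrance)

.stimToList <- function(s) list(
  pulseTimes = s@pulseTimes, polarity = s@polarity,
  phaseWidth = s@phaseWidth, repetitions = s@repetitions,
  artifactAmplitude = s@artifactAmplitude,
  artifactDuration = s@artifactDuration)

.stimFromList <- function(l) new(
  "StimulusProtocol", pulseTimes = as.numeric(l$pulseTimes),
  polarity = l$polarity, phaseWidth = l$phaseWidth,
  repetitions = as.integer(l$repetitions),
  artifactAmplitude = l$artifactAmplitude,
  artifactDuration = l$artifactDuration)

.illToList <- function(i) {
  if (is.null(i)) return(NULL)
  list(pulseOnsets = i@pulseOnsets, pulseDuration = i@pulseDuration,
       spotCenter = i@spotCenter, spotSigma = i@spotSigma,
       deltaTMax = i@deltaTMax, tauPolymer = i@tauPolymer)
}

.illFromList <- function(l) {
  if (is.null(l)) return(NULL)
  new("IlluminationProtocol", pulseOnsets = as.numeric(l$pulseOnsets),
      pulseDuration = l$pulseDuration, spotCenter = l$spotCenter,
      spotSigma = l$spotSigma, deltaTMax = l$deltaTMax,
      tauPolymer = l$tauPolymer)
}

#' Write / read a Recording container
#'
#' `writeRecording()` serializes a [Recording-class] to a directory
#' (`traces.csv` at full double precision plus JSON metadata and ground
#' truth); `readRecording()` restores it and validates the invariants
#' (positive sampling rate, finite traces, consistent epoch geometry). The
#' write-read round trip is bit-identical for traces and lossless for
#' metadata.
#'
#' @param recording a [Recording-class].
#' @param path directory to write to / read from (created if needed).
#' @return `writeRecording()` the path invisibly; `readRecording()` a
#'   [Recording-class].
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "Recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- t(recording@traces)
  colnames(tr) <- paste0("E", seq_len(nrow(recording@traces)))
  txt <- apply(tr, 2L, function(col) sprintf("%.17g", col))
  write.csv(txt, file.path(path, "traces.csv"), row.names = FALSE,
            quote = FALSE)
  meta <- list(
    fs = recording@fs, epochSamples = recording@epochSamples,
    preWindow = recording@preWindow, seed = recording@seed,
    noiseSnrDb = recording@noiseSnrDb,
    design = .designToList(recording@design),
    stim = .stimToList(recording@stim),
    illumination = .illToList(recording@illumination))
  write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
             digits = NA, null = "null")
  gt <- recording@groundTruth
  gtFlat <- if (length(gt))
    do.call(rbind, Map(function(i, df) cbind(pulse = i, df),
                       seq_along(gt), gt))
  else data.frame()
  write_json(gtFlat, file.path(path, "ground_truth.json"),
             digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  metaPath <- file.path(path, "meta.json")
  tracesPath <- file.path(path, "traces.csv")
  if (!file.exists(metaPath) || !file.exists(tracesPath))
    stop("not a recording container (missing meta.json or traces.csv): ",
         path)
  meta <- read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$fs) || meta$fs <= 0)
    stop("invalid container: fs must be > 0 (got ",
         if (is.null(meta$fs)) "missing" else meta$fs, ")")
  tr <- read.csv(tracesPath, colClasses = "character")
  traces <- t(vapply(tr, as.numeric, numeric(nrow(tr))))
  gtPath <- file.path(path, "ground_truth.json")
  gt <- list()
  if (file.exists(gtPath)) {
    raw <- read_json(gtPath, simplifyVector = TRUE)
    if (is.data.frame(raw) && nrow(raw))
      gt <- lapply(split(raw[, setdiff(names(raw), "pulse")], raw$pulse),
                   function(df) { rownames(df) <- NULL; df })
    names(gt) <- NULL
  }
  noise <- meta$noiseSnrDb
  if (is.null(noise)) noise <- NA_real_
  rec <- new("Recording",
             traces = unname(traces), fs = meta$fs,
             design = .designFromList(meta$design),
             stim = .stimFromList(meta$stim),
             illumination = .illFromList(meta$illumination),
             epochSamples = as.integer(meta$epochSamples),
             preWindow = meta$preWindow,
             seed = as.integer(meta$seed),
             groundTruth = gt,
             noiseSnrDb = as.numeric(noise))
  validObject(rec)
  rec
}

#' Export / import a recording as long-format CSV
#'
#' Small-fixture text interchange: one row per (time, electrode) sample with
#' columns `time` (s, session coordinates are not preserved; time is the
#' concatenated-epoch sample index over fs), `electrode` and `value` (uV,
#' float32-like %.8g precision). Import rebuilds the trace matrix only; use
#' the directory container for full metadata.
#'
#' @param recording a [Recording-class].
#' @param file CSV path.
#' @return `exportRecordingCsv()` the file invisibly; `importRecordingCsv()`
#'   a numeric electrodes x samples matrix with attribute `fs`.
#' @export
exportRecordingCsv <- function(recording, file) {
  nE <- nrow(recording@traces)
  n <- ncol(recording@traces)
  df <- data.frame(
    time = rep((seq_len(n) - 1) / recording@fs, each = nE),
    electrode = rep(seq_len(nE), times = n),
    value = sprintf("%.8g", as.numeric(recording@traces)))
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname exportRecordingCsv
#' @export
importRecordingCsv <- function(file) {
  df <- read.csv(file)
  nE <- max(df$electrode)
  n <- nrow(df) / nE
  m <- matrix(df$value, nrow = nE)
  dt <- unique(round(diff(unique(df$time)), 12))
  attr(m, "fs") <- if (length(dt)) 1 / dt[1] else NA_real_
  m
}
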