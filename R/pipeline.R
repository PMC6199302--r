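# Configured end-to-end pipeline: simulate -> process -> VSR/SR-model or
# neuroinhibition, with strict config schema, seed management and a session
# manifest for reproducibility.

.configSchema <- list(
  pipeline = c("sr", "inhibition"),
  seed = NULL,
  designs = c("channel_length", "n_electrodes", "pitch", "stim_to_entrance",
              "cross_section", "electrode_positions"),
  fibers = c("velocity", "amplitude", "width", "latency_jitter_sd"),
  grid = c("width", "velocity", "snr_db"),
  stimulus = c("repetitions", "period", "polarity", "phase_width",
               "artifact_amplitude", "artifact_duration"),
  illumination = c("onsets", "duration", "spot_center", "spot_sigma",
                   "delta_t_max", "tau_polymer"),
  coupling = c("c_slow", "c_fast", "tau_slow", "tau_fast",
               "block_depth", "velocity_temp_coeff"),
  noise = c("snr_db"),
  sim = c("fs", "epoch_duration", "pre_window", "onset_fraction"),
  analysis = c("v_min", "v_max", "n_control",
               "mask_electrodes", "v_threshold"))

#' Default pipeline configuration
#'
#' Full configuration with every recognized key; the SR pipeline sweeps two
#' standard designs over a small waveform grid, the inhibition pipeline runs
#' one session under the bench light schedule. Print it as YAML with
#' [dumpConfig()].
#'
#' @param pipeline "sr" or "inhibition".
#' @return nested named list.
#' @export
defaultConfig <- function(pipeline = c("sr", "inhibition")) {
  pipeline <- match.arg(pipeline)
  base <- list(
    pipeline = pipeline,
    seed = 1L,
    designs = list(
      list(channel_length = 10, n_electrodes = 8, pitch = 1,
           stim_to_entrance = 8),
      list(channel_length = 6, n_electrodes = 5, pitch = 1,
           stim_to_entrance = 8)),
    stimulus = list(repetitions = 10L, period = 3, polarity = "cathodic",
                    phase_width = 50, artifact_amplitude = 150,
                    artifact_duration = 1e-4),
    noise = list(snr_db = 30),
    sim = list(fs = 5e5, epoch_duration = NULL, pre_window = 0.005,
               onset_fraction = 0.08),
    analysis = list(v_min = 1, v_max = 60,
                    n_control = 10L, mask_electrodes = integer(0),
                    v_threshold = 5))
  if (pipeline == "sr") {
    base$grid <- list(width = c(0.1, 0.3), velocity = c(10, 30),
                      snr_db = c(10, 30))
  } else {
    base$fibers <- list(
      list(velocity = 12, amplitude = 45, width = 0.2),
      list(velocity = 2, amplitude = 18, width = 0.45))
    base$illumination <- list(onsets = c(30, 75, 120), duration = 15,
                              spot_center = 4.5, spot_sigma = 1.5,
                              delta_t_max = 10, tau_polymer = 3.22)
    cp <- couplingDefaults()
    base$coupling <- list(c_slow = cp$cSlow, c_fast = cp$cFast,
                          tau_slow = cp$tauSlow, tau_fast = cp$tauFast,
                          block_depth = cp$blockDepth,
                          velocity_temp_coeff = cp$velocityTempCoeff)
    base$stimulus$repetitions <- 55L
    base$sim$fs <- 25000
    base$designs <- base$designs[1]
  }
  base
}

#' @rdname defaultConfig
#' @param config a configuration list (default: [defaultConfig()]).
#' @export
dumpConfig <- function(config = defaultConfig()) {
  cat(as.yaml(config))
  invisible(config)
}

.validateConfig <- function(config) {
  unknown <- setdiff(names(config), names(.configSchema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(names(.configSchema), collapse = ", "))
  for (sec in names(config)) {
    valid <- .configSchema[[sec]]
    if (is.null(valid) || sec %in% c("pipeline", "seed")) next
    entries <- config[[sec]]
    if (sec %in% c("designs", "fibers")) {
      for (e in entries) {
        bad <- setdiff(names(e), valid)
        if (length(bad))
          stop("unknown key(s) in config section '", sec, "': ",
               paste(bad, collapse = ", "), "; valid keys: ",
               paste(valid, collapse = ", "))
      }
    } else {
      bad <- setdiff(names(entries), valid)
      if (length(bad))
        stop("unknown key(s) in config section '", sec, "': ",
             paste(bad, collapse = ", "), "; valid keys: ",
             paste(valid, collapse = ", "))
    }
  }
  if (is.null(config$pipeline) ||
      !config$pipeline %in% .configSchema$pipeline)
    stop("config must set pipeline to one of: ",
         paste(.configSchema$pipeline, collapse = ", "))
  invisible(config)
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(toJSON(config, auto_unbox = TRUE, digits = NA, null = "null"),
             tmp)
  unname(md5sum(tmp))
}

.designFromConfig <- function(dc) MicrochannelDesign(
  channelLength = dc$channel_length, nElectrodes = dc$n_electrodes,
  pitch = dc$pitch,
  electrodePositions = dc$electrode_positions,
  crossSection = if (is.null(dc$cross_section)) c(100, 100)
  else as.numeric(dc$cross_section),
  stimToEntrance = if (is.null(dc$stim_to_entrance)) 8 else dc$stim_to_entrance)

#' Run the configured analysis pipeline
#'
#' Executes simulate -> signal processing -> VSR -> SR model (pipeline
#' "sr") or simulate -> NSD -> kinetics -> ANOVA (pipeline "inhibition"),
#' writing all result tables as CSV, fitted models as JSON, and a
#' `manifest.json` carrying the config hash, seed and output list so any
#' table can be regenerated. Identical config + seed reproduces identical
#' tables. Unknown config keys are a hard error.
#'
#' @param config configuration list or path to a YAML file (see
#'   [defaultConfig()]).
#' @param outDir output directory (created).
#' @param seed optional override of the config seed.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = defaultConfig(), outDir, seed = NULL) {
  if (is.character(config)) config <- read_yaml(config)
  .validateConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  outputs <- character()
  stage <- function(name, expr) {
    s <- Sys.time()
    message("[nervechip] stage ", name, " ...")
    r <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    r
  }
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, name)
    p
  }
  sim <- config$sim
  if (config$pipeline == "sr") {
    designs <- lapply(config$designs, .designFromConfig)
    rs <- stage("simulate", simulateSrSweep(
      designs, widths = config$grid$width,
      velocities = config$grid$velocity, snrDbs = config$grid$snr_db,
      nRepetitions = config$stimulus$repetitions, fs = sim$fs,
      seed = config$seed))
    ds <- stage("vsr", srDataset(rs, vMin = config$analysis$v_min,
                                 vMax = config$analysis$v_max))
    emit(ds, "sr_dataset.csv")
    model <- tryCatch(stage("sr_model", fitSrModel(ds)),
                      error = function(e) {
                        message("[nervechip] SR model not fitted (",
                                conditionMessage(e), "); emitting the ",
                                "dataset only")
                        NULL
                      })
    if (!is.null(model)) {
      he <- standardizedHalfEffects(model)
      emit(he, "half_effects.csv")
      write_json(list(coefficients = as.list(model@coefficients),
                      se = as.list(model@se),
                      termPvalues = as.list(model@termPvalues),
                      r2 = model@r2, residualDf = model@residualDf,
                      ranges = as.data.frame(model@ranges)),
                 file.path(outDir, "model.json"), auto_unbox = TRUE,
                 digits = NA)
      outputs <- c(outputs, "model.json")
    }
  } else {
    design <- .designFromConfig(config$designs[[1]])
    fibers <- lapply(config$fibers, function(f) FiberSpec(
      velocity = f$velocity, amplitude = f$amplitude, width = f$width,
      latencyJitterSd = if (is.null(f$latency_jitter_sd)) 0
      else f$latency_jitter_sd))
    ill <- IlluminationProtocol(
      pulseOnsets = as.numeric(config$illumination$onsets),
      pulseDuration = config$illumination$duration,
      spotCenter = config$illumination$spot_center,
      spotSigma = config$illumination$spot_sigma,
      deltaTMax = config$illumination$delta_t_max,
      tauPolymer = config$illumination$tau_polymer)
    cp <- config$coupling
    coupling <- list(cSlow = cp$c_slow, cFast = cp$c_fast,
                     tauSlow = cp$tau_slow, tauFast = cp$tau_fast,
                     blockDepth = cp$block_depth,
                     velocityTempCoeff = cp$velocity_temp_coeff)
    stimP <- StimulusProtocol(
      repetitions = config$stimulus$repetitions,
      period = config$stimulus$period,
      polarity = config$stimulus$polarity,
      phaseWidth = config$stimulus$phase_width,
      artifactAmplitude = config$stimulus$artifact_amplitude,
      artifactDuration = config$stimulus$artifact_duration)
    rec <- stage("simulate", simulateInhibitionSession(
      design, fibers, stimP, ill, coupling = coupling,
      noiseSnrDb = config$noise$snr_db, fs = sim$fs, seed = config$seed))
    nsd <- stage("nsd", nsdSeries(
      rec, nControl = config$analysis$n_control,
      maskElectrodes = as.integer(config$analysis$mask_electrodes),
      vThreshold = config$analysis$v_threshold))
    emit(nsd, "nsd.csv")
    kin <- stage("kinetics", rbind(
      fitKinetics(nsd, ill, "inhibition"),
      fitKinetics(nsd, ill, "recovery")))
    emit(kin, "kinetics.csv")
    anv <- stage("anova", inhibitionAnova(nsd))
    emit(anv$omnibus, "anova_omnibus.csv")
    emit(anv$posthoc, "anova_posthoc.csv")
  }
  manifest <- list(
    configHash = .configHash(config),
    seed = config$seed,
    package = "nervechip",
    version = as.character(packageVersion("nervechip")),
    pipeline = config$pipeline,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs,
    timingsSec = timings)
  write_json(manifest, file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
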