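# S4 containers for microchannel recordings and derived results.
#
# Unit conventions, used throughout the package:
#   positions / lengths  mm      (channel geometry, electrode positions)
#   conduction velocity  m s^-1
#   SFAP width           ms      (full width at half amplitude)
#   amplitudes           uV
#   times                s       (session time; epoch time relative to pulse)
#   sampling rate        Hz
# Electrode positions are measured from the recording-channel entrance;
# electrode 1 is nearest the entrance. All windows are half-open [start, end).

#' Microchannel recording/stimulation geometry
#'
#' Describes one recording microchannel: its length, cross-section, and the
#' electrode array embedded in it, plus the distance from the stimulation
#' cathode to the recording-channel entrance (used to convert conduction
#' velocity into per-electrode arrival latency).
#'
#' @slot channelLength channel length in mm.
#' @slot crossSection numeric length-2, cross-section in um x um.
#' @slot nElectrodes number of electrodes (>= 2).
#' @slot pitch electrode pitch in mm.
#' @slot electrodePositions electrode positions in mm from the channel
#'   entrance, strictly increasing, all inside (0, channelLength).
#' @slot stimToEntrance distance from the stimulation cathode to the
#'   recording-channel entrance, mm.
#' @export
setClass("MicrochannelDesign", representation(
  channelLength = "numeric",
  crossSection = "numeric",
  nElectrodes = "integer",
  pitch = "numeric",
  electrodePositions = "numeric",
  stimToEntrance = "numeric"
))

setValidity("MicrochannelDesign", function(object) {
  msg <- character()
  if (length(object@channelLength) != 1L || object@channelLength <= 0)
    msg <- c(msg, "channelLength must be a single positive number (mm)")
  if (length(object@crossSection) != 2L || any(object@crossSection <= 0))
    msg <- c(msg, "crossSection must be two positive numbers (um x um)")
  if (object@nElectrodes < 2L)
    msg <- c(msg, "nElectrodes must be >= 2")
  if (length(object@pitch) != 1L || object@pitch <= 0)
    msg <- c(msg, "pitch must be > 0 (mm)")
  p <- object@electrodePositions
  if (length(p) != object@nElectrodes)
    msg <- c(msg, "electrodePositions must have length nElectrodes")
  if (length(p) && (any(diff(p) <= 0)))
    msg <- c(msg, "electrodePositions must be strictly increasing")
  if (length(p) && (any(p <= 0) || any(p >= object@channelLength)))
    msg <- c(msg, "electrodePositions must lie within (0, channelLength)")
  if (length(p) > 1L) {
    gaps <- diff(p)
    if (max(abs(gaps - gaps[1])) < 1e-9 &&
        abs(gaps[1] - object@pitch) > 1e-6)
      msg <- c(msg, "uniform electrodePositions inconsistent with pitch")
  }
  if (length(object@stimToEntrance) != 1L || object@stimToEntrance < 0)
    msg <- c(msg, "stimToEntrance must be a single non-negative number (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a MicrochannelDesign
#'
#' If `electrodePositions` is omitted, the electrode array is centred in the
#' channel with the requested pitch (the standard layout: 8 electrodes at 1 mm
#' pitch in a 10 mm channel sit at 1.5, 2.5, ..., 8.5 mm).
#'
#' @param channelLength channel length, mm (4-10 mm in the standard designs).
#' @param nElectrodes number of electrodes (2-8).
#' @param pitch electrode pitch, mm.
#' @param electrodePositions optional explicit positions, mm from entrance.
#' @param crossSection channel cross-section, um x um.
#' @param stimToEntrance stimulation cathode to recording entrance, mm (the
#'   default matches the 8 mm stimulation channel preceding the recording
#'   channel).
#' @return a [MicrochannelDesign-class] object.
#' @examples
#' d <- MicrochannelDesign(channelLength = 10, nElectrodes = 8, pitch = 1)
#' electrodePositions(d)
#' @export
MicrochannelDesign <- function(channelLength, nElectrodes, pitch,
                               electrodePositions = NULL,
                               crossSection = c(100, 100),
                               stimToEntrance = 8) {
  nElectrodes <- as.integer(nElectrodes)
  if (is.null(electrodePositions)) {
    span <- (nElectrodes - 1L) * pitch
    if (span >= channelLength)
      stop("electrode array span (", span, " mm) does not fit in a ",
           channelLength, " mm channel")
    start <- (channelLength - span) / 2
    electrodePositions <- start + pitch * seq(0L, nElectrodes - 1L)
  }
  new("MicrochannelDesign", channelLength = channelLength,
      crossSection = crossSection, nElectrodes = nElectrodes, pitch = pitch,
      electrodePositions = electrodePositions,
      stimToEntrance = stimToEntrance)
}

#' Single-fiber waveform specification
#'
#' Ground-truth description of one nerve fiber's extracellular signature:
#' conduction velocity, pre-amplification baseline-to-peak amplitude, full
#' width at half amplitude, and trial-to-trial latency jitter. The fiber class
#' ("slow" vs "fast") is derived from the 5 m/s velocity threshold and is not
#' stored.
#'
#' @slot velocity conduction velocity, m/s (> 0).
#' @slot amplitude baseline-to-peak amplitude before channel amplification, uV.
#' @slot width full width at half amplitude, ms.
#' @slot latencyJitterSd standard deviation of per-repetition latency jitter, ms.
#' @export
setClass("FiberSpec", representation(
  velocity = "numeric",
  amplitude = "numeric",
  width = "numeric",
  latencyJitterSd = "numeric"
))

setValidity("FiberSpec", function(object) {
  msg <- character()
  if (object@velocity <= 0) msg <- c(msg, "velocity must be > 0")
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (object@latencyJitterSd < 0) msg <- c(msg, "latencyJitterSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FiberSpec
#' @param velocity conduction velocity, m/s.
#' @param amplitude baseline-to-peak amplitude, uV.
#' @param width full width at half amplitude, ms.
#' @param latencyJitterSd per-repetition latency jitter SD, ms.
#' @return a [FiberSpec-class] object.
#' @examples
#' f <- FiberSpec(velocity = 13.3, amplitude = 55, width = 0.22)
#' fiberClass(f)
#' @export
FiberSpec <- function(velocity, amplitude, width, latencyJitterSd = 0) {
  new("FiberSpec", velocity = velocity, amplitude = amplitude, width = width,
      latencyJitterSd = latencyJitterSd)
}

#' Electrical stimulation protocol
#'
#' @slot pulseTimes stimulus pulse times, s from session start, strictly
#'   increasing; one elicited response (epoch) per pulse.
#' @slot polarity "cathodic" or "anodic".
#' @slot phaseWidth stimulation phase width, us.
#' @slot repetitions number of repetitions of the stimulus (equals
#'   length(pulseTimes)).
#' @slot artifactAmplitude stimulation-artifact amplitude, uV.
#' @slot artifactDuration stimulation-artifact duration, s.
#' @export
setClass("StimulusProtocol", representation(
  pulseTimes = "numeric",
  polarity = "character",
  phaseWidth = "numeric",
  repetitions = "integer",
  artifactAmplitude = "numeric",
  artifactDuration = "numeric"
))

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (object@repetitions < 1L) msg <- c(msg, "repetitions must be >= 1")
  if (length(object@pulseTimes) != object@repetitions)
    msg <- c(msg, "pulseTimes must have length repetitions")
  if (length(object@pulseTimes) > 1L && any(diff(object@pulseTimes) <= 0))
    msg <- c(msg, "pulseTimes must be strictly increasing")
  if (!object@polarity %in% c("cathodic", "anodic"))
    msg <- c(msg, "polarity must be 'cathodic' or 'anodic'")
  if (object@artifactDuration <= 0)
    msg <- c(msg, "artifactDuration must be > 0 (s)")
  if (length(msg)) msg else TRUE
})

#' Construct a StimulusProtocol
#'
#' Defaults follow the bench protocol: square cathodic pulses, 50 us phase,
#' 0.33 Hz repetition (one pulse every 3 s).
#'
#' @param repetitions number of stimulus repetitions.
#' @param period inter-pulse period, s.
#' @param pulseTimes explicit pulse times, s (overrides repetitions/period).
#' @param polarity "cathodic" (default) or "anodic".
#' @param phaseWidth phase width, us.
#' @param artifactAmplitude stimulation-artifact amplitude, uV.
#' @param artifactDuration stimulation-artifact duration, s.
#' @return a [StimulusProtocol-class] object.
#' @export
StimulusProtocol <- function(repetitions = 10, period = 3, pulseTimes = NULL,
                             polarity = "cathodic", phaseWidth = 50,
                             artifactAmplitude = 150,
                             artifactDuration = 1e-4) {
  if (is.null(pulseTimes))
    pulseTimes <- period * seq(0L, repetitions - 1L)
  new("StimulusProtocol", pulseTimes = as.numeric(pulseTimes),
      polarity = polarity, phaseWidth = phaseWidth,
      repetitions = as.integer(length(pulseTimes)),
      artifactAmplitude = artifactAmplitude,
      artifactDuration = artifactDuration)
}

#' Illumination protocol for opto-thermal inhibition
#'
#' Light pulses through the photothermal polymer film: onset times, common
#' duration, spot position along the channel, spatial spread of the induced
#' heating, peak steady-state temperature rise and the polymer's first-order
#' thermal time constant (3.22 s for the P3HT:PCBM film).
#'
#' @slot pulseOnsets light-pulse onset times, s from session start.
#' @slot pulseDuration light-pulse duration, s (15 s in the bench protocol).
#' @slot spotCenter illumination-spot centre, mm from channel entrance
#'   (electrode E4 in the bench layout).
#' @slot spotSigma Gaussian sigma of the heat profile along the channel, mm.
#' @slot deltaTMax steady-state temperature rise at the spot centre, deg C.
#' @slot tauPolymer thermal time constant, s.
#' @export
setClass("IlluminationProtocol", representation(
  pulseOnsets = "numeric",
  pulseDuration = "numeric",
  spotCenter = "numeric",
  spotSigma = "numeric",
  deltaTMax = "numeric",
  tauPolymer = "numeric"
))

setValidity("IlluminationProtocol", function(object) {
  msg <- character()
  if (object@pulseDuration <= 0) msg <- c(msg, "pulseDuration must be > 0")
  if (object@tauPolymer <= 0) msg <- c(msg, "tauPolymer must be > 0")
  if (object@deltaTMax < 0) msg <- c(msg, "deltaTMax must be >= 0")
  if (object@spotSigma <= 0) msg <- c(msg, "spotSigma must be > 0")
  on <- object@pulseOnsets
  if (length(on) > 1L && any(diff(on) < object@pulseDuration))
    msg <- c(msg, "light pulses must not overlap")
  if (length(msg)) msg else TRUE
})

#' Construct an IlluminationProtocol
#'
#' Defaults reproduce the bench schedule: a 15-s light pulse every 45 s aimed
#' at electrode E4, with the polymer thermal time constant of 3.22 s.
#'
#' @param pulseOnsets onset times, s.
#' @param pulseDuration pulse duration, s.
#' @param spotCenter spot centre, mm from channel entrance.
#' @param spotSigma heating spatial sigma, mm.
#' @param deltaTMax peak temperature rise, deg C.
#' @param tauPolymer thermal time constant, s.
#' @return an [IlluminationProtocol-class] object.
#' @export
IlluminationProtocol <- function(pulseOnsets = c(30, 75, 120),
                                 pulseDuration = 15, spotCenter = 4.5,
                                 spotSigma = 1.5, deltaTMax = 10,
                                 tauPolymer = 3.22) {
  new("IlluminationProtocol", pulseOnsets = pulseOnsets,
      pulseDuration = pulseDuration, spotCenter = spotCenter,
      spotSigma = spotSigma, deltaTMax = deltaTMax, tauPolymer = tauPolymer)
}

setClassUnion("IlluminationProtocolOrNULL", c("IlluminationProtocol", "NULL"))

#' Multichannel microchannel recording
#'
#' Epoched multichannel extracellular recording: one fixed-length window per
#' stimulus pulse, each starting `preWindow` seconds before its pulse. Traces
#' are stored as an electrodes x samples matrix in uV, epochs concatenated in
#' pulse order; use [epochMatrix()] to extract one epoch and [epochTime()] for
#' the within-epoch time axis (0 = stimulus).
#'
#' @slot traces numeric matrix, electrodes x (epochSamples * nEpochs), uV.
#' @slot fs sampling rate, Hz.
#' @slot design a [MicrochannelDesign-class].
#' @slot stim a [StimulusProtocol-class].
#' @slot illumination an [IlluminationProtocol-class] or NULL.
#' @slot epochSamples samples per epoch.
#' @slot preWindow pre-stimulus baseline included in each epoch, s.
#' @slot seed integer seed the recording was simulated with (NA for imported
#'   data).
#' @slot groundTruth list with one data.frame per pulse describing the
#'   simulated fibers (velocity, amplitude, width, jitter, modulation scale),
#'   empty for imported data.
#' @slot noiseSnrDb requested best-electrode SNR in dB (NA if noiseless).
#' @export
setClass("Recording", representation(
  traces = "matrix",
  fs = "numeric",
  design = "MicrochannelDesign",
  stim = "StimulusProtocol",
  illumination = "IlluminationProtocolOrNULL",
  epochSamples = "integer",
  preWindow = "numeric",
  seed = "integer",
  groundTruth = "list",
  noiseSnrDb = "numeric"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (!all(is.finite(object@traces))) msg <- c(msg, "traces must be finite")
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (nrow(object@traces) != object@design@nElectrodes)
    msg <- c(msg, "traces must have one row per electrode")
  nEp <- object@stim@repetitions
  if (ncol(object@traces) != object@epochSamples * nEp)
    msg <- c(msg, "traces width must equal epochSamples * repetitions")
  if (object@preWindow < 0 ||
      object@preWindow >= object@epochSamples / object@fs)
    msg <- c(msg, "preWindow must lie in [0, epoch duration)")
  if (length(msg)) msg else TRUE
})

#' Velocity grid for velocity-selective recording
#'
#' Integer-shift candidate grid: every integer shift s (samples, both signs,
#' s = 0 excluded) whose velocity pitch/(|s| dt) lies in [vMin, vMax].
#'
#' @slot shifts integer shifts, samples.
#' @slot velocities candidate velocities, m/s (pitch * fs / |s|).
#' @slot pitch electrode pitch, mm.
#' @slot fs sampling rate of the analysed traces, Hz.
#' @slot vMin,vMax velocity bounds, m/s.
#' @export
setClass("VelocityGrid", representation(
  shifts = "integer",
  velocities = "numeric",
  pitch = "numeric",
  fs = "numeric",
  vMin = "numeric",
  vMax = "numeric"
))

#' Velocity estimate from the delay-and-sum search
#'
#' @slot velocity estimated conduction velocity, m/s (NA if no estimate).
#' @slot direction "forward" (arrival time increasing with electrode index),
#'   "backward", or "none".
#' @slot delta velocity tolerance implied by the grid spacing at the estimate,
#'   m/s.
#' @slot peakMetric peak constructive-sum amplitude, uV.
#' @slot sStar winning integer shift, samples (signed).
#' @slot ok logical; FALSE when the metric was flat (no estimate).
#' @export
setClass("VelocityEstimate", representation(
  velocity = "numeric",
  direction = "character",
  delta = "numeric",
  peakMetric = "numeric",
  sStar = "integer",
  ok = "logical"
))

#' Success-rate result across stimulus repetitions
#'
#' @slot successRate fraction of repetitions whose estimated velocity falls
#'   within +/- delta of the reference velocity.
#' @slot nSuccess number of successful repetitions.
#' @slot nRepetitions number of repetitions.
#' @slot vReference velocity of the mean (averaged) epoch, m/s.
#' @slot delta tolerance used, m/s (grid delta at vReference).
#' @slot perRepetitionVelocities per-repetition velocity estimates, m/s.
#' @slot ok FALSE when the mean epoch yielded no estimate.
#' @export
setClass("SRResult", representation(
  successRate = "numeric",
  nSuccess = "integer",
  nRepetitions = "integer",
  vReference = "numeric",
  delta = "numeric",
  perRepetitionVelocities = "numeric",
  ok = "logical"
))

setValidity("SRResult", function(object) {
  msg <- character()
  if (object@ok) {
    if (object@nSuccess < 0L || object@nSuccess > object@nRepetitions)
      msg <- c(msg, "nSuccess must lie in [0, nRepetitions]")
    if (abs(object@successRate -
            object@nSuccess / object@nRepetitions) > 1e-12)
      msg <- c(msg, "successRate must equal nSuccess/nRepetitions")
  }
  if (length(msg)) msg else TRUE
})

#' Waveform metrology for one detected unit
#'
#' @slot amplitude baseline-to-peak amplitude on the best electrode, uV.
#' @slot width full width at half amplitude (half prominence) of the main
#'   lobe, ms.
#' @slot snrDb 20*log10(amplitude / pre-stimulus noise RMS), dB.
#' @slot perElectrodePeaks peak times per electrode, s relative to stimulus
#'   (NA where the unit was not detected).
#' @slot bestElectrode index of the maximum-amplitude electrode.
#' @slot clipped TRUE when the waveform appears clipped.
#' @export
setClass("SpikeMetrics", representation(
  amplitude = "numeric",
  width = "numeric",
  snrDb = "numeric",
  perElectrodePeaks = "numeric",
  bestElectrode = "integer",
  clipped = "logical"
))

#' Linear success-rate response-surface model
#'
#' Ordinary least squares fit of SR on [1, N_E, pitch, width, exp(1/v), SNR].
#'
#' @slot fit the underlying `lm` object.
#' @slot coefficients named coefficient vector.
#' @slot se coefficient standard errors.
#' @slot termPvalues type-II ANOVA F-test p-values per term.
#' @slot r2 in-sample R squared.
#' @slot residualDf residual degrees of freedom.
#' @slot ranges 2 x terms matrix of observed factor ranges (min/max), used for
#'   standardized half effects.
#' @slot source data source label ("simulated" or "experimental-like").
#' @export
setClass("SRLinearModel", representation(
  fit = "ANY",
  coefficients = "numeric",
  se = "numeric",
  termPvalues = "numeric",
  r2 = "numeric",
  residualDf = "numeric",
  ranges = "matrix",
  source = "character"
))

#' First-order surface-temperature response
#'
#' @slot times sample times, s.
#' @slot deltaT temperature rise above ambient, deg C.
#' @slot illumination the generating [IlluminationProtocol-class].
#' @export
setClass("TemperatureTrace", representation(
  times = "numeric",
  deltaT = "numeric",
  illumination = "IlluminationProtocol"
))

setValidity("TemperatureTrace", function(object) {
  if (any(object@deltaT < -1e-9)) "deltaT must be >= 0" else TRUE
})

#' A set of simulated recordings with their generation manifest
#'
#' @slot recordings list of [Recording-class] objects.
#' @slot manifest data.frame with one row per recording: design geometry and
#'   waveform-grid parameters (designId, channelLength, nElectrodes, pitch,
#'   width, velocity, snrDb, seed).
#' @export
setClass("RecordingSet", representation(
  recordings = "list",
  manifest = "data.frame"
))

setValidity("RecordingSet", function(object) {
  if (length(object@recordings) != nrow(object@manifest))
    "manifest must have one row per recording" else TRUE
})
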