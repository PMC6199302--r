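# Accessor generics and show methods.

#' @name accessors
#' @title Accessors for nervechip S4 classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an object from this package.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("channelLength", function(object) standardGeneric("channelLength"))
#' @rdname accessors
#' @export
setMethod("channelLength", "MicrochannelDesign",
          function(object) object@channelLength)

#' @rdname accessors
#' @export
setGeneric("nElectrodes", function(object) standardGeneric("nElectrodes"))
#' @rdname accessors
#' @export
setMethod("nElectrodes", "MicrochannelDesign",
          function(object) object@nElectrodes)
#' @rdname accessors
#' @export
setMethod("nElectrodes", "Recording",
          function(object) object@design@nElectrodes)

#' @rdname accessors
#' @export
setGeneric("electrodePitch", function(object) standardGeneric("electrodePitch"))
#' @rdname accessors
#' @export
setMethod("electrodePitch", "MicrochannelDesign", function(object) object@pitch)
#' @rdname accessors
#' @export
setMethod("electrodePitch", "Recording", function(object) object@design@pitch)

#' @rdname accessors
#' @export
setGeneric("electrodePositions",
           function(object) standardGeneric("electrodePositions"))
#' @rdname accessors
#' @export
setMethod("electrodePositions", "MicrochannelDesign",
          function(object) object@electrodePositions)
#' @rdname accessors
#' @export
setMethod("electrodePositions", "Recording",
          function(object) object@design@electrodePositions)

#' @rdname accessors
#' @export
setGeneric("stimToEntrance", function(object) standardGeneric("stimToEntrance"))
#' @rdname accessors
#' @export
setMethod("stimToEntrance", "MicrochannelDesign",
          function(object) object@stimToEntrance)

#' Fiber class from the 5 m/s velocity threshold
#'
#' Fibers slower than `threshold` (default 5 m/s) are "slow" (thin fibers),
#' the rest "fast" (large myelinated fibers).
#'
#' @param object a [FiberSpec-class] or numeric velocity vector (m/s).
#' @param threshold class boundary, m/s.
#' @return character, "slow" or "fast".
#' @export
setGeneric("fiberClass", function(object, threshold = 5)
  standardGeneric("fiberClass"))
#' @rdname fiberClass
#' @export
setMethod("fiberClass", "FiberSpec", function(object, threshold = 5)
  if (object@velocity < threshold) "slow" else "fast")
#' @rdname fiberClass
#' @export
setMethod("fiberClass", "numeric", function(object, threshold = 5)
  ifelse(object < threshold, "slow", "fast"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(object) object@fs)

#' @rdname accessors
#' @export
setGeneric("design", function(object) standardGeneric("design"))
#' @rdname accessors
#' @export
setMethod("design", "Recording", function(object) object@design)

#' @rdname accessors
#' @export
setGeneric("stimProtocol", function(object) standardGeneric("stimProtocol"))
#' @rdname accessors
#' @export
setMethod("stimProtocol", "Recording", function(object) object@stim)

#' @rdname accessors
#' @export
setGeneric("illumination", function(object) standardGeneric("illumination"))
#' @rdname accessors
#' @export
setMethod("illumination", "Recording", function(object) object@illumination)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "Recording", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setGeneric("traces", function(object) standardGeneric("traces"))
#' @rdname accessors
#' @export
setMethod("traces", "Recording", function(object) object@traces)

#' Number of epochs (stimulus pulses) in a recording
#' @param object a [Recording-class].
#' @return integer epoch count.
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname nEpochs
#' @export
setMethod("nEpochs", "Recording", function(object) object@stim@repetitions)

#' Extract one epoch from an epoched recording
#'
#' @param object a [Recording-class].
#' @param i epoch (pulse) index, 1-based.
#' @return electrodes x epochSamples matrix, uV.
#' @export
setGeneric("epochMatrix", function(object, i) standardGeneric("epochMatrix"))
#' @rdname epochMatrix
#' @export
setMethod("epochMatrix", "Recording", function(object, i) {
  i <- as.integer(i)
  if (i < 1L || i > nEpochs(object)) stop("epoch index out of range")
  es <- object@epochSamples
  object@traces[, ((i - 1L) * es + 1L):(i * es), drop = FALSE]
})

#' Within-epoch time axis
#'
#' @param object a [Recording-class].
#' @return numeric vector of sample times, s relative to the stimulus pulse
#'   (negative over the pre-stimulus baseline).
#' @export
setGeneric("epochTime", function(object) standardGeneric("epochTime"))
#' @rdname epochTime
#' @export
setMethod("epochTime", "Recording", function(object)
  (seq_len(object@epochSamples) - 1) / object@fs - object@preWindow)

#' Pointwise mean across all epochs
#'
#' Averages the repetitions of a time-locked stimulus, the first step of the
#' success-rate statistic (the averaged epoch defines the reference velocity).
#'
#' @param object a [Recording-class].
#' @return electrodes x epochSamples matrix, uV.
#' @export
setGeneric("meanEpoch", function(object) standardGeneric("meanEpoch"))
#' @rdname meanEpoch
#' @export
setMethod("meanEpoch", "Recording", function(object) {
  es <- object@epochSamples
  acc <- matrix(0, nrow(object@traces), es)
  for (i in seq_len(nEpochs(object))) acc <- acc + epochMatrix(object, i)
  acc / nEpochs(object)
})

setMethod("show", "MicrochannelDesign", function(object) {
  cat("MicrochannelDesign:", object@channelLength, "mm channel,",
      paste(object@crossSection, collapse = " x "), "um^2,",
      object@nElectrodes, "electrodes at", object@pitch, "mm pitch\n")
  cat("  positions (mm):",
      paste(format(object@electrodePositions), collapse = ", "), "\n")
})

setMethod("show", "FiberSpec", function(object) {
  cat(sprintf("FiberSpec: v = %g m/s (%s), amplitude = %g uV, width = %g ms\n",
              object@velocity, fiberClass(object), object@amplitude,
              object@width))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording: %d electrodes x %d epochs x %d samples @ %g kHz\n",
    nrow(object@traces), nEpochs(object), object@epochSamples,
    object@fs / 1000))
  cat(sprintf("  design: %g mm channel, pitch %g mm;%s SNR %s dB\n",
              object@design@channelLength, object@design@pitch,
              if (is.null(object@illumination)) "" else " illuminated;",
              if (is.na(object@noiseSnrDb)) "noiseless"
              else format(object@noiseSnrDb)))
})

setMethod("show", "VelocityEstimate", function(object) {
  if (!object@ok) {
    cat("VelocityEstimate: no estimate (flat metric)\n")
  } else {
    cat(sprintf(
      "VelocityEstimate: %.3f m/s (%s), delta = %.3f m/s, s* = %d\n",
      object@velocity, object@direction, object@delta, object@sStar))
  }
})

setMethod("show", "SRResult", function(object) {
  if (!object@ok) {
    cat("SRResult: undefined (mean epoch yielded no estimate)\n")
  } else {
    cat(sprintf(
      "SRResult: SR = %.2f (%d/%d), v_ref = %.3f m/s, delta = %.3f m/s\n",
      object@successRate, object@nSuccess, object@nRepetitions,
      object@vReference, object@delta))
  }
})

setMethod("show", "SpikeMetrics", function(object) {
  cat(sprintf(
    "SpikeMetrics: amplitude = %.2f uV, width = %.4f ms, SNR = %.1f dB (best electrode %d)%s\n",
    object@amplitude, object@width, object@snrDb, object@bestElectrode,
    if (object@clipped) " [clipped]" else ""))
})

setMethod("show", "SRLinearModel", function(object) {
  cat("SRLinearModel (", object@source, " data): R^2 = ",
      format(object@r2, digits = 3), ", residual df = ",
      object@residualDf, "\n", sep = "")
  print(data.frame(coefficient = object@coefficients, se = object@se))
})

setMethod("show", "VelocityGrid", function(object) {
  cat(sprintf(
    "VelocityGrid: %d shifts, v in [%.3g, %.3g] m/s (pitch %g mm @ %g kHz)\n",
    length(object@shifts), min(object@velocities), max(object@velocities),
    object@pitch, object@fs / 1000))
})

setMethod("show", "RecordingSet", function(object) {
  cat("RecordingSet:", length(object@recordings), "recordings\n")
  print(head(object@manifest))
})

setMethod("show", "TemperatureTrace", function(object) {
  cat(sprintf(
    "TemperatureTrace: %d samples over %.1f s, peak dT = %.2f degC, tau = %g s\n",
    length(object@times), diff(range(object@times)), max(object@deltaT),
    object@illumination@tauPolymer))
})
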