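# Synthetic microchannel recordings: SFAP templates, channel amplification,
# artifacts, calibrated noise, repetitions and opto-thermal modulation.

# Half-amplitude constant of the Ricker template: the positive root of
# (1 - x) exp(-x/2) = 1/2, so that the full width at half amplitude of
# (1 - t^2/s^2) exp(-t^2/(2 s^2)) equals 2 s sqrt(x).
.rickerHalfX <- 0.3917979837736634

.ricker <- function(t, sigma) {
  z <- (t / sigma)^2
  (1 - z) * exp(-z / 2)
}

#' Position-dependent microchannel amplification profile
#'
#' Phenomenological gain of the sealed microchannel as a function of the
#' normalized position `u` = z / channelLength along the channel. The default
#' shape g(u) proportional to u^a * (1 - u)^b with (a, b) = (1, 1/2) vanishes
#' at the entrance, peaks at u = a/(a+b) = 2/3 of the channel length
#' (normalized to gain 1 there) and falls off asymmetrically towards the exit,
#' matching the measured amplitude/SNR profile. Replace `shape` (or supply a
#' lookup-table gain via [channelGainScale()]'s calibration) to emulate other
#' seal geometries.
#'
#' @param u normalized position(s) in `[0, 1]`.
#' @param shape numeric length-2, exponents (a, b) of u^a (1-u)^b.
#' @return dimensionless gain(s) in `[0, 1]`.
#' @examples
#' amplificationProfile(2 / 3)   # 1 at the peak
#' amplificationProfile(0)       # no sealed length at the entrance
#' @export
amplificationProfile <- function(u, shape = c(1, 0.5)) {
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("u must lie in [0, 1]")
  a <- shape[1]; b <- shape[2]
  uStar <- a / (a + b)
  peak <- uStar^a * (1 - uStar)^b
  (u^a * (1 - u)^b) / peak
}

#' Peak-gain scaling with microchannel length
#'
#' Longer microchannels seal more of the extracellular path and amplify more.
#' The default calibration is linear in channel length, normalized to 1 at
#' `refLength`; a measured calibration can be supplied as a
#' `data.frame(length, gain)` lookup table (linearly interpolated) or as a
#' function of length.
#'
#' @param channelLength channel length(s), mm (> 0).
#' @param calibration `NULL` (linear default), a `data.frame` with columns
#'   `length` and `gain`, or a function length -> gain.
#' @param refLength reference length for the linear default, mm.
#' @param extrapolate allow evaluation outside a table calibration's range.
#' @return dimensionless scale factor(s).
#' @examples
#' channelGainScale(10) / channelGainScale(4)  # longer channel, larger gain
#' @export
channelGainScale <- function(channelLength, calibration = NULL,
                             refLength = 10, extrapolate = FALSE) {
  if (any(channelLength <= 0)) stop("channelLength must be > 0")
  if (is.null(calibration)) return(channelLength / refLength)
  if (is.function(calibration)) return(calibration(channelLength))
  if (!all(c("length", "gain") %in% names(calibration)))
    stop("table calibration needs columns 'length' and 'gain'")
  rng <- range(calibration$length)
  outside <- channelLength < rng[1] | channelLength > rng[2]
  if (any(outside) && !extrapolate)
    stop("channelLength ", paste(channelLength[outside], collapse = ", "),
         " mm outside calibration range [", rng[1], ", ", rng[2],
         "] mm and extrapolation is disabled")
  approx(calibration$length, calibration$gain, xout = channelLength,
         rule = 2)$y
}

#' Triphasic SFAP waveform template
#'
#' Ricker (second derivative of a Gaussian) template parameterized directly by
#' its full width at half amplitude and baseline-to-peak amplitude. The
#' template is zero-mean (AC-coupled-like) and triphasic, matching the
#' extracellular SFAP shapes recorded in the microchannel.
#'
#' @param width full width at half amplitude of the main lobe, ms.
#' @param amplitude baseline-to-peak amplitude, uV (0 gives an all-zero trace).
#' @param fs sampling rate, Hz; must provide at least 10 samples across
#'   `width`.
#' @param support half-support of the returned window, in units of the
#'   template's Gaussian sigma.
#' @return numeric waveform (uV) with attributes `center` (peak sample index),
#'   `sigma` (s) and `fs`.
#' @examples
#' w <- sfapTemplate(width = 0.22, amplitude = 55, fs = 5e5)
#' max(w)  # 55 uV
#' @export
sfapTemplate <- function(width, amplitude, fs, support = 8) {
  if (width <= 0) stop("width must be > 0 (ms)")
  if (amplitude < 0) stop("amplitude must be >= 0 (uV)")
  if (fs * width * 1e-3 < 10)
    stop("undersampled template: width ", width, " ms requires fs >= ",
         format(10 / (width * 1e-3)), " Hz (got ", format(fs), " Hz)")
  sigma <- width * 1e-3 / (2 * sqrt(.rickerHalfX))
  half <- ceiling(support * sigma * fs)
  t <- (-half:half) / fs
  w <- amplitude * .ricker(t, sigma)
  structure(w, center = half + 1L, sigma = sigma, fs = fs)
}

# First-order response fraction (0..1) of the illumination drive evaluated
# with an arbitrary time constant tau: rises as 1 - exp(-(t - on)/tau) during
# each light pulse and decays exponentially after light-off, contributions of
# successive pulses superposed.
.stateFraction <- function(t, illumination, tau) {
  f <- numeric(length(t))
  dur <- illumination@pulseDuration
  for (on in illumination@pulseOnsets) {
    off <- on + dur
    rising <- t >= on & t < off
    f[rising] <- f[rising] + (1 - exp(-(t[rising] - on) / tau))
    fOff <- 1 - exp(-dur / tau)
    after <- t >= off
    f[after] <- f[after] + fOff * exp(-(t[after] - off) / tau)
  }
  pmin(f, 1)
}

#' Default opto-thermal coupling parameters
#'
#' Phenomenological temperature-to-amplitude coupling of the two fiber
#' classes. The per-class modulation follows a first-order response to the
#' light drive with class-specific time constants (membrane response), on top
#' of the Gaussian spatial heat profile:
#' scale = 1 - c_class * deltaT(z, t). Slow (thin) fibers couple more strongly
#' and respond more slowly than fast (large myelinated) fibers. In addition,
#' slow-fiber conduction through the heated spot is progressively blocked:
#' electrodes downstream of the spot see the slow-fiber signal multiplied by
#' a transmission factor 1 - blockDepth * state(t, tauSlow), so at the
#' default blockDepth = 1 slow fibers appear fully blocked downstream at
#' steady state, reversibly. Fast-fiber conduction velocity increases mildly
#' with temperature (`velocityTempCoeff` per deg C).
#'
#' @return named list with elements `cSlow`, `cFast` (1/degC), `tauSlow`,
#'   `tauFast` (s), `blockDepth` (0..1), `velocityTempCoeff` (1/degC).
#' @export
couplingDefaults <- function() {
  list(cSlow = 0.08, cFast = 0.055, tauSlow = 6.44, tauFast = 3.22,
       blockDepth = 1, velocityTempCoeff = 0.005)
}

#' Draw random fibers with amplitude-velocity coupling
#'
#' Median amplitude increases linearly with conduction velocity (SNR and
#' amplitude are positively correlated with velocity in the microchannel),
#' with lognormal scatter and an occasional high-amplitude outlier emulating
#' superposed same-velocity spikes.
#'
#' @param n number of fibers.
#' @param velocityRange m/s range to draw velocities from (log-uniform).
#' @param widthIntercept,widthScale median width = intercept + scale / v, ms
#'   (large myelinated fibers conduct fast and spike briefly); widths are
#'   clipped to [0.03, 0.3] ms.
#' @param widthSdLog lognormal sdlog of the width scatter.
#' @param amplitudeIntercept,amplitudeSlope median amplitude = intercept +
#'   slope * velocity, uV.
#' @param scatterSdLog lognormal sdlog of the amplitude scatter.
#' @param outlierProb probability a fiber is a doubled-amplitude outlier.
#' @param latencyJitterSd per-repetition latency jitter SD, ms.
#' @param seed integer seed.
#' @return list of [FiberSpec-class] objects.
#' @export
randomFibers <- function(n, velocityRange = c(2, 60),
                         widthIntercept = 0.05, widthScale = 1.2,
                         widthSdLog = 0.2,
                         amplitudeIntercept = 20, amplitudeSlope = 1.2,
                         scatterSdLog = 0.25, outlierProb = 0.1,
                         latencyJitterSd = 0, seed = 1) {
  set.seed(seed)
  v <- exp(runif(n, log(velocityRange[1]), log(velocityRange[2])))
  w <- pmin(0.3, pmax(0.03,
                      (widthIntercept + widthScale / v) *
                        exp(rnorm(n, 0, widthSdLog))))
  med <- amplitudeIntercept + amplitudeSlope * v
  amp <- med * exp(rnorm(n, 0, scatterSdLog))
  amp <- amp * ifelse(runif(n) < outlierProb, 2, 1)
  lapply(seq_len(n), function(i)
    FiberSpec(velocity = v[i], amplitude = amp[i], width = w[i],
              latencyJitterSd = latencyJitterSd))
}

# Auto epoch duration: pre-stimulus baseline + slowest arrival + template
# tails + 20% margin, rounded up to 0.5 ms.
.autoEpochDuration <- function(design, fibers, preWindow) {
  vMin <- min(vapply(fibers, function(f) f@velocity, 0))
  wMax <- max(vapply(fibers, function(f) f@width, 0))
  jMax <- max(vapply(fibers, function(f) f@latencyJitterSd, 0))
  dMax <- design@stimToEntrance + max(design@electrodePositions)
  tail <- 8 * wMax * 1e-3 / (2 * sqrt(.rickerHalfX))
  dur <- preWindow + 1.2 * (dMax * 1e-3 / vMin) + tail + 6 * jMax * 1e-3 +
    5e-4
  ceiling(dur / 5e-4) * 5e-4
}

#' Simulate an epoched multichannel microchannel recording
#'
#' Per stimulus pulse, each electrode receives: (i) the stimulation artifact,
#' identical and simultaneous on all electrodes; (ii) one onset artifact per
#' fiber at its entrance-crossing time, also simultaneous across electrodes;
#' and (iii) each fiber's SFAP template delayed by
#' (stimToEntrance + z_e) / v and scaled by
#' `amplificationProfile(z_e / L) * channelGainScale(L)`. Gaussian noise is
#' calibrated so the best-electrode SNR (20 log10 of peak amplitude over noise
#' RMS) equals `noiseSnrDb`. When `illumination` and `coupling` are supplied,
#' fiber amplitudes are additionally modulated by the opto-thermal model (see
#' [couplingDefaults()]), slow fibers are blocked downstream of the spot while
#' the local temperature rise exceeds the block threshold, and fast-fiber
#' velocity increases with temperature. Identical arguments and seed give
#' identical traces.
#'
#' @param design a [MicrochannelDesign-class].
#' @param fibers a [FiberSpec-class] or list of them.
#' @param stim a [StimulusProtocol-class]; one epoch is simulated per pulse.
#' @param noiseSnrDb requested best-electrode SNR, dB (`NULL` = noiseless;
#'   negative values are allowed but warned about).
#' @param fs sampling rate, Hz.
#' @param seed integer seed; per-pulse noise/jitter sub-streams are derived
#'   deterministically from it.
#' @param epochDuration epoch length, s (`NULL` = sized automatically from the
#'   slowest fiber).
#' @param preWindow pre-stimulus baseline included in each epoch, s.
#' @param onsetFraction onset-artifact amplitude as a fraction of the
#'   fiber's amplitude (the artifact is caused by the spike entering the
#'   channel, so it scales with fiber size; it is amplified by the channel
#'   gain but carries no positional profile).
#' @param onsetWidth width of the onset transient, ms (a brief
#'   entrance-crossing event, independent of the fiber's SFAP width).
#' @param onsetLambda spatial decay length of the onset artifact along the
#'   channel, mm: the transient is simultaneous on all electrodes but its
#'   amplitude decays as exp(-z/onsetLambda) away from the entrance where it
#'   is generated.
#' @param illumination optional [IlluminationProtocol-class].
#' @param coupling optional coupling parameter list (see [couplingDefaults()]).
#' @param profileShape exponents passed to [amplificationProfile()].
#' @param gainCalibration calibration passed to [channelGainScale()].
#' @return a [Recording-class].
#' @examples
#' rec <- simulateRecording(
#'   MicrochannelDesign(10, 8, 1),
#'   FiberSpec(velocity = 13.3, amplitude = 55, width = 0.22),
#'   StimulusProtocol(repetitions = 3), noiseSnrDb = 30, seed = 1)
#' rec
#' @export
simulateRecording <- function(design, fibers, stim, noiseSnrDb = NULL,
                              fs = 50000, seed = 1, epochDuration = NULL,
                              preWindow = 0.005, onsetFraction = 0.08,
                              onsetWidth = 0.06, onsetLambda = 3,
                              illumination = NULL, coupling = NULL,
                              profileShape = c(1, 0.5),
                              gainCalibration = NULL) {
  if (is(fibers, "FiberSpec")) fibers <- list(fibers)
  stopifnot(length(fibers) >= 1)
  for (f in fibers) validObject(f)
  validObject(design); validObject(stim)
  if (!is.null(noiseSnrDb) && noiseSnrDb < 0)
    warning("negative requested SNR (", noiseSnrDb, " dB)")
  if (is.null(epochDuration))
    epochDuration <- .autoEpochDuration(design, fibers, preWindow)
  es <- as.integer(round(epochDuration * fs))
  tRel <- (seq_len(es) - 1) / fs - preWindow
  nE <- design@nElectrodes
  nP <- stim@repetitions
  L <- design@channelLength
  z <- design@electrodePositions
  lengthScale <- channelGainScale(L, calibration = gainCalibration)
  gain <- amplificationProfile(z / L, shape = profileShape) * lengthScale
  useTherm <- !is.null(illumination) && !is.null(coupling)

  # per-fiber static pieces
  sigmas <- vapply(fibers, function(f) f@width * 1e-3 / (2 * sqrt(.rickerHalfX)), 0)
  classes <- vapply(fibers, fiberClass, "")

  # stimulation artifact (identical on all electrodes)
  sgn <- if (stim@polarity == "cathodic") -1 else 1
  art <- numeric(es)
  firstHalf <- tRel >= 0 & tRel < stim@artifactDuration / 2
  secondHalf <- tRel >= stim@artifactDuration / 2 & tRel < stim@artifactDuration
  art[firstHalf] <- sgn * stim@artifactAmplitude
  art[secondHalf] <- -sgn * stim@artifactAmplitude

  traces <- matrix(0, nE, es * nP)
  gt <- vector("list", nP)
  clippedWarn <- FALSE
  bestPeak <- NA_real_

  for (p in seq_len(nP)) {
    set.seed((seed + 7919L * p) %% .Machine$integer.max)
    tp <- stim@pulseTimes[p]
    epoch <- matrix(rep(art, each = nE), nE, es)
    fiberOnly <- matrix(0, nE, es)
    rows <- vector("list", length(fibers))
    for (k in seq_along(fibers)) {
      f <- fibers[[k]]
      jit <- if (f@latencyJitterSd > 0)
        rnorm(1, 0, f@latencyJitterSd * 1e-3) else 0
      vEff <- f@velocity
      blocked <- FALSE
      scaleZ <- rep(1, nE)
      if (useTherm) {
        # true (polymer) temperature at the spot at this pulse time
        dTspot <- illumination@deltaTMax *
          .stateFraction(tp, illumination, illumination@tauPolymer)
        # class-specific effective modulation state (membrane response)
        tauC <- if (classes[k] == "slow") coupling$tauSlow else coupling$tauFast
        cC <- if (classes[k] == "slow") coupling$cSlow else coupling$cFast
        state <- .stateFraction(tp, illumination, tauC)
        G <- exp(-(z - illumination@spotCenter)^2 /
                   (2 * illumination@spotSigma^2))
        scaleZ <- 1 - cC * illumination@deltaTMax * state * G
        if (any(scaleZ < 0)) {
          scaleZ <- pmax(scaleZ, 0)
          if (!clippedWarn) {
            warning("opto-thermal coupling clipped at zero scale")
            clippedWarn <- TRUE
          }
        }
        if (classes[k] == "slow" && coupling$blockDepth > 0) {
          # conduction through the heated spot: downstream electrodes see
          # the signal attenuated by the (reversible) block transmission
          trans <- max(0, 1 - coupling$blockDepth * state)
          scaleZ[z > illumination@spotCenter] <-
            scaleZ[z > illumination@spotCenter] * trans
          blocked <- trans < 0.5
        }
        if (classes[k] == "fast")
          vEff <- f@velocity * (1 + coupling$velocityTempCoeff * dTspot)
      }
      tOn <- design@stimToEntrance * 1e-3 / vEff + jit
      # onset artifact: simultaneous on all electrodes, decaying along z
      on <- onsetFraction * f@amplitude * lengthScale *
        .ricker(tRel - tOn, onsetWidth * 1e-3 / (2 * sqrt(.rickerHalfX)))
      epoch <- epoch + exp(-z / onsetLambda) %o% on
      tArr <- (design@stimToEntrance + z) * 1e-3 / vEff + jit
      if (max(tArr) + 6 * sigmas[k] > max(tRel))
        stop("fiber arrival (", format(max(tArr) * 1e3),
             " ms) beyond trace end; increase epochDuration")
      for (e in seq_len(nE)) {
        a <- f@amplitude * gain[e] * scaleZ[e]
        if (a == 0) next
        wave <- a * .ricker(tRel - tArr[e], sigmas[k])
        fiberOnly[e, ] <- fiberOnly[e, ] + wave
      }
      rows[[k]] <- data.frame(
        fiber = k, velocity = f@velocity, vEff = vEff,
        amplitude = f@amplitude, width = f@width, class = classes[k],
        jitter = jit, blocked = blocked,
        scaleBest = scaleZ[which.max(gain)])
    }
    epoch <- epoch + fiberOnly
    if (p == 1L) bestPeak <- max(abs(fiberOnly))
    if (!is.null(noiseSnrDb)) {
      sdN <- bestPeak / 10^(noiseSnrDb / 20)
      epoch <- epoch + matrix(rnorm(nE * es, 0, sdN), nE, es)
    }
    traces[, ((p - 1L) * es + 1L):(p * es)] <- epoch
    gt[[p]] <- do.call(rbind, rows)
  }

  new("Recording", traces = traces, fs = fs, design = design, stim = stim,
      illumination = illumination, epochSamples = es, preWindow = preWindow,
      seed = as.integer(seed), groundTruth = gt,
      noiseSnrDb = if (is.null(noiseSnrDb)) NA_real_ else noiseSnrDb)
}

#' Simulate the success-rate sweep over designs and waveform grid
#'
#' One [Recording-class] per design x (width, velocity, SNR) grid point, each
#' with `nRepetitions` time-locked stimulus pulses and ground truth attached;
#' the standard bench sweep uses 10 designs x 30 waveforms x 10 repetitions.
#' Fiber amplitudes follow the amplitude-velocity coupling of
#' [randomFibers()] unless `amplitude` is given.
#'
#' @param designs list of [MicrochannelDesign-class] objects.
#' @param widths SFAP widths, ms.
#' @param velocities conduction velocities, m/s.
#' @param snrDbs requested SNRs, dB.
#' @param nRepetitions stimulus repetitions per recording (>= 2).
#' @param fs simulation sampling rate, Hz (500 kHz so narrow widths stay
#'   adequately sampled).
#' @param seed master seed; each recording derives its own sub-seed.
#' @param amplitude optional fixed fiber amplitude, uV.
#' @param ... passed to [simulateRecording()].
#' @return a [RecordingSet-class].
#' @export
simulateSrSweep <- function(designs, widths, velocities, snrDbs,
                            nRepetitions = 10, fs = 5e5, seed = 1,
                            amplitude = NULL, ...) {
  if (is(designs, "MicrochannelDesign")) designs <- list(designs)
  grid <- expand.grid(width = widths, velocity = velocities, snrDb = snrDbs,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L || length(designs) == 0L)
    stop("designs and waveform grid must be non-empty")
  if (nRepetitions < 2L)
    warning("nRepetitions < 2: downstream success rate is degenerate")
  recs <- list()
  man <- list()
  idx <- 0L
  for (d in seq_along(designs)) {
    for (g in seq_len(nrow(grid))) {
      idx <- idx + 1L
      subSeed <- (seed + 104729L * idx) %% .Machine$integer.max
      amp <- amplitude
      if (is.null(amp)) {
        set.seed(subSeed)
        amp <- (20 + 1.2 * grid$velocity[g]) * exp(rnorm(1, 0, 0.25))
      }
      fib <- FiberSpec(velocity = grid$velocity[g], amplitude = amp,
                       width = grid$width[g])
      recs[[idx]] <- simulateRecording(
        designs[[d]], fib,
        StimulusProtocol(repetitions = nRepetitions),
        noiseSnrDb = grid$snrDb[g], fs = fs, seed = subSeed, ...)
      man[[idx]] <- data.frame(
        designId = d, channelLength = designs[[d]]@channelLength,
        nElectrodes = designs[[d]]@nElectrodes, pitch = designs[[d]]@pitch,
        width = grid$width[g], velocity = grid$velocity[g],
        snrDb = grid$snrDb[g], amplitude = amp, seed = subSeed)
    }
  }
  new("RecordingSet", recordings = recs, manifest = do.call(rbind, man))
}

#' Simulate an opto-thermal inhibition session
#'
#' Convenience wrapper around [simulateRecording()] for illumination sessions:
#' requires at least one slow (v < 5 m/s) and one fast (v > 5 m/s) fiber, and
#' applies the opto-thermal modulation model. All modulation reverses after
#' light-off (thermal inhibition is reversible).
#'
#' @inheritParams simulateRecording
#' @param coupling coupling parameters, default [couplingDefaults()]; set the
#'   coupling coefficients to zero for a null (no-effect) session.
#' @return a [Recording-class] with illumination metadata attached.
#' @export
simulateInhibitionSession <- function(design, fibers, stim, illumination,
                                      coupling = couplingDefaults(),
                                      noiseSnrDb = 30, fs = 25000, seed = 1,
                                      ...) {
  if (is(fibers, "FiberSpec")) fibers <- list(fibers)
  cls <- vapply(fibers, fiberClass, "")
  if (!all(c("slow", "fast") %in% cls))
    stop("fibers must include at least one slow (v < 5 m/s) and one fast ",
         "(v > 5 m/s) fiber")
  validObject(illumination)
  simulateRecording(design, fibers, stim, noiseSnrDb = noiseSnrDb, fs = fs,
                    seed = seed, illumination = illumination,
                    coupling = coupling, ...)
}
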