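# Acquisition-side processing: zero-phase band-pass, cubic-spline
# up-sampling, threshold spike detection and waveform metrology.

.asElectrodeMatrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-1 Butterworth band-pass (default 100 Hz - 3 kHz) applied
#' forward-backward (`filtfilt`) so spike peak times are not shifted by the
#' filter's group delay; DC is removed by the high-pass edge. Note the bench
#' amplifier filters causally; zero-phase application is a deliberate choice
#' so velocity estimates do not inherit group delay.
#'
#' @param x numeric vector, electrodes x samples matrix, or
#'   [Recording-class].
#' @param fs sampling rate, Hz (taken from the recording when `x` is one).
#' @param lo,hi band edges, Hz; `hi` must be below Nyquist.
#' @param order filter order (1 as in the bench chain).
#' @return filtered object of the same shape/class as the input.
#' @export
setGeneric("bandpass", function(x, fs, lo = 100, hi = 3000, order = 1)
  standardGeneric("bandpass"))

.bandpassMatrix <- function(x, fs, lo, hi, order) {
  if (!(0 < lo && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2)
    stop("hi (", hi, " Hz) must be below the Nyquist frequency ", fs / 2,
         " Hz")
  bf <- butter(order, c(lo, hi) / (fs / 2), type = "pass")
  x <- .asElectrodeMatrix(x)
  # demean and reflect-pad each trace so the forward-backward pass has no
  # start-up transient (the high-pass edge removes any DC exactly)
  pad <- min(ncol(x) - 1L, as.integer(ceiling(fs / lo)))
  t(apply(x, 1L, function(row) {
    mu <- mean(row)
    row <- row - mu
    n <- length(row)
    ext <- c(2 * row[1] - rev(row[2:(pad + 1)]), row,
             2 * row[n] - rev(row[(n - pad):(n - 1)]))
    filtfilt(bf, ext)[(pad + 1):(pad + n)]
  }))
}

#' @rdname bandpass
#' @export
setMethod("bandpass", "numeric", function(x, fs, lo = 100, hi = 3000,
                                          order = 1)
  as.numeric(.bandpassMatrix(x, fs, lo, hi, order)))

#' @rdname bandpass
#' @export
setMethod("bandpass", "matrix", function(x, fs, lo = 100, hi = 3000,
                                         order = 1)
  .bandpassMatrix(x, fs, lo, hi, order))

#' @rdname bandpass
#' @export
setMethod("bandpass", "Recording", function(x, fs, lo = 100, hi = 3000,
                                            order = 1) {
  x@traces <- .bandpassMatrix(x@traces, x@fs, lo, hi, order)
  x
})

#' Cubic-spline up-sampling
#'
#' Interpolates each trace with a cubic spline from `fsIn` to `fsOut`
#' (50 kHz -> 500 kHz in the bench chain). The output passes through every
#' input sample exactly; `fsOut` must be an integer multiple of `fsIn`.
#'
#' @param x numeric vector, electrodes x samples matrix, or
#'   [Recording-class].
#' @param fsIn input sampling rate, Hz.
#' @param fsOut output sampling rate, Hz.
#' @return up-sampled object of the same shape/class; a recording's `fs` and
#'   epoch geometry are updated.
#' @export
setGeneric("upsampleSpline", function(x, fsIn, fsOut = 5e5)
  standardGeneric("upsampleSpline"))

.upsampleMatrix <- function(x, fsIn, fsOut) {
  r <- fsOut / fsIn
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop("fsOut must be an integer multiple of fsIn (got ratio ", r, ")")
  r <- as.integer(round(r))
  x <- .asElectrodeMatrix(x)
  n <- ncol(x)
  xin <- seq_len(n)
  xout <- seq(1, n, by = 1 / r)
  out <- t(apply(x, 1L, function(row)
    spline(xin, row, xout = xout, method = "fmm")$y))
  # exact recovery of the input samples at the original stride
  out[, seq(1L, ncol(out), by = r)] <- x
  out
}

#' @rdname upsampleSpline
#' @export
setMethod("upsampleSpline", "numeric", function(x, fsIn, fsOut = 5e5)
  as.numeric(.upsampleMatrix(x, fsIn, fsOut)))

#' @rdname upsampleSpline
#' @export
setMethod("upsampleSpline", "matrix", function(x, fsIn, fsOut = 5e5)
  .upsampleMatrix(x, fsIn, fsOut))

#' @rdname upsampleSpline
#' @export
setMethod("upsampleSpline", "Recording", function(x, fsIn, fsOut = 5e5) {
  if (missing(fsIn)) fsIn <- x@fs
  r <- as.integer(round(fsOut / fsIn))
  es <- x@epochSamples
  pieces <- lapply(seq_len(nEpochs(x)), function(i)
    .upsampleMatrix(epochMatrix(x, i), fsIn, fsOut))
  x@traces <- do.call(cbind, pieces)
  x@fs <- fsOut
  x@epochSamples <- as.integer(ncol(pieces[[1]]))
  x
})

# Robust noise scale of a segment: 1.4826 * MAD, spike-robust.
.noiseScale <- function(x) mad(x, constant = 1.4826)

#' Pooled pre-stimulus noise scale of a recording
#'
#' Robust noise scale (1.4826 x MAD) per electrode, pooled over the
#' pre-stimulus baselines of every epoch.
#'
#' @param recording a [Recording-class].
#' @return numeric vector, one scale per electrode (uV).
#' @export
pooledNoiseScale <- function(recording) {
  tRel <- epochTime(recording)
  pre <- rep(tRel < 0, nEpochs(recording))
  apply(recording@traces[, pre, drop = FALSE], 1L, .noiseScale)
}

# Pre-stimulus baseline samples of an epoch time axis.
.preMask <- function(tRel) tRel < 0

#' Threshold spike detection within one epoch
#'
#' Per electrode, samples whose absolute (baseline-subtracted) value exceeds
#' `k` times the robust noise scale (1.4826 x MAD of the pre-stimulus
#' segment) are grouped into events; events inside `blankWindows` (which must
#' cover the stimulation and onset artifacts) are discarded. Events are
#' returned sorted by time.
#'
#' @param epoch electrodes x samples matrix, uV.
#' @param fs sampling rate, Hz.
#' @param preWindow pre-stimulus baseline length, s (the first
#'   `preWindow * fs` samples of the epoch).
#' @param blankWindows list of `c(start, end)` windows, s relative to the
#'   stimulus, excluded from detection (half-open).
#' @param k detection threshold in noise-scale units.
#' @param minSep minimum separation between events, s.
#' @param noiseScale optional pre-computed robust noise scale per electrode
#'   (recycled); supply the pooled pre-stimulus scale across all epochs of a
#'   recording for a stabler threshold than a single epoch's baseline gives.
#' @return data.frame with columns electrode, peakTime (s rel. stimulus),
#'   polarity ("pos"/"neg"), start, end (s); zero rows when nothing crosses
#'   threshold (an all-blanked epoch is not an error).
#' @export
detectSpikes <- function(epoch, fs, preWindow, blankWindows = list(),
                         k = 4, minSep = 5e-4, noiseScale = NULL) {
  epoch <- .asElectrodeMatrix(epoch)
  es <- ncol(epoch)
  tRel <- (seq_len(es) - 1) / fs - preWindow
  pre <- .preMask(tRel)
  blank <- rep(FALSE, es)
  for (w in blankWindows) blank <- blank | (tRel >= w[1] & tRel < w[2])
  out <- list()
  if (!is.null(noiseScale))
    noiseScale <- rep_len(noiseScale, nrow(epoch))
  for (e in seq_len(nrow(epoch))) {
    x <- epoch[e, ]
    base <- median(x[pre])
    x <- x - base
    thr <- k * (if (is.null(noiseScale)) .noiseScale(x[pre])
                else noiseScale[e])
    if (thr == 0) thr <- k * 1e-12
    hot <- abs(x) > thr & !blank & !pre
    idx <- which(hot)
    if (!length(idx)) next
    gap <- c(Inf, diff(idx)) > minSep * fs
    grp <- cumsum(gap)
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      pk <- ii[which.max(abs(x[ii]))]
      out[[length(out) + 1L]] <- data.frame(
        electrode = e, peakTime = tRel[pk],
        polarity = if (x[pk] > 0) "pos" else "neg",
        start = tRel[min(ii)], end = tRel[max(ii)] + 1 / fs)
    }
  }
  if (!length(out))
    return(data.frame(electrode = integer(), peakTime = numeric(),
                      polarity = character(), start = numeric(),
                      end = numeric()))
  ev <- do.call(rbind, out)
  ev[order(ev$peakTime), , drop = FALSE]
}

# Full width at half amplitude of the dominant lobe around sample `pk`,
# with linear interpolation of the half crossings. x is baseline-subtracted.
.halfWidth <- function(x, pk, fs) {
  v <- x * sign(x[pk])        # rectify around the peak's polarity
  half <- v[pk] / 2
  iL <- pk
  while (iL > 1L && v[iL - 1L] > half) iL <- iL - 1L
  iR <- pk
  n <- length(v)
  while (iR < n && v[iR + 1L] > half) iR <- iR + 1L
  fracL <- if (iL > 1L) (v[iL] - half) / (v[iL] - v[iL - 1L]) else 0
  fracR <- if (iR < n) (v[iR] - half) / (v[iR] - v[iR + 1L]) else 0
  ((iR + fracR) - (iL - fracL)) / fs
}

#' Waveform metrology for one propagating unit
#'
#' Given the events of one unit (one event per electrode at most), measures
#' on the best (maximum-amplitude) electrode: amplitude from the pre-stimulus
#' baseline median, full width at half amplitude of the dominant lobe (half
#' crossings linearly interpolated), and SNR defined as 20 log10(amplitude /
#' RMS of the pre-stimulus noise). Also reports per-electrode peak times.
#'
#' @param epoch electrodes x samples matrix, uV.
#' @param fs sampling rate, Hz.
#' @param preWindow pre-stimulus baseline, s.
#' @param events data.frame from [detectSpikes()], restricted to one unit.
#' @param clipLimit absolute amplitude, uV, above which the waveform is
#'   flagged as clipped.
#' @return a [SpikeMetrics-class], or `NULL` when no events were supplied
#'   (e.g. a zero trace).
#' @export
measureSpike <- function(epoch, fs, preWindow, events, clipLimit = 5000) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  epoch <- .asElectrodeMatrix(epoch)
  es <- ncol(epoch)
  tRel <- (seq_len(es) - 1) / fs - preWindow
  pre <- .preMask(tRel)
  nE <- nrow(epoch)
  peaks <- rep(NA_real_, nE)
  amps <- rep(NA_real_, nE)
  for (e in seq_len(nE)) {
    ev <- events[events$electrode == e, , drop = FALSE]
    if (nrow(ev) == 0L) next
    base <- median(epoch[e, pre])
    pkCand <- vapply(ev$peakTime, function(pt) which.min(abs(tRel - pt)), 0L)
    pk <- pkCand[which.max(abs(epoch[e, pkCand] - base))]
    peaks[e] <- tRel[pk]
    amps[e] <- abs(epoch[e, pk] - base)
  }
  if (all(is.na(amps))) return(NULL)
  best <- which.max(amps)
  x <- epoch[best, ] - median(epoch[best, pre])
  pk <- which.min(abs(tRel - peaks[best]))
  width <- .halfWidth(x, pk, fs) * 1e3
  noiseRms <- sqrt(mean(x[pre]^2))
  snr <- if (noiseRms > 0) 20 * log10(amps[best] / noiseRms) else Inf
  new("SpikeMetrics", amplitude = amps[best], width = width, snrDb = snr,
      perElectrodePeaks = peaks, bestElectrode = as.integer(best),
      clipped = amps[best] >= clipLimit)
}

#' Predicted SNR gain from coherent averaging
#'
#' Averaging `n` time-locked repetitions leaves the signal unchanged and
#' reduces incoherent noise RMS by sqrt(n):
#' SNR_out = SNR_in + 10 log10(n).
#'
#' @param snrDb input SNR, dB.
#' @param nAverages number of averaged repetitions (>= 1).
#' @return predicted SNR, dB.
#' @examples
#' snrAfterAveraging(20, 100)  # 30 dB
#' @export
snrAfterAveraging <- function(snrDb, nAverages) {
  if (any(nAverages < 1)) stop("nAverages must be >= 1")
  snrDb + 10 * log10(nAverages)
}

#' Standard acquisition preprocessing for velocity analysis
#'
#' Mirrors the bench processing chain while keeping artifacts out of the
#' analysis: (i) subtract the stimulus-locked artifact template (square
#' biphasic pulse known from the stimulation protocol; fast waves genuinely
#' overlap it in time, so subtraction is preferred over blanking, which
#' would clip their leading lobe), (ii) cubic-spline up-sample to `fsOut`
#' when recorded below it, (iii) zero-phase band-pass. Artifact removal
#' before filtering prevents the band-pass tail of the large stimulation
#' artifact from leaking into the analysis window.
#'
#' @param recording a [Recording-class].
#' @param subtractStimArtifact remove the stimulation artifact using the
#'   protocol's template.
#' @param blankStimUntil optional end of an additional hard blank of the
#'   stimulation window, s after the stimulus (`NULL` = none).
#' @param fsOut target sampling rate, Hz (`NULL` to skip up-sampling).
#' @param filter apply the band-pass.
#' @param lo,hi band edges, Hz.
#' @return the processed [Recording-class].
#' @export
preprocessRecording <- function(recording, subtractStimArtifact = TRUE,
                                blankStimUntil = NULL, fsOut = 5e5,
                                filter = TRUE, lo = 100, hi = 3000) {
  tRel <- epochTime(recording)
  es <- recording@epochSamples
  stim <- recording@stim
  if (subtractStimArtifact) {
    sgn <- if (stim@polarity == "cathodic") -1 else 1
    art <- numeric(es)
    art[tRel >= 0 & tRel < stim@artifactDuration / 2] <-
      sgn * stim@artifactAmplitude
    art[tRel >= stim@artifactDuration / 2 &
          tRel < stim@artifactDuration] <- -sgn * stim@artifactAmplitude
    for (p in seq_len(nEpochs(recording)))
      recording@traces[, ((p - 1L) * es + 1L):(p * es)] <-
        sweep(recording@traces[, ((p - 1L) * es + 1L):(p * es),
                               drop = FALSE], 2L, art)
  }
  if (!is.null(blankStimUntil)) {
    zero <- tRel >= 0 & tRel < blankStimUntil
    for (p in seq_len(nEpochs(recording)))
      recording@traces[, (p - 1L) * es + which(zero)] <- 0
  }
  if (!is.null(fsOut) && fsOut > recording@fs)
    recording <- upsampleSpline(recording, fsOut = fsOut)
  if (filter) recording <- bandpass(recording, lo = lo, hi = hi)
  recording
}
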