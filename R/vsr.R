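# Velocity selective recording: integer-shift velocity grid, delay-and-sum
# search, grid tolerance delta, Eq.-style success rate and discard rules.

#' Integer-shift candidate velocity grid
#'
#' Candidate velocities implied by integer inter-electrode sample shifts:
#' v(s) = pitch / (|s| dt) = pitch * fs / |s|. All integer shifts with
#' velocity in `[vMin, vMax]`, both signs, s = 0 excluded (a zero shift only
#' matches non-propagating, artifact-like signals).
#'
#' @param pitch electrode pitch, mm.
#' @param fs sampling rate of the analysed traces, Hz (500 kHz after
#'   up-sampling in the bench chain).
#' @param vMin,vMax velocity bounds, m/s (fibers above 60 m/s are discarded
#'   from the study).
#' @return a [VelocityGrid-class].
#' @examples
#' g <- velocityGrid(pitch = 1, fs = 5e5)
#' g@velocities[g@shifts == 10]  # 50 m/s
#' @export
velocityGrid <- function(pitch, fs, vMin = 1, vMax = 60) {
  if (pitch <= 0) stop("pitch must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  vOf <- pitch * 1e-3 * fs # velocity of |s| = 1
  sMin <- ceiling(vOf / vMax - 1e-9)
  sMax <- floor(vOf / vMin + 1e-9)
  sMin <- max(sMin, 1L)
  if (sMax < sMin)
    stop("empty velocity grid for v in [", vMin, ", ", vMax,
         "] m/s with pitch ", pitch, " mm at fs ", fs, " Hz")
  sPos <- as.integer(sMin:sMax)
  shifts <- c(rev(-sPos), sPos)
  new("VelocityGrid", shifts = shifts, velocities = vOf / abs(shifts),
      pitch = pitch, fs = fs, vMin = vMin, vMax = vMax)
}

# velocity of a signed/unsigned shift on a grid's sampling
.vOfShift <- function(grid, s) grid@pitch * 1e-3 * grid@fs / abs(s)

# delta tolerance at integer shift magnitude sAbs: half the spacing between
# the two adjacent candidate velocities; one-sided (the full gap to the next
# slower candidate) at the fast edge of the grid where |s| - 1 has no
# candidate.
.deltaAt <- function(grid, sAbs) {
  sMin <- min(abs(grid@shifts))
  if (sAbs > sMin)
    (.vOfShift(grid, sAbs - 1L) - .vOfShift(grid, sAbs + 1L)) / 2
  else
    .vOfShift(grid, sAbs) - .vOfShift(grid, sAbs + 1L)
}

#' Delay-and-sum of a multichannel epoch at one shift
#'
#' Advances electrode i (0-based) by `i * s` samples and sums across
#' electrodes: out(t) = sum_i x_i(t + i s dt), zero-padded at the edges and
#' length-preserving, so the sum is constructive when `s` matches the true
#' inter-electrode propagation delay.
#'
#' @param epoch electrodes x samples matrix (stimulus-aligned, artifacts
#'   blanked).
#' @param s integer shift, samples (signed; positive = forward propagation).
#' @return numeric summed trace, same length as the epoch.
#' @export
delayAndSum <- function(epoch, s) {
  epoch <- .asElectrodeMatrix(epoch)
  n <- ncol(epoch)
  nE <- nrow(epoch)
  s <- as.integer(s)
  if (abs(s) * (nE - 1L) >= n)
    stop("|s| * (nElectrodes - 1) = ", abs(s) * (nE - 1L),
         " exceeds the epoch length ", n)
  out <- numeric(n)
  for (e in seq_len(nE)) {
    off <- (e - 1L) * s
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    out[keep] <- out[keep] + epoch[e, src[keep]]
  }
  out
}

#' Detect artifact windows by cross-electrode simultaneity
#'
#' Stimulation and onset artifacts are simultaneous on all electrodes,
#' whereas a propagating wave is delayed between electrodes. Events detected
#' on at least `minFraction` of the electrodes whose peak times agree within
#' `tol` seconds are declared artifacts, and their union window (padded by
#' `pad`) is returned for blanking before delay-and-sum.
#'
#' @param epoch electrodes x samples matrix, uV.
#' @param fs sampling rate, Hz.
#' @param preWindow pre-stimulus baseline, s.
#' @param k detection threshold in noise-scale units.
#' @param tol cross-electrode peak-time tolerance, s.
#' @param minFraction fraction of electrodes that must coincide.
#' @param pad padding added around each artifact window, s.
#' @return list of `c(start, end)` windows, s relative to the stimulus.
#' @export
artifactWindows <- function(epoch, fs, preWindow, k = 4,
                            tol = NULL, minFraction = 0.75, pad = 2e-5) {
  epoch <- .asElectrodeMatrix(epoch)
  if (is.null(tol)) tol <- max(2 / fs, 1e-5)
  ev <- detectSpikes(epoch, fs, preWindow, blankWindows = list(), k = k)
  if (nrow(ev) == 0L) return(list())
  nE <- nrow(epoch)
  need <- ceiling(minFraction * nE)
  ev <- ev[order(ev$peakTime), , drop = FALSE]
  wins <- list()
  i <- 1L
  while (i <= nrow(ev)) {
    inGrp <- abs(ev$peakTime - ev$peakTime[i]) <= tol
    grp <- ev[inGrp, , drop = FALSE]
    if (length(unique(grp$electrode)) >= need) {
      wins[[length(wins) + 1L]] <-
        c(min(grp$start) - pad, max(grp$end) + pad)
      i <- max(which(inGrp)) + 1L
    } else {
      i <- i + 1L
    }
  }
  wins
}

# Zero the given windows (s, relative to stimulus) on all electrodes.
.blankEpoch <- function(epoch, fs, preWindow, blankWindows) {
  if (!length(blankWindows)) return(epoch)
  tRel <- (seq_len(ncol(epoch)) - 1) / fs - preWindow
  for (w in blankWindows) epoch[, tRel >= w[1] & tRel < w[2]] <- 0
  epoch
}

#' Delay-and-sum velocity spectrum and estimate
#'
#' Evaluates the peak absolute constructive sum over every shift of the grid
#' (within the post-artifact analysis window) and returns the winning
#' candidate. Ties are broken deterministically towards the smaller |s|
#' (faster velocity). The tolerance `delta` is half the spacing to the two
#' adjacent grid velocities (one-sided at the fast grid edge). No sub-sample
#' refinement is applied: estimates live on the integer-shift grid.
#'
#' @param epoch electrodes x samples matrix, stimulus-aligned.
#' @param grid a [VelocityGrid-class]; its `fs` must match the epoch's
#'   sampling.
#' @param fs sampling rate of `epoch`, Hz.
#' @param preWindow pre-stimulus baseline of the epoch, s.
#' @param blankWindows artifact windows to zero before summation (the
#'   stimulation and onset artifacts are simultaneous across electrodes and
#'   would otherwise dominate near-zero shifts).
#' @param searchWindow optional `c(start, end)` (s, relative to stimulus)
#'   restricting where the summed-trace peak is taken; defaults to the whole
#'   post-stimulus epoch (blanked regions are zero and cannot host the peak).
#' @param autoBlank also blank artifact windows found by [artifactWindows()].
#' @param removeCommonMode subtract the across-electrode mean from every
#'   electrode before summation. Stimulation and onset artifacts are
#'   identical and simultaneous on all electrodes, so the common-average
#'   reference cancels them exactly while barely touching the propagating
#'   (delayed) wave; this is the default artifact treatment of [srDataset()].
#' @return a [VelocityEstimate-class]; `ok = FALSE` with NA velocity when the
#'   metric is flat (all-zero epoch).
#' @export
estimateVelocity <- function(epoch, grid, fs, preWindow = 0,
                             blankWindows = list(), searchWindow = NULL,
                             autoBlank = FALSE, removeCommonMode = FALSE) {
  epoch <- .asElectrodeMatrix(epoch)
  if (abs(grid@fs - fs) > 1e-6)
    stop("grid was built for fs = ", grid@fs, " Hz, epoch is ", fs, " Hz")
  if (autoBlank)
    blankWindows <- c(blankWindows,
                      artifactWindows(epoch, fs, preWindow))
  if (removeCommonMode && nrow(epoch) > 1L)
    epoch <- sweep(epoch, 2L, colMeans(epoch))
  epoch <- .blankEpoch(epoch, fs, preWindow, blankWindows)
  n <- ncol(epoch)
  tRel <- (seq_len(n) - 1) / fs - preWindow
  if (is.null(searchWindow)) searchWindow <- c(0, max(tRel) + 1 / fs)
  i0 <- which(tRel >= searchWindow[1])[1]
  i1 <- max(which(tRel < searchWindow[2]))
  if (is.na(i0) || i1 < i0) stop("empty search window")
  usable <- abs(grid@shifts) * (nrow(epoch) - 1L) < n
  shifts <- grid@shifts[usable]
  metric <- .dsPeakMetric(epoch, shifts, i0 - 1L, i1)
  if (max(metric) <= 0)
    return(new("VelocityEstimate", velocity = NA_real_, direction = "none",
               delta = NA_real_, peakMetric = 0, sStar = NA_integer_,
               ok = FALSE))
  best <- max(metric)
  cand <- which(metric >= best - 1e-12)
  sStar <- shifts[cand][which.min(abs(shifts[cand]))]
  new("VelocityEstimate",
      velocity = .vOfShift(grid, sStar),
      direction = if (sStar > 0) "forward" else "backward",
      delta = .deltaAt(grid, abs(sStar)),
      peakMetric = best, sStar = as.integer(sStar), ok = TRUE)
}

#' Success rate of velocity calculation across repetitions
#'
#' The reference velocity is estimated on the pointwise mean of the
#' repetition epochs; the success rate is the proportion of per-repetition
#' velocity estimates falling within `[vReference - delta, vReference +
#' delta]`, with `delta` the grid tolerance at the reference velocity.
#'
#' @param epochs list of electrodes x samples matrices (>= 2 time-locked
#'   repetitions), or a [Recording-class].
#' @inheritParams estimateVelocity
#' @return an [SRResult-class]; `ok = FALSE` (undefined SR) when the mean
#'   epoch yields no estimate.
#' @export
successRate <- function(epochs, grid, fs, preWindow = 0,
                        blankWindows = list(), searchWindow = NULL,
                        autoBlank = FALSE, removeCommonMode = FALSE) {
  if (is(epochs, "Recording")) {
    rec <- epochs
    fs <- rec@fs
    preWindow <- rec@preWindow
    epochs <- lapply(seq_len(nEpochs(rec)), function(i) epochMatrix(rec, i))
  }
  nRep <- length(epochs)
  if (nRep < 2L) stop("need >= 2 repetitions to compute a success rate")
  meanEp <- Reduce(`+`, epochs) / nRep
  ref <- estimateVelocity(meanEp, grid, fs, preWindow, blankWindows,
                          searchWindow, autoBlank, removeCommonMode)
  if (!ref@ok)
    return(new("SRResult", successRate = NA_real_, nSuccess = NA_integer_,
               nRepetitions = as.integer(nRep), vReference = NA_real_,
               delta = NA_real_, perRepetitionVelocities = rep(NA_real_, nRep),
               ok = FALSE))
  vRep <- vapply(epochs, function(ep)
    estimateVelocity(ep, grid, fs, preWindow, blankWindows,
                     searchWindow, autoBlank, removeCommonMode)@velocity, 0)
  delta <- ref@delta
  nSucc <- sum(!is.na(vRep) &
                 abs(vRep - ref@velocity) <= delta + 1e-9)
  new("SRResult", successRate = nSucc / nRep, nSuccess = as.integer(nSucc),
      nRepetitions = as.integer(nRep), vReference = ref@velocity,
      delta = delta, perRepetitionVelocities = vRep, ok = TRUE)
}

#' Epoch discard rules
#'
#' An epoch is discarded when its estimated velocity exceeds `vMax`
#' (60 m/s in the study) or when more than one spike per electrode was
#' detected in the epoch (multi-unit contamination).
#'
#' @param metrics a [SpikeMetrics-class] (may be `NULL`).
#' @param estimate a [VelocityEstimate-class].
#' @param events data.frame from [detectSpikes()] for the epoch.
#' @param vMax velocity cut-off, m/s.
#' @return list with `keep` (logical) and `reason` (character; "" when kept).
#' @examples
#' \dontrun{discardFilter(metrics, est, events)}
#' @export
discardFilter <- function(metrics, estimate, events, vMax = 60) {
  if (estimate@ok && !is.na(estimate@velocity) && estimate@velocity > vMax)
    return(list(keep = FALSE, reason = "velocity>60"))
  if (!is.null(events) && nrow(events) > 0L) {
    perElectrode <- table(events$electrode)
    if (any(perElectrode > 1L))
      return(list(keep = FALSE, reason = "multiple spikes"))
  }
  list(keep = TRUE, reason = "")
}

#' Success-rate dataset from a simulated sweep
#'
#' Runs the full VSR chain on every recording of a sweep: per recording the
#' mean-epoch reference velocity and the per-repetition success rate, joined
#' with the generation parameters, giving the rows the SR response-surface
#' model is fitted to.
#'
#' @param rs a [RecordingSet-class] from [simulateSrSweep()].
#' @param vMin,vMax velocity grid bounds for the analysis, m/s.
#' @param fsOut analysis sampling rate (recordings below it are up-sampled).
#' @return data.frame with columns nElectrodes, pitch, width, velocity,
#'   snrDb, sr, vReference, delta, channelLength, source.
#' @export
srDataset <- function(rs, vMin = 1, vMax = 60, fsOut = 5e5) {
  rows <- vector("list", length(rs@recordings))
  for (i in seq_along(rs@recordings)) {
    rec <- preprocessRecording(rs@recordings[[i]], fsOut = fsOut)
    grid <- velocityGrid(rec@design@pitch, rec@fs, vMin, vMax)
    sr <- successRate(rec, grid)
    m <- rs@manifest[i, ]
    rows[[i]] <- data.frame(
      nElectrodes = m$nElectrodes, pitch = m$pitch, width = m$width,
      velocity = m$velocity, snrDb = m$snrDb,
      sr = sr@successRate, vReference = sr@vReference, delta = sr@delta,
      channelLength = m$channelLength, source = "simulated")
  }
  do.call(rbind, rows)
}
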