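test_that("amplification profile peaks at two-thirds of the channel", {
  expect_equal(amplificationProfile(2 / 3), 1)
  expect_equal(amplificationProfile(0), 0)
  expect_equal(amplificationProfile(1), 0)
  # brute-force grid argmax of the default closed form
  u <- seq(0, 1, by = 0.01)
  expect_equal(u[which.max(amplificationProfile(u))], 0.67,
               tolerance = 0.011)
  expect_error(amplificationProfile(-0.1), "0, 1")
  expect_error(amplificationProfile(1.1), "0, 1")
  # asymmetric about the maximum
  g <- amplificationProfile(2 / 3 + c(-0.2, 0.2))
  expect_false(isTRUE(all.equal(g[1], g[2])))
})

test_that("channel gain scale increases with microchannel length", {
  expect_gt(channelGainScale(10), channelGainScale(4))
  expect_equal(channelGainScale(7), 7 / 10)  # linear default, L/L_ref
  s <- channelGainScale(c(4, 5, 6, 10))
  expect_true(all(diff(s) > 0))
  cal <- data.frame(length = c(4, 10), gain = c(0.3, 1))
  expect_error(channelGainScale(12, calibration = cal), "extrapolation")
  expect_equal(channelGainScale(12, calibration = cal, extrapolate = TRUE), 1)
  expect_equal(channelGainScale(10, calibration = function(L) L^2), 100)
})

test_that("SFAP template honours width, amplitude and zero mean", {
  w <- sfapTemplate(width = 0.22, amplitude = 55, fs = 5e5)
  expect_equal(max(w), 55)
  # full width at half amplitude of the main lobe, via linear interpolation
  measureFwhm <- function(w, fs) {
    x <- as.numeric(w); pk <- which.max(x); half <- x[pk] / 2
    iL <- pk; while (x[iL - 1] > half) iL <- iL - 1
    iR <- pk; while (x[iR + 1] > half) iR <- iR + 1
    fl <- (x[iL] - half) / (x[iL] - x[iL - 1])
    fr <- (x[iR] - half) / (x[iR] - x[iR + 1])
    ((iR + fr) - (iL - fl)) / fs * 1e3
  }
  expect_equal(measureFwhm(w, 5e5), 0.22, tolerance = 0.002 / 0.22)
  # zero-mean (AC-coupled-like): normalized time integral below 5%
  expect_lt(abs(sum(w) / 5e5) / (55 * 0.22e-3), 0.05)
  expect_equal(max(abs(sfapTemplate(0.22, 0, 5e5))), 0)
  expect_error(sfapTemplate(0.03, 55, 5e4), "undersampled")
})

test_that("simulated fibers propagate with delay pitch/velocity", {
  d <- standardDesign()
  rec <- simulateRecording(d, FiberSpec(10, 55, 0.22),
                           StimulusProtocol(repetitions = 1),
                           fs = 5e5, seed = 1, onsetFraction = 0)
  ep <- epochMatrix(rec, 1)
  peaks <- apply(ep[, epochTime(rec) > 3e-4], 1, which.max)
  lags <- diff(peaks) / 5e5
  expect_true(all(abs(lags - 1e-3 / 10) <= 1 / 5e5 + 1e-12))
  # affine arrival times: slope of peak time vs electrode index = pitch/v
  fit <- lm(peaks / 5e5 ~ seq_len(8))
  expect_equal(unname(coef(fit)[2]), 1e-3 / 10, tolerance = 1e-2)
})

test_that("stimulation artifact is simultaneous on all electrodes", {
  rec <- simulateRecording(standardDesign(), fig2cFiber(),
                           StimulusProtocol(repetitions = 1), seed = 1)
  ep <- epochMatrix(rec, 1)
  art <- ep[, epochTime(rec) >= 0 & epochTime(rec) < 1e-4, drop = FALSE]
  peakIdx <- apply(abs(art), 1, which.max)
  expect_equal(diff(range(peakIdx)), 0)
  # near-identical waveform on every electrode within the artifact window
  # (only the far tails of the propagating wave differ, well below 1 uV)
  expect_lt(max(apply(art, 2, function(col) diff(range(col)))), 1)
})

test_that("noiseless electrode amplitudes follow the amplification profile", {
  d <- MicrochannelDesign(12, 2, 6,
                          electrodePositions = c(12 / 6, 2 * 12 / 3))
  rec <- simulateRecording(d, FiberSpec(10, 50, 0.2),
                           StimulusProtocol(repetitions = 1),
                           fs = 5e5, seed = 1, onsetFraction = 0)
  rec <- preprocessRecording(rec, fsOut = NULL, filter = FALSE)
  ep <- epochMatrix(rec, 1)
  amps <- apply(abs(ep[, epochTime(rec) > 3e-4]), 1, max)
  expect_equal(amps[2] / amps[1],
               amplificationProfile(2 / 3) / amplificationProfile(1 / 6),
               tolerance = 1e-6)
})

test_that("identical seeds reproduce identical recordings", {
  args <- list(standardDesign(), fig2cFiber(),
               StimulusProtocol(repetitions = 3), noiseSnrDb = 20, seed = 7)
  r1 <- do.call(simulateRecording, args)
  r2 <- do.call(simulateRecording, args)
  expect_identical(r1@traces, r2@traces)
  r3 <- do.call(simulateRecording, utils::modifyList(args, list(seed = 8)))
  expect_false(identical(r1@traces, r3@traces))
})

test_that("requested SNR is realized on the best electrode", {
  d <- standardDesign()
  measured <- vapply(1:100, function(i) {
    rec <- simulateRecording(d, fig2cFiber(),
                             StimulusProtocol(repetitions = 1),
                             noiseSnrDb = 25, seed = 9000 + i)
    ep <- epochMatrix(rec, 1)
    ev <- detectSpikes(ep, rec@fs, rec@preWindow,
                       blankWindows = list(c(-1e-4, 7e-4)))
    m <- measureSpike(ep, rec@fs, rec@preWindow, ev)
    m@snrDb
  }, 0)
  expect_lt(abs(mean(measured) - 25), 1)
})

test_that("fiber arrivals beyond the epoch raise an error", {
  expect_error(
    simulateRecording(standardDesign(), FiberSpec(1, 30, 0.2),
                      StimulusProtocol(repetitions = 1),
                      epochDuration = 0.005, seed = 1),
    "beyond trace end")
  expect_warning(
    simulateRecording(standardDesign(), fig2cFiber(),
                      StimulusProtocol(repetitions = 1),
                      noiseSnrDb = -3, seed = 1),
    "negative requested SNR")
})

test_that("SR sweeps emit one recording per design and grid point", {
  designs <- lapply(seq(4, 8.5, by = 0.5),
                    function(L) MicrochannelDesign(L, 3, 1))
  expect_length(designs, 10L)
  rs <- simulateSrSweep(designs, widths = c(0.25, 0.3),
                        velocities = c(20, 30, 40, 50, 60),
                        snrDbs = c(10, 20, 30),
                        nRepetitions = 2, fs = 5e4, seed = 3)
  expect_length(rs@recordings, 10L * 30L)
  expect_equal(nrow(rs@manifest), 300L)
  expect_warning(
    simulateSrSweep(designs[1], widths = 0.3, velocities = 30, snrDbs = 20,
                    nRepetitions = 1, fs = 5e4, seed = 3),
    "degenerate")
  rs2 <- simulateSrSweep(designs[1:2], widths = 0.3, velocities = c(30, 50),
                         snrDbs = 20, nRepetitions = 2, fs = 5e4, seed = 5)
  rs3 <- simulateSrSweep(designs[1:2], widths = 0.3, velocities = c(30, 50),
                         snrDbs = 20, nRepetitions = 2, fs = 5e4, seed = 5)
  expect_identical(serialize(rs2, NULL), serialize(rs3, NULL))
})

test_that("zero opto-thermal coupling reproduces the no-light session", {
  d <- standardDesign()
  fibers <- list(FiberSpec(12, 45, 0.2), FiberSpec(2, 18, 0.45))
  stim <- StimulusProtocol(repetitions = 12, period = 3)
  ill <- IlluminationProtocol(pulseOnsets = 9, pulseDuration = 15)
  recNull <- simulateInhibitionSession(d, fibers, stim, ill,
                                       coupling = nullCoupling(),
                                       noiseSnrDb = 25, seed = 5)
  recDark <- simulateRecording(d, fibers, stim, noiseSnrDb = 25, fs = 25000,
                               seed = 5)
  expect_equal(recNull@traces, recDark@traces)
  expect_error(
    simulateInhibitionSession(d, list(FiberSpec(12, 45, 0.2)), stim, ill),
    "slow")
})

test_that("slow fibers are blocked downstream at steady illumination", {
  d <- standardDesign()
  fibers <- list(FiberSpec(12, 45, 0.2), FiberSpec(2, 18, 0.45))
  # pulse late in a long light pulse = steady state
  stim <- StimulusProtocol(pulseTimes = c(0, 3, 44))
  ill <- IlluminationProtocol(pulseOnsets = 5, pulseDuration = 45)
  rec <- simulateInhibitionSession(d, fibers, stim, ill, noiseSnrDb = NULL,
                                   seed = 6)
  gt <- groundTruth(rec)[[3]]
  expect_true(gt$blocked[gt$class == "slow"])
  # downstream electrode (E8): slow contribution absent, fast present
  tRel <- epochTime(rec)
  ep <- epochMatrix(rec, 3)
  zs <- electrodePositions(d)[8]
  tFast <- (stimToEntrance(d) + zs) * 1e-3 / gt$vEff[gt$class == "fast"]
  tSlow <- (stimToEntrance(d) + zs) * 1e-3 / gt$vEff[gt$class == "slow"]
  winAmp <- function(t0) max(abs(ep[8, abs(tRel - t0) < 3e-4]))
  expect_gt(winAmp(tFast), 1)
  expect_lt(winAmp(tSlow), 0.05)
  expect_lt(winAmp(tSlow), winAmp(tFast) / 100)
  # reversibility: ground-truth scales return to 1 after > 5 tau of cooling
  stim2 <- StimulusProtocol(pulseTimes = c(0, 21, 90))
  ill2 <- IlluminationProtocol(pulseOnsets = 5, pulseDuration = 15)
  rec2 <- simulateInhibitionSession(d, fibers, stim2, ill2,
                                    noiseSnrDb = NULL, seed = 6)
  gtLate <- groundTruth(rec2)[[3]]
  expect_equal(gtLate$scaleBest, c(1, 1), tolerance = 0.02)
  expect_false(any(gtLate$blocked))
})
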