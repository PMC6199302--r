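test_that("thermal response follows first-order charging and discharging", {
  ill <- IlluminationProtocol(pulseOnsets = 0, pulseDuration = 15,
                              deltaTMax = 10, tauPolymer = 3.22)
  tt <- thermalResponse(ill, c(0, 3.22, 15, 15 + 3.22))
  expect_equal(tt@deltaT[1], 0)
  expect_equal(tt@deltaT[2], 10 * (1 - exp(-1)))
  peak <- 10 * (1 - exp(-15 / 3.22))
  expect_equal(tt@deltaT[3], peak)
  expect_equal(tt@deltaT[4], peak * exp(-1))
  # round-trip: refitting a noiseless pulse recovers tau to 3 decimals
  tFit <- seq(0, 15, by = 0.1)
  dT <- thermalResponse(ill, tFit)@deltaT
  fit <- minpack.lm::nlsLM(dT ~ A * (1 - exp(-tFit / tau)),
                           start = list(A = 8, tau = 2))
  expect_equal(unname(coef(fit)["tau"]), 3.22, tolerance = 1e-3 / 3.22)
})

test_that("integration windows split at distance over 5 m/s", {
  d <- MicrochannelDesign(10, 2, 4, electrodePositions = c(2, 6),
                          stimToEntrance = 8)
  w <- integrationWindows(d, 1, epochEnd = 0.02)   # d = 10 mm
  expect_equal(w$boundary, 0.002)
  expect_equal(w$fast[2], 0.002)
  expect_equal(w$slow, c(0.002, 0.02))
  # arrivals fall in the expected windows
  arr12 <- 10e-3 / 12; arr2 <- 10e-3 / 2
  expect_true(arr12 >= w$fast[1] && arr12 < w$fast[2])
  expect_true(arr2 >= w$slow[1] && arr2 < w$slow[2])
  expect_warning(integrationWindows(d, 1, epochEnd = 0.001), "empty")
})

test_that("signal density integrates the rectified trace", {
  fs <- 50000
  expect_equal(signalDensity(rep(0, 1000), fs, c(0, 0.02)), 0)
  x <- rnorm(1000)
  d1 <- signalDensity(x, fs, c(0, 0.02))
  expect_equal(signalDensity(0.5 * x, fs, c(0, 0.02)), 0.5 * d1)
  expect_warning(signalDensity(x, fs, c(1, 2)), "empty")
  # single template: density matches independent quadrature of |ricker|
  tpl <- sfapTemplate(0.2, 40, fs)
  sigma <- attr(tpl, "sigma")
  oracle <- stats::integrate(function(t)
    abs(40 * (1 - (t / sigma)^2) * exp(-(t / sigma)^2 / 2)),
    -8 * sigma, 8 * sigma, subdivisions = 2000)$value
  dens <- signalDensity(as.numeric(tpl), fs, c(-1, 1))
  expect_lt(abs(dens - oracle) / oracle, 0.1)
  # squared-signal alternative is positive and differs from |x|
  expect_gt(signalDensity(x, fs, c(0, 0.02), integrand = "square"), 0)
})

test_that("NSD is normalized to the control pulses exactly", {
  fx <- testInhibitionSession()
  nsd <- fx$nsd
  ctrl <- nsd[nsd$pulseIndex <= 10, ]
  for (e in unique(ctrl$electrode)) for (cl in c("fast", "slow")) {
    m <- mean(ctrl$nsd[ctrl$electrode == e & ctrl$class == cl])
    expect_equal(m, 1, tolerance = 1e-12)
  }
  expect_true(all(nsd$nsd >= 0, na.rm = TRUE))
  expect_false(any(nsd$lightOn[nsd$pulseIndex <= 10]))
})

test_that("illumination inhibits slow fibers more than fast fibers", {
  fx <- testInhibitionSession()
  nsd <- fx$nsd
  on <- nsd[nsd$lightOn, ]
  for (e in unique(on$electrode)) {
    expect_lt(min(on$nsd[on$electrode == e & on$class == "slow"]),
              min(on$nsd[on$electrode == e & on$class == "fast"]))
  }
  # end of light cycle: fast NSD about twice the slow NSD
  lastOn <- max(on$pulseIndex)
  ratio <- mean(on$nsd[on$pulseIndex == lastOn & on$class == "fast"]) /
    mean(on$nsd[on$pulseIndex == lastOn & on$class == "slow"])
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3.2)
  # downstream fast NSD recovers to 1 after light off
  offLate <- nsd[!nsd$lightOn & nsd$pulseIndex > 20 &
                   nsd$electrode %in% c(7, 8) & nsd$class == "fast", ]
  lastDark <- offLate[offLate$pulseIndex > max(offLate$pulseIndex) - 3, ]
  expect_lt(abs(mean(lastDark$nsd) - 1), 0.1)
  # spatial gradient: light-on suppression decreases with distance from
  # the spot among upstream electrodes (E3 closest, E1 farthest)
  supp <- vapply(1:3, function(e)
    1 - mean(on$nsd[on$electrode == e & on$class == "fast"]), 0)
  expect_true(all(diff(supp) > 0))
})

test_that("kinetics fits recover class time constants", {
  # self-consistency: noiseless synthetic NSD from the model
  tp <- seq(0.5, 14.5, by = 0.75)
  nsdSyn <- data.frame(
    session = 1L, electrode = 1L, pulseIndex = seq_along(tp), time = tp,
    class = "fast", nsd = 0.4 + 0.6 * exp(-tp / 4), lightOn = TRUE)
  nsdSyn <- rbind(nsdSyn, transform(nsdSyn, class = "slow",
                                    nsd = 0.2 + 0.8 * exp(-tp / 8)))
  illSyn <- IlluminationProtocol(pulseOnsets = 0, pulseDuration = 15)
  fit <- fitKinetics(nsdSyn, illSyn, "inhibition")
  expect_equal(fit$tau[fit$class == "fast"], 4, tolerance = 0.01)
  expect_equal(fit$tau[fit$class == "slow"], 8, tolerance = 0.01)
  expect_true(all(fit$r2 > 0.999))
  # tau recovery within 10% under 5% noise, 20 pulses per phase
  set.seed(31)
  for (tau in c(2, 5, 10, 20)) {
    illLong <- IlluminationProtocol(pulseOnsets = 0,
                                    pulseDuration = 3.2 * tau)
    t20 <- seq(0.15, 3, length.out = 20) * tau
    # 20 pulses per phase, pooled over the five analysed electrodes as in
    # a real session, 5% Gaussian noise
    d20 <- do.call(rbind, lapply(1:5, function(e) data.frame(
      session = 1L, electrode = e, pulseIndex = seq_along(t20),
      time = t20, class = "fast",
      nsd = pmax(0.3 + 0.7 * exp(-t20 / tau) + rnorm(20, 0, 0.05), 0),
      lightOn = TRUE)))
    f <- fitKinetics(d20, illLong, "inhibition", minPulses = 5)
    f <- f[f$class == "fast", ]
    expect_true(f$converged)
    expect_lt(abs(f$tau - tau) / tau, 0.1)
  }
  # full session: fast time constant about half the slow one, end-of-pulse
  # plateau about twice
  fx <- testInhibitionSession()
  kin <- fitKinetics(fx$nsd, illumination(fx$rec), "inhibition")
  ratio <- kin$tau[kin$class == "fast"] / kin$tau[kin$class == "slow"]
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.75)
  pr <- kin$plateau[kin$class == "fast"] / kin$plateau[kin$class == "slow"]
  expect_gt(pr, 1.5)
  # recovery phase fits converge too
  rec <- fitKinetics(fx$nsd, illumination(fx$rec), "recovery")
  expect_true(all(rec$converged))
})

test_that("four-way ANOVA flags illumination and class effects", {
  fx <- testInhibitionSession()
  av <- inhibitionAnova(fx$nsd)
  p <- setNames(av$omnibus$p, av$omnibus$term)
  expect_lt(p[["phase"]], 0.05)
  expect_lt(p[["phase:class"]], 0.05)
  expect_true(av$posthoc$significant[av$posthoc$class == "slow"])
  # weak fast coupling: post-hoc on fast non-significant
  weak <- utils::modifyList(couplingDefaults(),
                            list(cFast = 0.002, velocityTempCoeff = 0))
  recW <- simulateInhibitionSession(
    standardDesign(),
    list(FiberSpec(12, 45, 0.2), FiberSpec(2, 18, 0.45)),
    StimulusProtocol(repetitions = 25, period = 3),
    IlluminationProtocol(pulseOnsets = 30, pulseDuration = 15),
    coupling = weak, noiseSnrDb = 20, seed = 17)
  nsdW <- nsdSeries(recW, nControl = 10, maskElectrodes = 4:6)
  avW <- inhibitionAnova(nsdW)
  expect_false(avW$posthoc$significant[avW$posthoc$class == "fast"])
  expect_error(
    inhibitionAnova(transform(fx$nsd, lightOn = FALSE)), "single level")
})

test_that("recovery is indistinguishable across heating cycles", {
  fx <- testInhibitionSession()
  nsd <- fx$nsd
  ill <- illumination(fx$rec)
  offs <- ill@pulseOnsets + ill@pulseDuration
  # fast-fiber dark pulses 15-27 s after each light-off: the same window
  # length in every cycle, long after the fast time constant has decayed
  cyc <- findInterval(nsd$time, offs)
  since <- nsd$time - offs[pmax(cyc, 1)]
  late <- !nsd$lightOn & cyc >= 1 & since > 15 & since < 27 &
    nsd$class == "fast"
  d <- nsd[late & !is.na(nsd$nsd), ]
  d$cycle <- factor(findInterval(d$time, offs))
  expect_equal(nlevels(d$cycle), 3L)
  a <- anova(lm(nsd ~ cycle, data = d))
  expect_gt(a[["Pr(>F)"]][1], 0.05)
})

test_that("SNR comparison across channel lengths uses Kruskal-Wallis", {
  # identical rank distributions: omnibus p near 1
  same <- rep(1:10, 3)
  g <- rep(c("4", "6", "10"), each = 10)
  res <- snrLengthComparison(same, g)
  expect_gt(res$omnibus$p, 0.99)
  # Bonferroni per-test threshold for 6 pairwise tests
  snr4 <- rnorm(22, 12, 2); snr5 <- rnorm(75, 15, 2)
  snr6 <- rnorm(86, 17, 2); snr10 <- rnorm(16, 22, 2)
  set.seed(41)
  res4 <- snrLengthComparison(c(snr4, snr5, snr6, snr10),
                              rep(c("L04", "L05", "L06", "L10"),
                                  c(22, 75, 86, 16)))
  expect_equal(res4$perTestAlpha, 0.05 / 6)
  expect_equal(nrow(res4$pairwise), 6L)
  # simulated SNR groups for 4 vs 10 mm differ significantly
  snrOf <- function(L, i) {
    d <- MicrochannelDesign(L, 3, 1)
    rec <- simulateRecording(d, FiberSpec(20, 50, 0.2),
                             StimulusProtocol(repetitions = 1),
                             noiseSnrDb = NULL, fs = 5e4, seed = 50 + i)
    ep <- epochMatrix(rec, 1)
    set.seed(500 + i)
    ep <- ep + matrix(rnorm(length(ep), 0, 1.5), nrow(ep))
    ev <- detectSpikes(ep, rec@fs, rec@preWindow,
                       blankWindows = list(c(-1e-4, 6e-4)))
    measureSpike(ep, rec@fs, rec@preWindow, ev)@snrDb
  }
  g4 <- vapply(1:8, snrOf, 0, L = 4)
  g10 <- vapply(9:16, snrOf, 0, L = 10)
  cmp <- snrLengthComparison(c(g4, g10), rep(c("4", "10"), each = 8))
  expect_lt(cmp$pairwise$pAdjusted[1], 0.05)
  expect_warning(
    snrLengthComparison(c(1, 2, 3, 4, 5, 6, 7),
                        c("a", "a", "a", "b", "b", "b", "c")),
    "excluding")
})
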