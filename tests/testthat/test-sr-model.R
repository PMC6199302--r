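# helper: synthesize an SR dataset from known coefficients over realistic
# factor ranges (no simulator involved)
srGridData <- function(coefs = c(`(Intercept)` = 0.7, nElectrodes = 0.015,
                                 pitch = 0.04, width = -0.2,
                                 expInvV = -0.4, snrDb = 0.008),
                       noiseSd = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(nElectrodes = c(3, 5, 8), pitch = c(0.67, 1, 1.33),
                      width = c(0.05, 0.15, 0.3),
                      velocity = c(5, 13.3, 30, 50), snrDb = c(5, 15, 30))
  X <- buildDesignMatrix(grid)
  grid$sr <- pmin(pmax(as.numeric(X %*% coefs) +
                         rnorm(nrow(grid), 0, noiseSd), 0), 1)
  grid
}

test_that("design matrix applies the exp(1/v) velocity transform", {
  df <- data.frame(nElectrodes = 8, pitch = 1, width = 0.22,
                   velocity = c(1, 1e9, 13.3), snrDb = 30)
  X <- buildDesignMatrix(df)
  expect_equal(colnames(X), c("(Intercept)", "nElectrodes", "pitch",
                              "width", "expInvV", "snrDb"))
  expect_equal(unname(X[1, "expInvV"]), exp(1))
  expect_equal(unname(X[2, "expInvV"]), 1, tolerance = 1e-8)
  expect_equal(unname(X[3, "expInvV"]), 1.0781, tolerance = 1e-4)
  expect_error(buildDesignMatrix(transform(df, velocity = 0)), "velocity")
  expect_error(buildDesignMatrix(df[, -1]), "lacks columns")
})

test_that("OLS recovers exact linear SR data to machine precision", {
  coefs <- c(`(Intercept)` = 0.7, nElectrodes = 0.015, pitch = 0.04,
             width = -0.2, expInvV = -0.4, snrDb = 0.008)
  ds <- srGridData(coefs, noiseSd = 0)
  m <- suppressWarnings(fitSrModel(ds))  # zero-residual fit
  expect_equal(m@coefficients, coefs, tolerance = 1e-10)
  expect_equal(m@r2, 1, tolerance = 1e-10)
  # rank deficiency is reported with the offending terms
  bad <- ds; bad$pitch <- 1
  expect_error(fitSrModel(bad), "collinear")
})

test_that("standardized half effects scale with factor ranges", {
  ds <- srGridData(noiseSd = 0.03)
  m <- fitSrModel(ds)
  he <- standardizedHalfEffects(m)
  expect_equal(he$halfEffect,
               unname(m@coefficients[he$term] *
                        (m@ranges["max", he$term] -
                           m@ranges["min", he$term]) / 2))
  expect_true(all(he$lo <= he$halfEffect & he$halfEffect <= he$hi))
  expect_equal(he$significant, he$pValue < 0.05)
  # zero coefficient gives a zero half effect
  coefs0 <- c(`(Intercept)` = 0.7, nElectrodes = 0, pitch = 0.04,
              width = -0.2, expInvV = -0.4, snrDb = 0.008)
  he0 <- standardizedHalfEffects(suppressWarnings(fitSrModel(srGridData(coefs0))))
  expect_equal(he0$halfEffect[he0$term == "nElectrodes"], 0,
               tolerance = 1e-10)
  # doubling a factor's range doubles its half effect
  coefs <- c(`(Intercept)` = 0.7, nElectrodes = 0.01, pitch = 0.04,
             width = -0.2, expInvV = -0.4, snrDb = 0.004)
  ds1 <- srGridData(coefs, noiseSd = 0)
  ds2 <- ds1
  ds2$snrDb <- (ds2$snrDb - min(ds2$snrDb)) * 2 + min(ds2$snrDb)
  ds2$sr <- pmin(pmax(as.numeric(buildDesignMatrix(ds2) %*% coefs), 0), 1)
  he1 <- standardizedHalfEffects(suppressWarnings(fitSrModel(ds1)))
  he2 <- standardizedHalfEffects(suppressWarnings(fitSrModel(ds2)))
  expect_equal(he2$halfEffect[he2$term == "snrDb"],
               2 * he1$halfEffect[he1$term == "snrDb"], tolerance = 1e-8)
})

test_that("predictions are clipped to [0, 1] and match the mean at center", {
  ds <- srGridData(noiseSd = 0.05, seed = 3)
  m <- fitSrModel(ds)
  # OLS property: prediction at the dataset mean equals the mean response
  expect_equal(
    unname(predictSr(m, mean(ds$nElectrodes), mean(ds$pitch),
                     mean(ds$width), 1 / log(mean(exp(1 / ds$velocity))),
                     mean(ds$snrDb))),
    mean(ds$sr), tolerance = 1e-6)
  # monotone increasing in SNR (positive coefficient)
  p <- predictSr(m, 8, 1, 0.03, 30, c(0, 10, 20, 30, 40),
                 warnExtrapolation = FALSE)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p <= 1))
  # width = 0.03 ms inputs are accepted
  expect_silent(predictSr(m, 8, 1, 0.03, 20, 20,
                          warnExtrapolation = FALSE))
  expect_warning(predictSr(m, 8, 1, 5, 20, 20), "outside")
  # clipping: extreme inputs never leave [0, 1]
  pExt <- predictSr(m, 8, 1, 0.03, 60, c(-100, 200),
                    warnExtrapolation = FALSE)
  expect_true(all(pExt >= 0 & pExt <= 1))
})

test_that("safe region reports minimal averaging requirements", {
  ds <- srGridData(noiseSd = 0)
  m <- suppressWarnings(fitSrModel(ds))
  sr <- safeRegion(m, snrDb = c(0, 10, 25, 40), velocity = c(10, 35),
                   channelLength = c(4, 10))
  expect_true(all(sr$nAverages[sr$safe] == 1))
  # requirement is non-increasing in SNR for fixed velocity and length
  for (v in unique(sr$velocity)) for (L in unique(sr$channelLength)) {
    sub <- sr[sr$velocity == v & sr$channelLength == L, ]
    sub <- sub[order(sub$snrDb), ]
    expect_true(all(diff(sub$nAverages) <= 0))
  }
  # shorter channel (lower attainable SNR) needs at least as much averaging
  s4 <- sr[sr$channelLength == 4, "nAverages"]
  s10 <- sr[sr$channelLength == 10, "nAverages"]
  expect_true(all(s4 >= s10))
  # heavy averaging needed at a low-SNR, 35 m/s operating point
  expect_gte(sr$nAverages[sr$snrDb == 0 & sr$velocity == 35 &
                            sr$channelLength == 4], 50)
  # non-positive SNR coefficient: threshold unreachable, flagged
  coefsNeg <- c(`(Intercept)` = 0.3, nElectrodes = 0.02, pitch = 0.05,
                width = -0.3, expInvV = -0.5, snrDb = -0.001)
  mNeg <- suppressWarnings(fitSrModel(srGridData(coefsNeg)))
  srNeg <- safeRegion(mNeg, snrDb = 0, velocity = 35, channelLength = 4)
  expect_true(srNeg$unreachable)
})

test_that("permuted responses yield uniform term p-values", {
  ds <- srGridData(noiseSd = 0.05, seed = 5)
  terms <- c("nElectrodes", "pitch", "width", "expInvV", "snrDb")
  set.seed(6)
  ps <- t(replicate(500, {
    dsp <- ds
    dsp$sr <- sample(dsp$sr)
    fitSrModel(dsp)@termPvalues[terms]
  }))
  for (tm in terms)
    expect_gt(ks.test(ps[, tm], "punif")$p.value, 0.01)
})

test_that("simulated sweep flags the waveform terms that drive the SR", {
  ds <- testSweepDataset()
  m <- fitSrModel(ds)
  # SNR dominates, and the temporal-resolution term (width) is significant;
  # with the grid tolerance delta scaling as v^2, the velocity error the
  # noise induces and the tolerance grow together, so exp(1/v) carries
  # little signal under these fixed-SNR conditions
  expect_lt(m@termPvalues["snrDb"], 0.05)
  expect_lt(m@termPvalues["width"], 0.05)
  he <- standardizedHalfEffects(m)
  eff <- setNames(abs(he$halfEffect), he$term)
  expect_gt(eff["snrDb"], max(eff[c("nElectrodes", "pitch", "expInvV")]))
})

test_that("out-of-sample R2 stays close to in-sample (no overfit)", {
  ds <- testSweepDataset()
  m <- fitSrModel(ds)
  set.seed(8)
  fold <- sample(rep(1:5, length.out = nrow(ds)))
  press <- 0
  for (k in 1:5) {
    mk <- fitSrModel(ds[fold != k, ])
    pk <- predictSr(mk, ds$nElectrodes[fold == k], ds$pitch[fold == k],
                    ds$width[fold == k], ds$velocity[fold == k],
                    ds$snrDb[fold == k], warnExtrapolation = FALSE)
    press <- press + sum((ds$sr[fold == k] - pk)^2)
  }
  r2cv <- 1 - press / sum((ds$sr - mean(ds$sr))^2)
  expect_lt(m@r2 - r2cv, 0.1)
})
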