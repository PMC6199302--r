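# Linear response-surface model of the VSR success rate against channel
# geometry (N_E, pitch) and waveform features (width, exp(1/v), SNR).

.srTerms <- c("nElectrodes", "pitch", "width", "expInvV", "snrDb")

#' Design matrix of the SR linear model
#'
#' Columns `[1, N_E, pitch, width, exp(1/v), SNR]` with the velocity entering
#' through the exponential transform exp(1/v) (v in m/s), which captures the
#' sharp loss of grid resolution at high velocity.
#'
#' @param dataset data.frame with columns nElectrodes, pitch, width,
#'   velocity, snrDb (and, for fitting, sr).
#' @return numeric matrix with named columns.
#' @examples
#' buildDesignMatrix(data.frame(nElectrodes = 8, pitch = 1, width = 0.22,
#'                              velocity = 13.3, snrDb = 30))
#' @export
buildDesignMatrix <- function(dataset) {
  need <- c("nElectrodes", "pitch", "width", "velocity", "snrDb")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  if (any(dataset$velocity == 0)) stop("velocity must be non-zero")
  X <- cbind(`(Intercept)` = 1,
             nElectrodes = dataset$nElectrodes,
             pitch = dataset$pitch,
             width = dataset$width,
             expInvV = exp(1 / dataset$velocity),
             snrDb = dataset$snrDb)
  X
}

#' Fit the SR linear model by ordinary least squares
#'
#' SR is regressed, untransformed, on the six-term design matrix (predictions
#' are clipped to `[0, 1]` at predict time). Per-term significance uses
#' type-II ANOVA F-tests. Observed factor ranges are stored with the model
#' for the standardized-half-effect coding. Fits from simulated and
#' experimental-like data are kept as separate model objects via `source`.
#'
#' @param dataset data.frame with the model columns plus `sr` in `[0, 1]`;
#'   needs more rows than model terms.
#' @param source data-source label stored with the model.
#' @param logitResponse fit on the logit of SR (clamped away from 0/1)
#'   instead of raw SR.
#' @return an [SRLinearModel-class].
#' @export
fitSrModel <- function(dataset, source = "simulated", logitResponse = FALSE) {
  dataset <- dataset[complete.cases(dataset[, c(.srTerms[-4], "velocity",
                                                "sr")]), ]
  if (any(dataset$sr < 0 | dataset$sr > 1)) stop("sr must lie in [0, 1]")
  if (nrow(dataset) < 7L)
    stop("need at least ", 7, " rows to fit 6 coefficients")
  df <- data.frame(
    sr = dataset$sr,
    nElectrodes = dataset$nElectrodes,
    pitch = dataset$pitch,
    width = dataset$width,
    expInvV = exp(1 / dataset$velocity),
    snrDb = dataset$snrDb)
  if (logitResponse) {
    p <- pmin(pmax(df$sr, 0.01), 0.99)
    df$sr <- log(p / (1 - p))
  }
  fit <- lm(sr ~ nElectrodes + pitch + width + expInvV + snrDb, data = df)
  qrRank <- fit$qr$rank
  if (qrRank < 6L) {
    ali <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design matrix; collinear terms: ",
         paste(ali, collapse = ", "))
  }
  sm <- summary(fit)
  pv <- tryCatch({
    an <- Anova(fit, type = 2)
    setNames(an[["Pr(>F)"]][seq_along(.srTerms)],
             rownames(an)[seq_along(.srTerms)])
  }, error = function(e) {
    # perfect (zero-residual) fits have no F distribution to test against
    setNames(rep(NA_real_, length(.srTerms)), .srTerms)
  })
  rng <- sapply(.srTerms, function(tm) range(df[[tm]]))
  rownames(rng) <- c("min", "max")
  new("SRLinearModel", fit = fit,
      coefficients = coef(fit),
      se = sm$coefficients[, "Std. Error"],
      termPvalues = pv,
      r2 = sm$r.squared,
      residualDf = fit$df.residual,
      ranges = rng, source = source)
}

#' Standardized half effects of the SR model terms
#'
#' With factors coded to `[-1, 1]` over their observed ranges, the half
#' effect of term j is `a_j * range_j / 2`: the SR change when the factor
#' moves from the midpoint of its range to an extreme. Confidence intervals
#' are per-coefficient t-intervals scaled the same way; significance is the
#' type-II ANOVA F-test at `alpha`.
#'
#' @param model an [SRLinearModel-class].
#' @param level confidence level for the intervals.
#' @param alpha significance threshold.
#' @return data.frame with term, halfEffect, lo, hi, pValue, significant; a
#'   zero-range factor yields a zero half effect and is flagged.
#' @export
standardizedHalfEffects <- function(model, level = 0.95, alpha = 0.05) {
  terms <- .srTerms
  halfRange <- (model@ranges["max", terms] - model@ranges["min", terms]) / 2
  est <- model@coefficients[terms] * halfRange
  tq <- qt(1 - (1 - level) / 2, model@residualDf)
  se <- model@se[terms] * halfRange
  data.frame(
    term = terms,
    halfEffect = unname(est),
    lo = unname(est - tq * se),
    hi = unname(est + tq * se),
    pValue = unname(model@termPvalues[terms]),
    significant = unname(model@termPvalues[terms] < alpha),
    zeroRange = unname(halfRange == 0),
    row.names = NULL)
}

#' Predict the success rate from the fitted model
#'
#' Linear prediction clipped to `[0, 1]`. A warning is emitted when an input
#' lies outside the factor ranges the model was fitted on (extrapolation).
#'
#' @param model an [SRLinearModel-class].
#' @param nElectrodes,pitch,width,velocity,snrDb predictor values (vectors
#'   recycle).
#' @param warnExtrapolation warn when predicting outside the coded ranges.
#' @return predicted SR in `[0, 1]`.
#' @export
predictSr <- function(model, nElectrodes, pitch, width, velocity, snrDb,
                      warnExtrapolation = TRUE) {
  newdata <- data.frame(nElectrodes = nElectrodes, pitch = pitch,
                        width = width, expInvV = exp(1 / velocity),
                        snrDb = snrDb)
  if (warnExtrapolation) {
    for (tm in .srTerms) {
      lo <- model@ranges["min", tm]; hi <- model@ranges["max", tm]
      span <- max(hi - lo, .Machine$double.eps)
      if (any(newdata[[tm]] < lo - 0.1 * span |
              newdata[[tm]] > hi + 0.1 * span)) {
        warning("predicting outside the fitted range of ", tm)
        break
      }
    }
  }
  pmin(pmax(predict(model@fit, newdata = newdata), 0), 1)
}

#' Safe operating region and required averaging
#'
#' Evaluates the fitted SR surface over a grid of (SNR, velocity, channel
#' length). The channel length sets the attainable SNR through the gain
#' calibration: snrEff = snrDb + 20 log10(channelGainScale(L)). Points with
#' predicted SR at or above `srThreshold` are "safe"; for the rest the
#' minimal number of coherent averages n such that the prediction at
#' `snrAfterAveraging(snrEff, n)` reaches the threshold is reported
#' (infinite, flagged, when the SNR coefficient is not positive).
#'
#' @param model an [SRLinearModel-class].
#' @param snrDb,velocity,channelLength grid vectors (single-electrode SNR in
#'   dB at the reference length, m/s, mm).
#' @param srThreshold SR defining "safe" velocity calculation.
#' @param nElectrodes,pitch,width operating point for the remaining terms.
#' @param gainCalibration,refLength passed to [channelGainScale()].
#' @param maxAverages cap on the reported averaging requirement.
#' @return data.frame over the grid with snrEff, srFit, safe, nAverages.
#' @export
safeRegion <- function(model, snrDb, velocity, channelLength,
                       srThreshold = 0.8, nElectrodes = 8, pitch = 1,
                       width = 0.22, gainCalibration = NULL, refLength = 10,
                       maxAverages = 1e6) {
  grid <- expand.grid(snrDb = snrDb, velocity = velocity,
                      channelLength = channelLength,
                      KEEP.OUT.ATTRS = FALSE)
  grid$snrEff <- grid$snrDb +
    20 * log10(channelGainScale(grid$channelLength,
                                calibration = gainCalibration,
                                refLength = refLength))
  grid$srFit <- predictSr(model, nElectrodes, pitch, width, grid$velocity,
                          grid$snrEff, warnExtrapolation = FALSE)
  aSnr <- model@coefficients["snrDb"]
  grid$safe <- grid$srFit >= srThreshold
  # unclipped linear prediction, needed to solve for the SNR deficit
  lin <- predict(model@fit, newdata = data.frame(
    nElectrodes = nElectrodes, pitch = pitch, width = width,
    expInvV = exp(1 / grid$velocity), snrDb = grid$snrEff))
  nAvg <- rep(NA_real_, nrow(grid))
  nAvg[grid$safe] <- 1
  below <- !grid$safe
  if (any(below)) {
    if (aSnr <= 0) {
      nAvg[below] <- Inf
    } else {
      deficit <- (srThreshold - lin[below]) / aSnr   # dB needed
      nAvg[below] <- pmin(ceiling(10^(deficit / 10) - 1e-9), maxAverages)
    }
  }
  grid$nAverages <- nAvg
  grid$unreachable <- is.infinite(nAvg)
  grid
}
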