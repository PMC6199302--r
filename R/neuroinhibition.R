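# Opto-thermal neuroinhibition analysis: first-order thermal model,
# velocity-thresholded integration windows, normalized signal density,
# exponential kinetics and the study's statistical tests.

#' First-order surface-temperature response to illumination
#'
#' During a light pulse the temperature rise follows
#' dT(t) = dTmax (1 - exp(-(t - tOn)/tau)); after light-off it decays
#' exponentially with the same time constant (3.22 s for the polymer film),
#' with superposition across pulses.
#'
#' @param illumination an [IlluminationProtocol-class].
#' @param times evaluation times, s.
#' @return a [TemperatureTrace-class].
#' @examples
#' ill <- IlluminationProtocol(pulseOnsets = 0)
#' tt <- thermalResponse(ill, seq(0, 15, 0.1))
#' max(tt@deltaT) / ill@deltaTMax  # approaches 1 - exp(-15/3.22)
#' @export
thermalResponse <- function(illumination, times) {
  validObject(illumination)
  dT <- illumination@deltaTMax *
    .stateFraction(times, illumination, illumination@tauPolymer)
  new("TemperatureTrace", times = times, deltaT = dT,
      illumination = illumination)
}

#' Fast/slow integration windows for one electrode
#'
#' Activity arriving before `d / vThreshold` (d = distance from the
#' stimulation cathode to the electrode) comes from fibers faster than the
#' 5 m/s class threshold; later activity comes from slow fibers. The fast
#' window starts at the end of the artifact blank and both windows are
#' clipped to the epoch.
#'
#' @param design a [MicrochannelDesign-class].
#' @param electrode electrode index (1-based from the channel entrance).
#' @param vThreshold class boundary, m/s.
#' @param epochEnd end of the usable epoch, s after the stimulus.
#' @param tBlankEnd end of the stimulation-artifact blank, s.
#' @return list with `fast` and `slow` `c(start, end)` windows (s, half-open)
#'   and `boundary`; the slow window is empty (and flagged via a warning)
#'   when the boundary lies beyond `epochEnd`.
#' @examples
#' d <- MicrochannelDesign(10, 8, 1, stimToEntrance = 8)
#' integrationWindows(d, 8, epochEnd = 0.02)$boundary  # (8 + 8.5 mm) / 5 m/s
#' @export
integrationWindows <- function(design, electrode, vThreshold = 5,
                               epochEnd, tBlankEnd = 2e-4) {
  d <- (design@stimToEntrance +
          design@electrodePositions[electrode]) * 1e-3
  boundary <- d / vThreshold
  if (boundary >= epochEnd)
    warning("fast/slow boundary (", format(boundary), " s) beyond epoch end;",
            " slow window is empty")
  list(fast = c(tBlankEnd, min(boundary, epochEnd)),
       slow = c(min(boundary, epochEnd), epochEnd),
       boundary = boundary)
}

#' Rectified signal density over a window
#'
#' Integral of the absolute value of the (band-passed) trace over the
#' half-open window: sum(|x|) / fs, in uV s. Squared-signal energy is
#' available as an alternative integrand.
#'
#' @param trace numeric vector, uV.
#' @param fs sampling rate, Hz.
#' @param window `c(start, end)`, s relative to the stimulus.
#' @param preWindow pre-stimulus baseline of the trace, s.
#' @param integrand "abs" (default) or "square".
#' @return density in uV s (or uV^2 s); an empty window returns 0 with a
#'   warning.
#' @export
signalDensity <- function(trace, fs, window, preWindow = 0,
                          integrand = c("abs", "square")) {
  integrand <- match.arg(integrand)
  tRel <- (seq_along(trace) - 1) / fs - preWindow
  keep <- tRel >= window[1] & tRel < window[2]
  if (!any(keep)) {
    warning("empty integration window")
    return(0)
  }
  v <- trace[keep]
  if (integrand == "abs") sum(abs(v)) / fs else sum(v^2) / fs
}

#' Normalized signal density per pulse, electrode and fiber class
#'
#' For each (electrode, class) the per-pulse rectified signal density is
#' normalized by the mean density over the first `nControl` (pre-light)
#' pulses, so the control-pulse mean NSD is 1 by construction. Densities are
#' computed on the band-passed epoch; the pre-stimulus rectified noise rate
#' times the window length is subtracted (clipped at zero) so the noise floor
#' does not dilute the inhibition estimate. Electrodes in `maskElectrodes`
#' (the ITO electrodes E4-E6 near the light spot in the bench layout) are
#' excluded.
#'
#' @param recording an illuminated [Recording-class].
#' @param nControl number of control pulses (must all precede the first light
#'   onset).
#' @param maskElectrodes electrode indices to exclude.
#' @param vThreshold fast/slow class boundary, m/s.
#' @param tBlankEnd end of the artifact blank, s.
#' @param epochEnd end of the usable epoch, s (default: epoch length).
#' @param baselineCorrect subtract the pre-stimulus noise-floor density.
#' @param integrand passed to [signalDensity()].
#' @return data.frame with columns session (NA placeholder), electrode,
#'   pulseIndex, time (s, session), class, nsd, lightOn.
#' @export
nsdSeries <- function(recording, nControl = 10, maskElectrodes = integer(0),
                      vThreshold = 5, tBlankEnd = 2e-4, epochEnd = NULL,
                      baselineCorrect = TRUE,
                      integrand = c("abs", "square")) {
  integrand <- match.arg(integrand)
  ill <- recording@illumination
  if (is.null(ill)) stop("recording has no illumination protocol")
  fs <- recording@fs
  pre <- recording@preWindow
  if (is.null(epochEnd))
    epochEnd <- recording@epochSamples / fs - pre
  pt <- recording@stim@pulseTimes
  if (nControl > sum(pt < min(ill@pulseOnsets)))
    stop("need >= ", nControl, " pulses before the first light onset")
  lightOn <- vapply(pt, function(tp)
    any(tp >= ill@pulseOnsets & tp < ill@pulseOnsets + ill@pulseDuration),
    TRUE)
  electrodes <- setdiff(seq_len(nElectrodes(recording)), maskElectrodes)
  nP <- nEpochs(recording)
  # subtract the protocol-known stimulation artifact before filtering so its
  # zero-phase band-pass tail cannot contaminate the pre-stimulus baseline
  filt <- preprocessRecording(recording, fsOut = NULL)
  tRel <- epochTime(filt)
  preMask <- tRel < 0
  out <- list()
  for (e in electrodes) {
    w <- integrationWindows(recording@design, e, vThreshold, epochEnd,
                            tBlankEnd)
    dens <- matrix(0, nP, 2, dimnames = list(NULL, c("fast", "slow")))
    for (p in seq_len(nP)) {
      x <- epochMatrix(filt, p)[e, ]
      rate <- if (baselineCorrect) mean(abs(x[preMask])) else 0
      for (cl in c("fast", "slow")) {
        win <- w[[cl]]
        len <- max(win[2] - win[1], 0)
        d <- if (len > 0)
          signalDensity(x, fs, win, preWindow = pre, integrand = integrand)
        else 0
        dens[p, cl] <- max(d - rate * len, 0)
      }
    }
    for (cl in c("fast", "slow")) {
      ctrl <- mean(dens[seq_len(nControl), cl])
      nsd <- if (ctrl > 0) dens[, cl] / ctrl else rep(NA_real_, nP)
      if (ctrl <= 0) warning("zero control-mean density: NSD undefined for ",
                             "electrode ", e, " class ", cl)
      out[[length(out) + 1L]] <- data.frame(
        session = NA_integer_, electrode = e, pulseIndex = seq_len(nP),
        time = pt, class = cl, nsd = nsd, lightOn = lightOn)
    }
  }
  do.call(rbind, out)
}

#' Exponential kinetics of NSD during inhibition or recovery
#'
#' Least-squares fit (Levenberg-Marquardt) per fiber class of
#' `NSD(t) = P + (1 - P) exp(-t / tau)` during inhibition (t measured from
#' the most recent light onset) or `NSD(t) = 1 + (NSD0 - 1) exp(-t / tau)`
#' during recovery (t from the most recent light-off), pooling pulses across
#' light cycles and electrodes.
#'
#' @param nsd data.frame from [nsdSeries()].
#' @param illumination the session's [IlluminationProtocol-class].
#' @param phase "inhibition" or "recovery".
#' @param minPulses minimum pulses per class required for a fit.
#' @return data.frame with class, phase, tau (s), plateau, r2, converged, n.
#' @export
fitKinetics <- function(nsd, illumination,
                        phase = c("inhibition", "recovery"), minPulses = 5) {
  phase <- match.arg(phase)
  on <- illumination@pulseOnsets
  off <- on + illumination@pulseDuration
  lastBefore <- function(t, marks) {
    m <- marks[marks <= t + 1e-9]
    if (length(m)) max(m) else NA_real_
  }
  if (phase == "inhibition") {
    sel <- nsd$lightOn
    ref <- vapply(nsd$time, lastBefore, 0, marks = on)
  } else {
    # recovery: dark pulses after at least one completed light pulse
    ref <- vapply(nsd$time, lastBefore, 0, marks = off)
    sel <- !nsd$lightOn & !is.na(ref)
  }
  out <- list()
  for (cl in c("fast", "slow")) {
    d <- nsd[sel & nsd$class == cl & !is.na(nsd$nsd), , drop = FALSE]
    t <- nsd$time[sel & nsd$class == cl & !is.na(nsd$nsd)] -
      ref[sel & nsd$class == cl & !is.na(nsd$nsd)]
    row <- data.frame(class = cl, phase = phase, tau = NA_real_,
                      plateau = NA_real_, r2 = NA_real_, converged = FALSE,
                      n = nrow(d))
    if (nrow(d) >= minPulses) {
      fit <- try(if (phase == "inhibition")
        nlsLM(nsd ~ P + (1 - P) * exp(-t / tau),
              data = data.frame(nsd = d$nsd, t = t),
              start = list(P = max(min(d$nsd), 0.01), tau = 3),
              lower = c(P = -1, tau = 1e-3), upper = c(P = 2, tau = 1e3))
        else
          nlsLM(nsd ~ 1 + (N0 - 1) * exp(-t / tau),
                data = data.frame(nsd = d$nsd, t = t),
                start = list(N0 = min(d$nsd), tau = 3),
                lower = c(N0 = -1, tau = 1e-3), upper = c(N0 = 2, tau = 1e3)),
        silent = TRUE)
      if (!inherits(fit, "try-error")) {
        cf <- coef(fit)
        ssRes <- sum(residuals(fit)^2)
        ssTot <- sum((d$nsd - mean(d$nsd))^2)
        row$tau <- cf[["tau"]]
        row$plateau <- if (phase == "inhibition") cf[["P"]] else cf[["N0"]]
        row$r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
        row$converged <- TRUE
      }
    }
    out[[cl]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Factorial ANOVA of NSD and class-wise post-hoc tests
#'
#' Four-way factorial ANOVA of NSD on illumination phase, fiber class,
#' electrode and session (main effects plus the phase x class interaction by
#' default; type-II F-tests), followed by post-hoc one-way ANOVA of the
#' illumination phase within each fiber class.
#'
#' @param nsd data.frame with columns nsd, lightOn, class, electrode,
#'   session (a session column that is all NA is treated as a single
#'   session and dropped from the model).
#' @param alpha significance threshold.
#' @param formula optional model formula overriding the default factor set.
#' @return list with `omnibus` (term, F, p, significant) and `posthoc`
#'   (class, F, p, significant).
#' @export
inhibitionAnova <- function(nsd, alpha = 0.05, formula = NULL) {
  d <- nsd[!is.na(nsd$nsd), , drop = FALSE]
  d$phase <- factor(ifelse(d$lightOn, "light", "dark"))
  d$class <- factor(d$class)
  d$electrode <- factor(d$electrode)
  oneSession <- all(is.na(d$session)) || length(unique(d$session)) < 2L
  if (!oneSession) d$session <- factor(d$session)
  for (fac in c("phase", "class"))
    if (nlevels(d[[fac]]) < 2L)
      stop("factor '", fac, "' has a single level: ",
           paste(levels(d[[fac]]), collapse = ", "))
  if (is.null(formula))
    formula <- if (oneSession)
      nsd ~ phase * class + electrode
    else
      nsd ~ phase * class + electrode + session
  fit <- lm(formula, data = d)
  an <- Anova(fit, type = 2)
  keep <- rownames(an) != "Residuals"
  omnibus <- data.frame(term = rownames(an)[keep],
                        F = an[["F value"]][keep],
                        p = an[["Pr(>F)"]][keep])
  omnibus$significant <- omnibus$p < alpha
  post <- list()
  for (cl in levels(d$class)) {
    dc <- d[d$class == cl, , drop = FALSE]
    a <- anova(lm(nsd ~ phase, data = dc))
    post[[cl]] <- data.frame(class = cl, F = a[["F value"]][1],
                             p = a[["Pr(>F)"]][1])
  }
  posthoc <- do.call(rbind, post)
  posthoc$significant <- posthoc$p < alpha
  rownames(posthoc) <- NULL
  list(omnibus = omnibus, posthoc = posthoc)
}

#' Kruskal-Wallis comparison of SNR across channel lengths
#'
#' Omnibus Kruskal-Wallis test over the length groups followed by pairwise
#' Kruskal-Wallis comparisons with Bonferroni correction over the number of
#' pairs (the per-test threshold for 6 pairwise tests at family alpha 0.05
#' is 0.05/6).
#'
#' @param snr numeric vector of SNR values, dB.
#' @param group grouping factor/vector (e.g. channel length in mm).
#' @param alpha family-wise significance level.
#' @return list with `omnibus` (statistic, p), `pairwise` data.frame
#'   (groupA, groupB, p, pAdjusted, significant) and `perTestAlpha`; groups
#'   with fewer than 2 observations are excluded with a warning.
#' @export
snrLengthComparison <- function(snr, group, alpha = 0.05) {
  group <- as.factor(group)
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !group %in% small
    snr <- snr[keep]; group <- droplevels(group[keep])
  }
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  omni <- kruskal.test(snr, group)
  prs <- utils::combn(levels(group), 2)
  m <- ncol(prs)
  pw <- lapply(seq_len(m), function(i) {
    sel <- group %in% prs[, i]
    kt <- kruskal.test(snr[sel], droplevels(group[sel]))
    data.frame(groupA = prs[1, i], groupB = prs[2, i], p = kt$p.value)
  })
  pw <- do.call(rbind, pw)
  pw$pAdjusted <- p.adjust(pw$p, method = "bonferroni")
  pw$significant <- pw$pAdjusted < alpha
  list(omnibus = data.frame(statistic = unname(omni$statistic),
                            p = omni$p.value),
       pairwise = pw, perTestAlpha = alpha / m)
}
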