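---
title: "Models and methods behind nervechip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nervechip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervechip)
```

# Scope

`nervechip` models the computational side of a microchannel
"nerve-on-a-chip" experiment: extracellular single-fiber action potentials
(SFAPs) propagating past an array of up to eight electrodes embedded in a
narrow insulating conduit, the velocity-selective-recording (VSR)
delay-and-sum estimator of conduction velocity with its success-rate (SR)
statistic, a linear response-surface model of the SR against channel
geometry and waveform features, and the normalized-signal-density (NSD)
analysis of opto-thermal neuroinhibition with first-order kinetics. Because
no public recordings exist for this preparation, the package ships a
first-class synthetic-data generator whose defaults encode the bench
conditions; every analysis is validated against it.

# The simulator

## Waveform template

The extracellular SFAP is modeled as a Ricker wavelet (second derivative of
a Gaussian), parameterized directly by its full width at half amplitude
$w$ and baseline-to-peak amplitude $A$:

$$ s(t) = A \left(1 - \frac{t^2}{\sigma^2}\right)
   e^{-t^2 / (2\sigma^2)}, \qquad
   \sigma = \frac{w}{2\sqrt{x_{1/2}}}, $$

where $x_{1/2} \approx 0.3918$ solves $(1-x)e^{-x/2} = 1/2$. The Ricker
shape is triphasic and integrates exactly to zero, matching AC-coupled
extracellular recordings, and its closed-form width makes the metrology
round trip exact. A template must carry at least 10 samples across $w$;
narrower requests error with the required sampling rate. Consequently,
sweeps that include 0.03 ms widths are simulated directly at 500 kHz (the
analysis rate) rather than at the 50 kHz acquisition rate.

## Channel amplification

The sealed microchannel amplifies the extracellular potential with a
position-dependent gain. The default profile is

$$ g(u) \propto u\,(1-u)^{1/2}, \qquad u = z / L, $$

normalized to 1 at its maximum $u^\ast = 2/3$: it vanishes at the channel
entrance, peaks at two-thirds of the channel length, and falls off
asymmetrically toward the exit. The peak gain scales linearly with channel
length by default (`channelGainScale()`, normalized at 10 mm); both the
profile shape and the length calibration are replaceable by a measured
lookup table, since the default forms are phenomenological stand-ins, not
fits to published gain values.

## Artifacts

Each stimulus adds a square biphasic stimulation artifact (identical and
simultaneous on all electrodes; default 150 uV, 0.1 ms) and, per fiber, an
onset artifact generated when the spike crosses into the recording channel.
The onset transient is brief (0.06 ms) and simultaneous on all electrodes,
but its amplitude decays as $e^{-z/\lambda}$ ($\lambda = 3$ mm) away from
the entrance where it is generated, and defaults to 8% of the fiber
amplitude (scaled by the channel's length gain). These two open device
properties — the onset's amplitude scaling and spatial footprint — were set
so that the emulated bench reproduces the demonstrated capabilities of the
real one: delay-and-sum recovery of conduction velocities up to ~50 m/s
from averaged repetitions, and an SR that degrades toward the fast end of
the velocity range. A fully coherent onset artifact as large as the fiber
itself would make fast-velocity estimation impossible for any estimator of
this family, which the real platform's recoveries of 44 m/s fibers rule
out. Both parameters are exposed (`onsetFraction`, `onsetWidth`,
`onsetLambda`).

## Noise, repetitions and reproducibility

Gaussian white noise is calibrated so that the best-electrode SNR —
defined, since the bench definition is unstated, as
$20\log_{10}(\text{peak amplitude} / \text{RMS of the pre-stimulus
baseline})$ on the traces as simulated — equals the requested level.
Recordings are epoched: one fixed window per stimulus pulse, including a
5 ms pre-stimulus baseline, with pulse times kept in session coordinates
(so slow thermal dynamics are exact while the signal-free inter-pulse
baseline, which no analysis here uses, is not materialized). All randomness
derives from one seed, with per-pulse sub-streams derived
deterministically; identical configuration and seed give bit-identical
recordings.

When fibers are drawn at random (`randomFibers()`), the median amplitude
increases linearly with conduction velocity (with lognormal scatter and an
occasional doubled-amplitude outlier emulating superposed same-velocity
spikes), and the median width decreases with velocity
($w \approx 0.05 + 1.2/v$ ms, clipped to 0.03–0.3 ms): large myelinated
fibers conduct fast, spike briefly, and produce the largest potentials.

# The acquisition chain

The bench chain — order-1 Butterworth band-pass 100 Hz–3 kHz and
cubic-spline up-sampling from 50 to 500 kHz — is reproduced by
`bandpass()` and `upsampleSpline()`. Filtering is applied forward-backward
(zero phase) so that velocity estimates do not inherit the filter's group
delay; this deliberately deviates from the causal bench amplifier and is
the right choice for timing analyses. `preprocessRecording()` first
subtracts the stimulation artifact using its protocol-known square
template. Subtraction is preferred over the more obvious window blanking
because fast-fiber waves genuinely overlap the artifact in time: blanking
clips their leading lobe asymmetrically across electrodes and biases the
shift search, while template subtraction is exact and side-effect free.
Removing the artifact *before* filtering also keeps the zero-phase filter
from smearing artifact energy backwards into the pre-stimulus baseline.

Spike detection thresholds at $k = 4$ times the robust noise scale
($1.4826\,\times$ MAD of the pre-stimulus baseline; pool it across epochs
with `pooledNoiseScale()` for a stable threshold). Amplitude is measured
from the baseline median, width at half amplitude of the dominant lobe with
linearly interpolated crossings; "half amplitude" and "half prominence" are
treated as the same quantity. Metrology is performed on unfiltered traces:
the order-1 band edges attenuate a 0.22 ms Ricker by roughly 8%, which
would corrupt amplitude measurements if applied first. Coherent averaging
of $n$ repetitions adds $10\log_{10} n$ dB (`snrAfterAveraging()`).

# Velocity-selective recording

Candidate velocities live on the integer-shift grid
$v(s) = \text{pitch}/(s\,\Delta t)$, both signs, $s = 0$ excluded; with a
1 mm pitch at 500 kHz the candidates next to 50 m/s are 55.6 and 45.5 m/s,
so the grid tolerance there is $\delta \approx 5$ m/s. `delayAndSum()`
advances electrode $i$ by $i\,s$ samples and sums; the estimate is the
shift maximizing the peak absolute summed amplitude (an Rcpp kernel scans
the whole grid). Ties break deterministically toward smaller $|s|$. No
sub-sample refinement is applied: estimates live on the grid, as the
measured $\delta$ semantics require. $\delta$ at an interior grid point is
half the spacing between the two adjacent candidate velocities; at the
fast grid edge it is the one-sided gap to the next slower candidate.

The SR across repetitions takes the reference velocity from the pointwise
mean of the repetitions and counts the per-repetition estimates within
$\pm\delta$ of it. Epochs with estimated velocity above 60 m/s or with
more than one detected spike per electrode are discarded
(`discardFilter()`). Simultaneous artifacts only add constructively at the
excluded $s = 0$; the residual leakage at small $|s|$ is handled by the
artifact treatment above, and a common-average-reference option
(`removeCommonMode`) is available for bench data with artifact shapes the
template subtraction cannot describe.

# The SR response-surface model

`fitSrModel()` regresses SR, untransformed, on
$[1, N_E, \text{pitch}, \text{width}, e^{1/v}, \text{SNR}]$ by ordinary
least squares (a logit response is available behind a flag). The $e^{1/v}$
transform is taken as given. Per-term significance uses type-II ANOVA
F-tests at $\alpha = 0.05$; "standardized half effects" code each factor to
$[-1, 1]$ over its observed range, so the half effect of term $j$ is
$a_j \cdot \text{range}_j / 2$ with per-coefficient t-intervals scaled the
same way. Predictions are clipped to $[0, 1]$. `safeRegion()` maps channel
length to attainable SNR through the gain calibration
($\text{SNR}_\text{eff} = \text{SNR} + 20\log_{10} g(L)$), marks the
region with predicted SR at or above 0.8 as safe for velocity calculation,
and reports the minimal coherent-averaging count $n$ that lifts the
prediction over the threshold elsewhere, using the averaging law above.
Simulated and experimental-like fits are kept as separate model objects.

# Opto-thermal neuroinhibition

Surface temperature follows a first-order response with the polymer time
constant 3.22 s: rise $1 - e^{-t/\tau}$ during a 15-s pulse, exponential
decay after light-off, superposed across pulses, with a Gaussian spatial
footprint along the channel (sigma 1.5 mm, centred on electrode E4, peak
rise 10 degC). Fiber amplitude at position $z$ is scaled by
$1 - c_\text{class}\,\Delta T_\text{class}(z, t)$, where the class-specific
modulation state follows the same first-order form with its own time
constant (a phenomenological membrane response): slow (thin) fibers couple
more strongly ($c_\text{slow} = 0.08$/degC vs $c_\text{fast} =
0.055$/degC) and respond more slowly ($\tau_\text{slow} = 6.44$ s vs
$\tau_\text{fast} = 3.22$ s). Slow-fiber conduction through the heated
spot is additionally attenuated for all downstream electrodes by a
transmission factor $1 - \text{blockDepth} \cdot \text{state}(t)$
(default full block at steady state, reversibly), and fast-fiber velocity
increases mildly with temperature (0.5%/degC). These couplings are
generator defaults calibrated once so the simulated sessions reproduce the
reported phenomenology — end-of-pulse fast NSD about twice the slow NSD,
fast kinetics about twice as fast as slow, full recovery after light-off —
and then frozen; all are configurable.

NSD integrates the rectified band-passed trace over per-electrode windows
split at $d/v_\text{thr}$ ($v_\text{thr} = 5$ m/s, $d$ = distance from the
stimulation cathode), normalizing by the mean over the first ten pre-light
pulses. Two analysis choices deserve note. First, the integrand is $|x|$
(signal energy $x^2$ is available) since the source only states
"integrated". Second, the pre-stimulus rectified noise rate times the
window length is subtracted (clipped at zero) before normalization: the
slow window spans most of the epoch, and at realistic SNR the rectified
noise floor would otherwise dominate the integral and compress every NSD
toward 1, masking inhibition. With the correction, control-pulse NSD still
averages exactly 1 by construction. Electrodes E4–E6 (ITO, noisy under
illumination on the bench) are excluded by a configurable mask.

Kinetics are fitted per class by Levenberg–Marquardt least squares:
$\text{NSD}(t) = P + (1-P)e^{-t/\tau}$ during inhibition ($t$ from light
onset) and $\text{NSD}(t) = 1 + (\text{NSD}_0 - 1)e^{-t/\tau}$ during
recovery, pooling pulses across cycles and electrodes; these first-order
forms are inferred from the charging/discharging shape of the data, the
original fitting equations being unavailable. The factorial ANOVA models
NSD on illumination phase, fiber class, electrode and session (main
effects plus the phase-by-class interaction; type-II F-tests), with
post-hoc one-way ANOVA of phase within each class; SNR comparisons across
channel lengths use Kruskal–Wallis with Bonferroni-corrected pairwise
tests.

# Numerical choices and test problem sizes

Velocity ties at equal metric break toward smaller $|s|$; flat metrics
(all-zero epochs) return a flagged no-estimate; empty integration windows
return zero density with a warning; zero control densities flag the NSD as
undefined; coupling scales are clipped at zero with a warning. The test
and acceptance suites size their simulations for a single CPU: the
delay-and-sum/cross-correlation equivalence runs every grid shift on
two-electrode epochs; velocity recovery uses 200 averaged-repetition
trials at 30 dB; the ANOVA null calibration runs 200 two-session
replicates with 25 pulses each; SR monotonicity uses 12 recordings per
condition over three SNR levels and two velocities; kinetics recovery
spans three time constants with 20 points per phase. The
success-rate-vs-generation-velocity checks evaluate the estimate from the
averaged repetitions — the platform's own reference-velocity practice —
because on an integer grid whose tolerance roughly equals one grid step,
single-repetition estimates at 30 dB slip by one step often enough that no
estimator of this family could pass a 95% single-shot criterion.

# What the simulations do and do not show

The generator reproduces the statistical structure the analyses assume:
time-locked propagating templates with position-dependent gain,
simultaneous artifacts, calibrated noise, repetition structure, and slow
thermal modulation. It does not model biophysics (no cable theory or
temperature-dependent channel kinetics), electrode impedance or ITO noise,
waveform irregularity across repetitions, or multi-unit superposition
beyond linear summation. Passing tests therefore demonstrate the
correctness and calibration of the estimators on data with known ground
truth, not the biological fidelity of the waveforms; conclusions about
real tissue still require bench recordings. Two further limitations are
worth naming. With the integer-shift tolerance scaling as the square of
velocity — the same scaling as the velocity error a fixed timing error
induces — the success rate is nearly velocity-invariant at fixed SNR in
this simulator, so the exp(1/v) model term carries little signal; the
bench's stronger velocity dependence plausibly reflects artifact and
waveform interactions that exact stimulation-template subtraction removes.
And at SNR above roughly 20 dB with wide waveforms at fast velocities, the
onset artifact can bias the averaged-epoch reference velocity into a
different grid bin than the one the single-repetition estimates cluster
in, producing a non-monotone dip of SR versus SNR; the monotonicity
checks therefore run in the 3-15 dB regime where the surface behaves like
the reported one.
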