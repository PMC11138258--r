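---
title: "Methods: test-retest reliability of resting-state EEG spectral features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: test-retest reliability of resting-state EEG spectral features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegretest)
```

## The problem

Before a quantitative EEG measure can serve as an outcome in a clinical
trial, it must be shown to be stable when the measurement is simply
repeated — on the same day, and across the weeks spanned by a trial. This
package implements that test-retest analysis for six resting-state EEG
power-spectral features (relative band power in delta, theta, alpha, beta
and gamma, plus the individual alpha peak frequency, IPF), together with a
synthetic-data generator whose true reliability structure is known, so that
every estimator in the chain can be validated by parameter recovery rather
than by eyeballing.

The reliability metric throughout is the intraclass correlation for a
two-way random-effects model with absolute agreement of a single
measurement, ICC(A,1): the ratio of between-subject variance to total
variance, where disagreement between visits — including a systematic visit
shift — counts against reliability.

## The generative model

The generator emulates a repeated-session resting-state acquisition:
128-channel recordings at 1000 Hz for 300 s per subject-session by default
(tests and examples use reduced 8-channel, 60 s, 250 Hz fixtures; problem
sizes are stated with each analysis below). Each channel is a sum of

* an aperiodic background with power ∝ 1/f^χ, χ drawn per subject
  (default mean 1.5, SD 0.15 — conventional values for resting EEG; the
  underlying study reports no population spectra, so these are documented
  conventions, not reproduced facts);
* five band-limited Gaussian components (delta 2–3.5, theta 4–7.5, alpha
  8–12.5, beta 13–30, gamma 30–80 Hz), produced by drawing a complex
  Gaussian spectrum on the band's bins and inverting — exact band control
  with no filter ringing;
* a narrowband alpha oscillation at a subject-specific peak frequency,
  drawn from a normal law truncated to [8, 12.5] Hz;
* optional artifacts: a 60 Hz mains sinusoid, flat bad channels, and
  blink-like low-frequency transients on frontal channels.

The reliability structure is imposed on the *log* band amplitudes:

```
log-amplitude[subject, visit, band] = mean[band] + subject effect + visit effect + residual
```

with variances `(sigma2_subject, sigma2_session, sigma2_error)` derived
from a per-feature target ICC by `variance_components_for_icc()`
(`sigma2_subject = ICC x total`, remainder split by `session_share`,
default 0.3). Log-scale components were chosen because band power is
positive and approximately log-normal across subjects. A consequence,
stated openly: the true ICC of the *extracted* relative band power differs
slightly from the latent target, because relative power couples the bands
through its common denominator and the waveform-level estimate adds
measurement noise. Tests therefore check the latent level exactly (oracle
arithmetic) and the end-to-end level within Monte-Carlo tolerance.

The IPF is a subject-level constant plus per-session jitter whose variance
is derived from the IPF target ICC; the 0.5 Hz spectral grid additionally
quantizes the extracted value. Default per-feature target ICCs are the
same-day values of the emulated study design (delta 0.81, theta 0.875,
alpha 0.959, beta 0.84, gamma 0.814, IPF 0.847).

Seeding is counter-based: one master seed, with per-subject and
per-session streams derived by a fixed mixing function, so enlarging the
study never perturbs already-generated subjects, and `generate_dataset()`
is byte-reproducible down to the EDF files it writes.

## Preprocessing

The conditioning chain reproduces a standard resting-EEG pipeline in a
fully deterministic form:

* **Filtering.** 2 Hz highpass, 80 Hz lowpass, and a 55–65 Hz mains
  bandstop repeated at every harmonic up to the Nyquist frequency of the
  original sampling rate. All stages are symmetric windowed-sinc FIR
  kernels (Blackman window) composed into one kernel and applied once, so
  the response is exactly zero-phase. Transition widths are 25% of each
  passband cutoff and 25% of the stop bandwidth for the notch edges. The
  designed response is better than −90 dB at 60 Hz and below 1 dB ripple
  across 4–50 Hz. Signals are extended by odd (antisymmetric) reflection
  before convolution; within half a kernel length of the record edges the
  output necessarily depends on that extension, so attenuation contracts
  are verified on the steady-state region and on the designed response.
* **Epoching.** Consecutive non-overlapping 2 s epochs; a trailing partial
  epoch is discarded.
* **Artifact rejection.** The original study used manual inspection and
  ICA-based artifact removal; both are irreproducible from code, and this
  package deliberately replaces them with deterministic screens — the
  headline methodological substitution. An epoch is dropped when any
  analysis channel exceeds 150 µV half peak-to-peak or when its log total
  variance sits more than 4 robust z-units above the across-epoch median.
* **Bad channels.** Channels that are exactly flat, or whose log variance
  deviates by more than 5 robust z-units *and* at least a 4x variance
  ratio (the absolute floor prevents spurious flags on small,
  near-homogeneous arrays where the MAD collapses), are flagged — at most
  5% of channels, worst first — and rebuilt by spherical-spline
  interpolation (Perrin-type g-function, Legendre series truncated at 7
  terms, spline order m = 4, ridge 1e-5 on the spline system). Detection
  and interpolation run before the final rejection statistics, fixing the
  order detect → interpolate → reject.

## Feature extraction

Welch's method per channel: 2 s Hanning windows, 50% overlap, window power
normalization, 0.5 Hz resolution. Segments are drawn within contiguous
runs of kept epochs only, so no segment spans a rejection gap. Relative
power divides each bin in [2, 80] Hz by the channel's total over the same
range; the five band averages use the documented bin assignment (a bin
belongs to [lo, hi] iff lo ≤ f ≤ hi, the shared 30 Hz bin going to beta;
the 55–65 Hz bins stay in the normalizing total but are excluded from the
gamma average). IPF is the global argmax of the log10 relative spectrum in
[5, 14] Hz, ties to the lower frequency; a peakless monotone spectrum
therefore returns the 5 Hz window edge and is counted in a quality flag.
Features are computed per channel and then averaged, unweighted, over the
108 non-excluded montage channels (computing IPF on the montage-averaged
spectrum instead would be a defensible alternative; the per-channel-first
convention matches averaging *feature values* over electrodes).

The packaged montage is a synthetic stand-in: 128 electrodes on a
Fibonacci lattice of the unit sphere with the 20 lowest (face/neck ring)
excluded, leaving 108 analysis channels. The geometry supports
spherical-spline interpolation and channel accounting; it does not
reproduce any manufacturer's labelled layout, for which no public label
list exists.

## Reliability estimation

For each feature and inter-session interval, sessions are paired into an
n x k matrix (same-day: the first k same-day sessions; week intervals:
baseline plus the labelled follow-up), keeping listwise-complete subjects
only. The two-way replication-free ANOVA gives BMS, RMS, EMS and WMS, and

```
ICC(A,1) = (BMS − EMS) / (BMS + (k − 1) EMS + (k / n)(RMS − EMS))
```

the McGraw–Wong two-way random-effects, absolute-agreement, single-measure
form. A published variant of this formula with `(k + 1) EMS` in the
denominator is retained behind `icc_a1(..., variant = "printed")` for
audit; it is treated as a typographical slip because it reproduces neither
the named model nor the reference implementations of it. Estimates can be
negative and are reported as computed; classification maps anything below
0.5 to "poor" (bands: poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤
excellent ≤ 1, left-closed). Confidence intervals use the F-based
McGraw–Wong approximation with Satterthwaite degrees of freedom; the
degenerate zero-variance case returns [−1, 1] with a flag, and the
perfect-agreement case collapses to [1, 1] (the Satterthwaite terms are
kept finite by evaluating them at 1 − 1e-10). Coverage is verified by
simulation (500 replicates at n = 30, k = 2, true ICC 0.85) in the test
suite.

## Power planning

The study-design calculation treats reliability as a one-way F-test: with
`C(ρ) = 1 + kρ/(1 − ρ)`, the power to reject H0: ICC = ρ0 against a true
ρ1 is `P[F(n−1, n(k−1)) > (C(ρ0)/C(ρ1)) F_crit(1−α)]`. The test is
one-sided at α = 0.05 by default (the conventional reliability-design
formulation; `two_sided = TRUE` spends α/2). `detectable_icc()` inverts
the power function by bracketed root-finding to 1e-6; with n = 30, k = 2,
ρ0 = 0.50 and 80% power it returns 0.767, i.e. 0.77 at the two-decimal
precision of design software. `required_n()` searches the exact power
function, with the Walter–Eliasziw–Donner closed form available for
comparison (within ±2 subjects across the tested grid). The analytic
power matches the simulated rejection rate of the F statistic within
Monte-Carlo error at 10,000 replicates. A companion design figure for a
"chronic condition" quoting 0.75 under apparently identical settings is
under-specified (sidedness or another option unstated) and is not
computed.

## What the synthetic data do and do not show

Passing parameter recovery on synthetic data demonstrates that the
estimators are correct for the stated generative model; it does not
certify the reliability of any real patient population. In particular the
generator's artifacts are schematic templates (sinusoidal mains, flat bad
channels, half-cosine blinks), channels are exchangeable rather than
spatially correlated sources, and no claim is made that the manual-ICA
steps it replaces are innocuous on real data. The study-size behaviour is
also honest about sampling noise: with a true ICC barely above 0.8, an
n = 30 estimate falls below 0.8 nearly half the time, so a single-study
report that all six same-day features exceeded 0.8 is informative but
would not recur in most repetitions of the same design.

## Problem sizes and numerical choices

Analyses and tests run at deliberately reduced sizes chosen to exercise
every code path: 8-channel, 60 s, 250 Hz fixtures for waveform-level work
(a full n = 30, k = 2 study at this scale runs in ~10 s), n = 200 with 200
replicates for estimator calibration, 500 replicates for CI coverage,
10,000 draws for power validation. Tolerances: unit-sphere norms 1e-6;
relative-power normalization 1e-9; oracle equality 1e-10 relative; spline
constant-field exactness 1e-6 relative and 5% on low-order harmonics; EDF
round-trip bounded by one 16-bit quantization step. Ties in the IPF argmax
break toward the lower frequency; the 30 Hz bin belongs to beta; EDF
physical ranges are symmetric per channel so zero is exactly
representable.
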