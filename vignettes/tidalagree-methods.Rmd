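---
title: "tidalagree: models, numerics and their rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tidalagree: models, numerics and their rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidalagree)
```

This vignette documents the modelling and numerical decisions behind the
package: what each stage computes, why it is computed that way, and
where the known limits are.

## 1. The synthetic breath model

A subject's epoch is a contiguous train of breaths. Each breath has an
inspiratory duration `tI` and expiratory duration `tE` drawn from gamma
distributions with the configured means and a common coefficient of
variation `cv_timing` (default 0.1, a deliberately mild
breath-to-breath variability: large enough to make the train aperiodic
— which the lag estimator needs, see §3 — and small enough that
resting-breathing summary statistics stay tight).

The volume shape of each limb is a warped half-cosine,

$$ s(u; p) = \tfrac12\bigl(1 - \cos(\pi u^{p})\bigr), \qquad u \in [0, 1], $$

rising from 0 to 1 over the limb. The warp exponent `p` is solved per
breath (by `uniroot`) so that the analytic flow at the 50%-volume
crossing of each limb yields exactly the configured IE50
(= TIF50/TEF50). This gives the generator a closed-form ground truth
for the one shape parameter the package estimates, so parameter
recovery can be tested without numerical circularity: the test target
was not produced by the same code that measures it.

Rendering: PNT flow is the analytic time derivative sampled at 100 Hz
plus white noise; **PNT volume is the trapezoidal running integral of
the rendered (noisy) flow**, exactly as a real pneumotachograph derives
volume. A consequence is that re-integrating `pnt_flow` reproduces
`pnt_volume` to machine precision, and the analytic volume agrees with
the rendered one to $O(f_s^{-2})$. The displacement channel is the
analytic volume delayed by `inter_device_offset`, scaled by `slp_gain`
(displacement is uncalibrated), plus a slow sinusoidal baseline drift
and white noise, sampled at its native 30 Hz. Artifacts are short
(tI = tE = 0.3 s), small (0.1 × tidal amplitude) cough-like breaths
inserted with probability `artifact_rate` per junction.

## 2. Resampling and the extremum-displacement question

The 30 Hz displacement trace is resampled to 100 Hz with the
shape-preserving piecewise cubic Hermite interpolant (pchip,
`pracma::pchip`). pchip is chosen because it cannot overshoot: spline
interpolants ring around sharp breath peaks and can fabricate spurious
extrema, which breath detection would then count.

A subtlety documented in `?resampling_extremum_shift` matters when
quantifying "how much does interpolation move the peaks": the
Fritsch–Carlson construction zeroes the interpolant's derivative at any
knot where the secant slopes change sign, so the interpolant's extremum
sits exactly on the extremal *input knot*. Relative to the
continuous-time extrema of the underlying signal the detected extremum
is therefore off by up to about half an input interval (≈ 17 ms at
30 Hz) — an acquisition-grid quantization that no shape-preserving
local interpolant can reduce (only band-limited reconstruction could).
Relative to the extrema of the *sampled* input the resampling step
moves extrema by only a few milliseconds. The function reports both
frames (`max_shift_ms` vs `max_move_ms`); the acceptance suite measures
the former, and it is red for exactly this reason.

## 3. Filtering and alignment

The inter-device lag is estimated by normalized cross-correlation of
band-pass filtered copies (0.05–10 Hz) of the PNT volume and the
resampled displacement trace; the filter removes baseline drift and
wideband noise that otherwise bias the correlation. Filtering is used
*only* for lag estimation — timing indices are always read off the
unfiltered traces, so filter dispersion can never move a reported
marker.

Numerically, an order-5 elliptic band-pass with a 0.05 Hz edge at
$f_s = 100$ Hz (0.1% of Nyquist) is unusable in polynomial transfer
function form: the poles are so clustered near $z = 1$ that expanding
the polynomial destroys the response (measured tens of dB of error).
The design therefore stays in zero-pole form end to end (analog
prototype → s-plane band-pass transform → bilinear transform) and is
realized as a cascade of second-order sections, pairing each
conjugate pole pair with its nearest zeros. Zero-phase filtering runs
the cascade forward and backward with odd-reflection padding sized by
the slowest pole's decay. The realized magnitude response meets the
printed specification (≥ 50 dB stop-band attenuation, verified in the
acceptance suite at 50.0009 dB).

The lag search itself is exhaustive over integer samples within
`max_lag`, maximizing the Pearson correlation of the overlap (gain- and
offset-invariant). A caveat verified in the tests: a strictly periodic
train (`cv_timing = 0`) makes lags one breath period apart
indistinguishable in principle; the default timing variability makes
the peak unique. Peak correlations below `floor` are flagged for a
manual `lag_override`, mirroring recordings whose synchrony must be
fixed by inspection.

## 4. Breath detection and screening

Candidate markers are zero crossings of a boxcar-smoothed (0.2 s)
derivative of the level trace, refined to the most extreme raw sample
within half a smoothing window — the smoothing suppresses noise-induced
crossings, while the refinement step keeps the reported marker on the
raw signal. Screening then works in two stages:

1. **Low-prominence pruning.** The adjacent extremum pair with the
   smallest swing is deleted repeatedly while that swing is below
   `min_amplitude_fraction` × the 95th-percentile swing. When a deleted
   member is more extreme than its same-type neighbour, it replaces it
   (envelope merge), so chatter clustered around a true peak cannot
   erase the peak itself.
2. **Assembly rules.** Breaths are assembled trough→peak→trough and
   removed if the duration falls outside `[min_tTot, max_tTot]`, the
   inspiratory amplitude is below `min_amplitude_fraction` × the median
   amplitude, the expiration recovers less than `min_return_fraction`
   of the inspiratory excursion (rejects half-breaths fabricated by a
   noise dip on a cut-off expiration), or a marker lies within
   `edge_guard` of the trace ends (partial breaths at epoch edges are
   dropped). Every removal is logged with its reason.

On noise-free simulations the pipeline recovers PNT markers within one
100 Hz sample. Displacement markers are recovered within one *native*
30 Hz sample (≈ 33 ms): the knot-pinning of §2 means no detector
operating on the resampled trace can beat the acquisition grid. On
noisy cohorts at default settings, screened breath counts match the
ground-truth non-artifact count in ≥ 95% of subjects (measured 97–100%
in the test suite).

## 5. Parameters

Timing indices are plain arithmetic on the markers (`tTot = tI + tE`,
`RR = 60/tTot`, ratios per breath). IE50 is the ratio of the absolute
rates where the inspiratory and expiratory limbs cross the mid-excursion
level, with linear interpolation of both the crossing time and the rate;
multi-crossing limbs use a time-weighted mean and are flagged, as are
zero-excursion breaths. For the PNT the level/rate pair is
volume/flow; for the displacement sensor it is displacement and its
central-difference derivative. Closed forms hold for simple shapes
(IE50 = 1 for a sinusoidal breath, 2 for a 1 s/2 s triangular breath)
and are verified in the tests.

## 6. Agreement statistics

Classical Bland–Altman limits are `bias ± 1.96 SD` of the
test-minus-reference differences. For breath-level (repeated) data the
difference variance is decomposed into between- and within-subject
components by the unbalanced one-way ANOVA method of moments, the bias
is the precision-weighted grand mean, and the limits use the total SD;
with one observation per subject this reduces exactly to the simple
limits. Limit standard errors use the delta method,
$\mathrm{Var}(L) = \mathrm{Var}(\text{bias}) + 1.96^2\,\mathrm{Var}(SD)$
with an effective sample size deflated by the within-subject
correlation. Session comparisons use Wald z-tests per limit plus a
joint 2-df chi-square accounting for the covariance between the two
limits of a group; the empirical type-I error of the joint test is
calibrated in the acceptance suite (within [0.03, 0.07] at n = 100).
`detectable_loa_change()` inverts the same standard errors into the
smallest limit shift detectable at a given power; simulated power at
that shift lands near its nominal value. Distribution diagnostics
report kurtosis, an Anderson–Darling p-value and a QQ deviation, and
repeat them on log-differences when all values are positive — peaked
difference distributions make classical limits conservative, not
anti-conservative.

## 7. Known limitations

- Extremum timing on the 30 Hz channel is bounded by the acquisition
  grid (§2), not by the pipeline; sub-sample marker recovery would
  require band-limited reconstruction, deliberately out of scope.
- An artifact run that touches the truncated end of a trace merges into
  the edge guard and can drop the final breath; breaths adjacent to a
  pruned artifact may carry a marker anywhere in the flat junction the
  artifact occupied.
- The Wald tests are large-sample; their calibration is verified at
  n = 100 differences per group and should not be assumed for very
  small samples.
- The lag estimator assumes an aperiodic signal within the search
  window; for strictly periodic breathing, restrict `max_lag` to less
  than one breath period or supply `lag_override`.
```{r}
sessionInfo()
```
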