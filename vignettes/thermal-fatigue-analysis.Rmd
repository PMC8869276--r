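---
title: "Analysing exercise-induced fatigue from thermal video: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing exercise-induced fatigue from thermal video: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofatigue)
```

## The measurement problem

Skin temperature, imaged contactlessly by an infrared camera, responds to
exercise in two ways that this package quantifies separately. First, a slow
net temperature change: an exercised muscle region warms over a session of
resistance exercise, while facial regions reflect autonomic responses to
effort and fatigue. Second, a change in the *oscillatory content* of the
temperature signal: skin blood flow oscillates in physiologically
attributed frequency bands (vasomotion), and exercise shifts the power in
those bands. The package takes thermal video of a session — an acclimation
baseline, three sets of knee extensions to exhaustion with interset rests,
and a recovery period — and produces per-region features plus the
repeated-measures inference across regions and the correlation of every
feature with the rating of perceived exertion (RPE, an integer 1–10
collected at the end of each set).

Four regions of interest (ROIs) are analysed: the exercised leg, the
contralateral (non-exercised) leg, the nose tip and the corrugator. The
legs index peripheral (muscular/microvascular) responses and the cross-over
effect; the facial regions index the central, brain-derived component of
fatigue.

## From video to traces

Frames are absolute-temperature images (°C) at a known rate (10 Hz for the
cameras this targets; NETD, the per-pixel noise floor, below 30 mK). Each
ROI is a rectangle, tracked frame-to-frame by normalized cross-correlation
template matching: the template is correlated at every integer offset
within ±10 px of the previous position, the best match wins, the template
is refreshed from the tracked box every 50 frames, and frames whose best
score falls below 0.5 (including featureless frames, where the correlation
is undefined) hold the previous position and are flagged rather than
interpolated — failures stay visible downstream. This is deliberately the
simplest tracker adequate for rigid, slow ROI motion; deformable or
landmark tracking is out of scope. The trace \(T_{ROI}(t)\) is the plain
arithmetic mean of the pixels in the tracked box on each frame; box ROIs
are used throughout (no mask shape), with 0-based pixel coordinates,
x along columns, y along rows, inclusive width/height.

## Features

**Time domain.** \(\Delta T_{ROI}\) is the mean of the trace over the last
10 s of the recording minus its mean over the window from 20 s to 10 s
before the first repetition. Windows are half-open \([a, b)\), so each
holds exactly `round(10 * fs)` samples; "10 s before the end" is read as
\([end - 10, end)\). With a linear trend of slope \(m\) the closed form is
\(m \times (t_{c,final} - t_{c,baseline})\) with the window centres
\(t_c\); this anchors the unit tests.

**Frequency domain.** The power spectral density of the 5 minutes before
the first repetition and the last 5 minutes of the recording is estimated
and integrated over the five vasomotion bands — metabolic 0.003–0.02 Hz,
neurogenic 0.02–0.04 Hz, myogenic 0.04–0.15 Hz, respiratory 0.15–0.5 Hz,
cardiac 0.5–1 Hz — and \(\Delta PSD_b\) is the post-minus-pre difference of
the band areas (raw differences, not normalised; a relative variant is
available but not the default). Only the stationary pre/post windows are
analysed; the sets themselves are skipped to avoid motion artifacts.

The estimator is Welch's averaged periodogram: 150-s segments, 50%
overlap, Hann taper, per-segment linear detrend, one-sided density
normalised so the integrated density equals the tapered signal variance
(Parseval, within taper leakage). The estimator is not dictated by the
measurement model — it is a design choice, and all settings travel with
the estimate so alternates are comparable. Band areas use the trapezoid
rule with linear interpolation at band edges that fall between grid
points, which makes band power exactly additive over any partition of a
band.

Two numerical consequences are worth stating. (1) With 150-s segments the
grid spacing is \(1/150 \approx 0.0067\) Hz, coarser than the 0.003 Hz
lower edge of the metabolic band; the metabolic area is therefore
integrated from the first positive grid frequency and flagged
`resolution_limited` rather than silently extrapolated — indeed one full
cycle at 0.003 Hz (~333 s) does not even fit the 300-s window, so the band
is genuinely unresolvable at its lower edge under this protocol. (2) The
DC bin is never integrated; combined with detrending this makes every band
power invariant to adding a constant to the trace.

## The statistics layer

For each of the six features (ΔT and five ΔPSD values), differences across
the four ROIs are tested with a one-way repeated-measures ANOVA (subjects
as blocks): \(F = MS_{cond}/MS_{err}\) on \((k-1, (k-1)(n-1))\) d.f. The
sphericity correction is Greenhouse–Geisser by default — \(\varepsilon\)
computed from the double-centred sample covariance of the condition
scores, multiplying both degrees of freedom (Huynh–Feldt by flag;
uncorrected results are always retained). Post hoc comparisons follow the
Fisher LSD convention: all pairwise paired t-tests, two-sided, unadjusted,
each pair using its own paired error term (the common software convention;
recorded in the report so the pooled-error alternative is auditable).
Pearson correlations of each feature with RPE give a 6 × 4 matrix with
two-sided p-values from the t transform on \(n-2\) d.f., unadjusted across
cells (footnoted in the report). Shapiro–Wilk normality checks are
reported as diagnostics and logged on failure; they never switch the
pipeline to nonparametric tests. \(\alpha = 0.05\) throughout.

One calibration fact the tests document: under exact sphericity at
\(n = 8, k = 4\) the GG-corrected test is conservative — its measured size
is ≈0.03 rather than 0.05 (the uncorrected test holds ≈0.05). That is the
price of a correction that protects against sphericity violations, and it
is why corrected and uncorrected p-values are both reported.

When subjects give one RPE per set, the final-set value is used by default
for the correlations (mean and max aggregations are config switches): the
correlation design pairs one rating per subject with each feature, and the
final set is the one taken to exhaustion.

## What the synthetic generator emulates — and what it does not

Real recordings of this protocol are not publicly deposited, so the
package ships a generator whose outputs carry known ground truth at every
level:

* **Traces.** Baseline temperature + piecewise-linear phase trends +
  band-limited sinusoids + white Gaussian noise (SD 0.03 °C, the sensor
  NETD), clamped to a physiological 20–45 °C. The injected temperature
  change is spread as a linear ramp across the exercise sets, so the flat
  analysis windows recover it exactly up to noise. Oscillators default to
  band geometric centres — away from band edges, so leakage cannot blur
  which band owns the injected power — and are separately specifiable for
  the pre and post epochs, making \(\Delta PSD\) ground truth directly
  injectable (a sinusoid of amplitude \(A\) carries \(A^2/2\)).
* **Frames.** Each ROI is a rectangular patch (uniform or Gaussian-edged)
  over an ambient background, its profile normalised to mean 1 over the
  box so the in-box pixel mean equals the trace exactly before noise.
  Motion paths (linear drift, sinusoidal sway) are quantised to integer
  pixels per frame and the quantised path is stored as ground truth,
  giving the tracker an exact reference.
* **Cohorts.** Per-subject parameters are drawn from between-subject
  distributions; RPE is a noisy linear readout of chosen true features,
  rounded and clamped to 1–10. For a single coupled feature the slope and
  residual SD are derived from a target correlation by the standard
  \(\rho \to\) slope relation; rounding attenuates the realised correlation
  slightly (≈0.78 realised for a latent 0.8), which the recovery tests
  account for by construction rather than by widening bands.

The generator is statistical, not physiological: no heat diffusion,
perfusion, camera optics or calibration drift. Passing tests therefore
demonstrate that the *analysis chain* is correct and calibrated — that
band powers, window means, ANOVA geometry and correlations recover exactly
what was injected — not that the biology behaves like the model.

The built-in `paper_like` scenario fixes the study conditions: 8 subjects,
5-min baseline and recovery, three sets (60/50/40 s) with 3-min rests,
+1.5 °C injected on the exercised leg, mild nose-tip warming, near-zero
changes elsewhere, raised post-exercise neurogenic power on the facial
ROIs, raised myogenic power on the exercised leg, and RPE coupled to the
exercised-leg ΔT at latent r = −0.8. It runs at trace level: rendering
8 subjects × 4 ROIs × 1110 s × 10 Hz of 640 × 480 video is far beyond desk
scale and would add nothing to the feature/statistics chain, which
consumes traces. The rendered-video path is exercised end to end by the
shorter `tracking_demo` scenario (3 subjects, shortened windows, a drifting
ROI) and by the test suite's dedicated tracking scenes (600 frames of
160 × 120 at full 10 Hz).

## Degenerate inputs and numerical conventions

* Windows that do not fit the trace are errors naming the window; subjects
  whose timeline cannot support the windows are excluded with a logged
  reason, and an all-excluded cohort aborts the pipeline at the features
  stage.
* PSD inputs must match the declared window length exactly — no silent
  padding.
* Constant input to Shapiro–Wilk is an explicit degeneracy error;
  zero-variance cells in the correlation matrix are flagged, not fatal; a
  zero-variance pair in the post hoc grid yields t = 0, p = 1 when the
  difference is identically zero.
* Featureless (zero-variance) tracking frames give undefined correlation:
  every such frame is flagged and the position held.
* TIFF float samples live in [0, 1], so temperatures are affinely encoded
  (offset/scale in the JSON sidecar; ~5 × 10⁻⁶ °C quantisation). The
  CSV-per-frame dialect is lossless and round-trips bit-identically. Units
  are verified against the sidecar; anything but °C is an error, never a
  silent conversion.
* All synthesis functions seed a local RNG stream and restore the caller's
  state; identical config + seed gives bit-identical traces, frames, RPE
  and output files (checksummed in the run manifest).

## Known limitations

* The metabolic band is resolution-limited under the 5-min/150-s defaults
  (flagged, see above); conclusions about that band rest on its upper
  portion.
* The tracker is integer-pixel and template-based; it is validated for
  slow drifts up to the search radius per frame, not for fast motion,
  rotation or deformation.
* ΔT windows are 10 s: partial cycles of the slowest oscillations
  contribute up to their summed amplitudes to a window mean. This is a
  property of the protocol's window choice, visible in the generator's
  ground-truth comparisons.
* The LSD post hoc and the 24 correlation cells are intentionally
  unadjusted for multiplicity, matching the analysis convention this
  implements; the report footnotes it.
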