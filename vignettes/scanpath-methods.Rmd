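---
title: "Scanpath length as an index of threat conditioning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanpath length as an index of threat conditioning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threatgaze)
```

## The measurement problem

In delay threat conditioning, an initially neutral cue (CS+) is paired with
an aversive event (US, e.g. an electric shock) while a second cue (CS−) is
never reinforced. The strength of the learned CS–US association is inferred
from responses during CS presentation. `threatgaze` implements a
gaze-based index of this learning: **scanpath length**, the total angular
distance travelled by gaze over a time window before the (anticipated) US.
Conditioned participants fixate longer and more centrally during CS+, so
their CS+ scanpaths are shorter than CS− scanpaths. The package's
evaluation criterion is *retrodictive validity*: the effect size (Hedge's
*g*) with which a measure distinguishes CS+ from CS− trials.

Only non-reinforced trials enter statistics. Because blank stretches are
interpolated (below), a response to a delivered US can leak backwards into
the anticipation window; reinforced (CS+US+) trials are therefore epoched
but excluded from every statistic, and the label "CS+" in results always
means CS+US−.

## From pixels to scan speed

Gaze arrives as binocular pixel coordinates sampled uniformly (500 Hz in
the emulated setup) with per-sample blank flags marking blinks, saccades
and dropouts. The kinematic chain is:

1. **Eye selection.** The eye with fewer blank samples is analyzed; ties go
   to the left eye.
2. **Interpolation.** Blank stretches are linearly interpolated per pixel
   coordinate against time. Leading/trailing blanks are held at the nearest
   valid value — this keeps trials usable while injecting zero artificial
   motion. Interpolation happens in pixel space, before any angular
   transform.
3. **Physical coordinates.** Pixels (origin top-left, y down) map affinely
   to screen-centered millimeters (right and up positive); the pixel pitch
   is derived per axis from the configured half-extents and is not assumed
   square. The gaze vector gains a constant depth `z = distance_mm`
   (nasion assumed on the perpendicular through the screen center).
4. **Spherical angles.** Azimuth `theta = atan2(z, x)` (90° = straight
   ahead) and elevation `phi = atan(y / sqrt(x^2 + z^2))`. Radial distance
   carries no directional information and is discarded.
5. **Scan speed.** For each adjacent sample pair the great-circle central
   angle is computed with the Haversine formula — numerically stable for
   the sub-degree arcs between adjacent samples, where the arccosine of a
   dot product loses precision — and divided by the inter-sample interval
   (deg/s). The Haversine intermediate is clamped to `[0, 1 − 1e−12]`;
   near-antipodal pairs cannot occur for on-screen gaze. No filtering is
   applied to data entering statistics.

Each speed sample is assigned to the *later* sample's timestamp and
windows are half-open `[start, end)`, which makes windowed arc sums exactly
additive over window partitions. A step straddling a window boundary is
assigned whole by that convention; at 500 Hz the bias is at most one
sample and identical across conditions.

## The windowed scanpath statistic

Per trial, scanpath length is the sum of arcs over the final `window_s`
seconds before anticipated US onset (`cs_onset + soa`); the default window
is 2 s, the window that maximizes retrodictive validity in the emulated
design. Trial lengths are averaged per participant and condition, and the
CS+ − CS− differences feed the statistical battery. `window_sweep()`
recomputes the statistic over 0.5-s-step windows up to the SOA and reports
per window the absolute Hedge's *g* and a log Bayes factor relative to the
full CS–US interval.

## The gamma response function and GLM

As an alternative summary, scan speed is modeled as a linear time-invariant
system: the CS−-minus-CS+ difference of grand-mean scan speed is fitted
with an amplitude-scaled, shifted gamma density

$$y(t) = \frac{A}{\mu^{k}\,\Gamma(k)}\,(t - t_0)^{k-1}
  e^{-(t - t_0)/\mu}, \qquad t > t_0,$$

with onset latency $t_0$ (s, may be negative — the fitted response begins
before CS onset), shape $k$, scale $\mu$ (s) and amplitude $A$ (the
integral of the response; the mode sits at $t_0 + (k-1)\mu$ for $k > 1$).
Some sources print the scale of this density as $\theta$; it is the same
parameter as `mu` here. Fitting is ordinary least squares by Nelder–Mead
from a fixed 8-point start grid (onsets −3, −2, −1, 0 s crossed with
slow/fast shape–scale pairs (3, 1) and (10, 0.4)), shape and scale on the
log scale, relative SSR tolerance 1e−8, at most 5000 iterations per start;
the lowest-SSR solution is polished once more. The fitted series is the
*smoothed* difference (centered moving average, span ≈ 1 s, shrinking
symmetrically at the edges); smoothing is for visualization and response-
function development only — GLM inversion always uses raw speeds. The fit
range runs from CS onset to SOA + 2 s.

The response function then enters a general linear convolution model
$Y = X\beta + \epsilon$: one regressor per condition (unit impulses at CS
onsets convolved with the unit-area kernel, tail truncated below 1e−8 of
peak) plus an intercept. All three conditions are modeled so reinforced
trials are absorbed by their own regressor instead of contaminating
residuals; statistics use only the CS+US− minus CS− amplitude contrast.
For designs whose CS–US interval is 0.5 s longer than the one the function
was fitted on, the kernel is shifted 0.5 s rightward (`glm_shift_s`).

A note on identifiability: when the empirical difference series is a
nearly symmetric bump, the least-squares gamma drifts toward its Gaussian
limit (large $k$, small $\mu$, strongly negative $t_0$, with the mode and
width preserved). The kernel *shape* — which is all the GLM uses — remains
well determined; the individual parameters are then only weakly
identified. Parameter-recovery simulations at a trial-averaged noise
regime (Gaussian noise at 5% of peak) recover $t_0$, $k$, $\mu$ with 5–7%
median error.

## Fixation analyses

To characterize the mechanism (longer fixations, more central fixations
during CS+), fixation events — taken from the tracker's parsing or the
generator, never re-detected — are windowed to `[cs_onset, cs_onset +
soa)` by onset; a fixation spanning the anticipated US onset is kept with
its duration truncated at the boundary rather than dropped, so late
fixations are not systematically lost. Durations and Euclidean distances
from screen center are pooled across participants within condition and
compared between conditions with the two-sided two-sample
Kolmogorov–Smirnov test (asymptotic p). Heat maps bin fixations on a
64 × 48 grid over the physical screen; binning is presentation-only.

## The statistical battery

* **Paired t** (two-tailed) on per-participant CS+ − CS− differences.
* **Hedge's g** with the *exact* small-sample correction
  $J(a) = \Gamma(a/2) / (\sqrt{a/2}\,\Gamma((a-1)/2))$ evaluated via
  log-gamma, not the $1 - 3/(4a-1)$ approximation; $|g| = J(n-1)|t|/\sqrt n$
  holds as an identity.
* **BCa bootstrap CI** for g by participant resampling; degenerate
  (zero-variance) resamples are skipped and counted.
* **AIC-based log Bayes factors** for comparing candidate measures:
  each candidate's participant × condition values are z-scored, the
  Gaussian AIC (MLE mean and variance, so every candidate has the same
  parameter count) of the standardized paired differences is computed, and
  $\mathrm{LBF} = (\mathrm{AIC} - \mathrm{AIC}_{ref})/2$ (equal to the
  BIC-based value at fixed parameter count; smaller is better, reference
  exactly 0). The exact AIC construction behind this comparison is a
  package choice — published tables built "as in previous work" may use a
  different likelihood, so LBF values should be compared within one
  analysis, not across toolchains.
* **Sign-based classification accuracy**: the share of participants whose
  difference matches the sign of the group mean; exact zeros count against
  accuracy (conservative).
* **Consecutive-pair split-half reliability**: per condition, trials are
  paired consecutively (the latent association is assumed similar within a
  pair even while learning drifts), one trial of each pair is randomly
  allocated to each half, halves are averaged, CS+ − CS− differences are
  correlated across participants, and the mean correlation over (by
  default) 5000 allocations is reported; an odd trailing trial is dropped.
  Interpretation limit: with no true between-participant variance the
  expected correlation is zero regardless of measurement precision, so a
  low value does not by itself indicate a noisy measure.
* **Holm–Bonferroni** (via `p.adjust`) is available for the confirmatory
  multi-test report.

## The synthetic generator

`simulate_cohort()` emulates the recording conditions end to end so every
stage is testable without real data: 500-Hz binocular sampling; trials of
the three conditions in random order (default 16/16/32) with SOA 3.5 s, CS
4 s, uniform ITIs; gaze alternating between center-biased fixations
(gamma-distributed durations; mean 450 ms during ITI where a fixation
cross is shown, 280 ms during CS) and main-sequence saccades (duration =
21 ms + 2.2 ms/deg — conventional oculomotor constants, configurable
plumbing); saccade samples are *emitted but flagged blank*, mimicking the
exclude-then-interpolate treatment so the interpolation step is
consequential and testable; Poisson blinks masked as missing; isotropic
per-sample jitter (0.02°) and independent per-eye pixel noise.

The conditioning effect follows the observed mechanism: during the final
`effect_window_s` (default 2 s, the empirically optimal window) before
anticipated US onset of CS+ trials, fixation durations are multiplied by
`csplus_fix_mult` (default 1.3) and the center-bias SD by
`csplus_center_shrink` (default 0.7); per-participant effect strength
varies lognormally (`between_sd`, default 0.15). A fixation straddling the
effect-window start has its in-window remainder lengthened, so the
saccade-rate change is aligned with the window rather than lagging it by
one fixation.

Two generator facts matter for interpreting tests. First, the
duration mechanism produces a *step-confined* signal, while the
center-bias mechanism compounds over successive saccades and smears the
signal onset by roughly half a second; tests that require signal sharply
confined to the window therefore use the duration-only configuration.
Second, when true effects are heterogeneous across participants, the mean
and SD of the paired difference scale together with the captured signal,
flattening the expected |g| across sub-windows that contain the effect;
the window-localization property is therefore tested in the homogeneous,
measurement-noise-limited regime, and single-cohort window orderings are
noisy (the SD estimate at n = 20 has ~16% sampling error), so expected
orderings are asserted on profiles averaged over replicate cohorts.

What the generator does *not* emulate: pursuit and post-saccadic
oscillations, tracker-specific noise spectra and drift, learning dynamics
across trials (the effect multiplier is constant within a participant),
pupil or skin-conductance channels, and any US-evoked gaze response.
Passing tests therefore validate the pipeline's arithmetic and its
statistical behavior under the stated generative model, not the empirical
claim that real gaze behaves this way. The default effect sizes are also
deliberately strong (synthetic cohorts reach |g| ≈ 2–3, versus ≈ 0.4–0.7
in real data) so that direction and ordering properties are testable at
small simulated cohort sizes.

## Problem sizes and numerical choices

Simulated checks run at reduced scale chosen to keep the full suite fast
while leaving the tested properties identifiable: unit tests use cohorts
of 2–8 participants with 4–12 trials at 250 Hz; the null calibration runs
200 cohorts of 10 participants with 4 + 4 analyzed trials; the
window-sweep check averages 8 cohorts of 20 participants with 10 + 10
trials; reliability checks operate directly on trial-wise tables. Key
tolerances: Haversine vs arccos-dot-product agreement < 1e−9 deg on-screen;
pixel round trip < 1e−9 px; gamma integral to amplitude within 1e−6; GLM
noiseless recovery at 1e−10; the Haversine clamp at 1 − 1e−12; RF kernel
tail truncation at 1e−8 of peak. Degenerate inputs (all-blank eyes, zero
variance differences, empty conditions, rank-deficient designs, windows
exceeding the SOA or the recording) raise typed errors naming the
offending entity rather than propagating NaN.

## Known limitations

Gamma parameters are weakly identified for symmetric responses (above);
the AIC construction behind LBF is a documented package choice; fixations
are trusted from the input stream, so tracker parsing quality bounds the
fixation analyses; the split-half metric is depressed by trial-to-trial
learning dynamics and by homogeneous samples, by design of the underlying
procedure; and the synthetic generator's effect sizes are stronger than
typical empirical ones, so absolute effect magnitudes from simulations
should not be read as forecasts for real data.
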