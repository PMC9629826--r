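---
title: "Tuning stability and representational drift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning stability and representational drift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftlab)
```

## The scientific problem

Chronic two-photon calcium imaging in mouse primary visual cortex (V1) can
follow the same neurons across days. Two questions recur in such
longitudinal experiments: how stable is each neuron's stimulus preference,
and how stable is the population code as a whole — can a decoder trained on
one day still read out the stimulus from another day's activity?
`driftlab` implements the analysis chain for these questions on
trial-structured *event* data (deconvolved calcium transients, in units of
inferred event counts): tuning estimation with a permutation
goodness-of-fit test, population metrics (signal correlation, reliability),
KNN stimulus decoding with a set-based cross-validation, and a
fixed-classifier drift metric. A synthetic-data generator with full ground
truth makes every stage testable without experimental data, and the
end-to-end pipeline (`run_experiment()`) emulates a four-session
dark-exposure design (baseline B1, baseline B2, post-dark-exposure pDE,
recovery Rec).

## Stimulus space and the tuning model

Stimuli are static sinusoidal gratings on a lattice of 12 orientations
(0–165° in 15° steps; orientation is axial, period 180°) by 15 spatial
frequencies (0.02–0.30 cycles/° in 0.02 steps), 180 stimuli in total
(`default_grid()`). Stimulus indices run spatial-frequency-major, which is
also the confusion-matrix ordering.

A tuned neuron's mean event count for a grating at orientation $\theta$
and spatial frequency $\varphi$ is a bivariate Gaussian surface

$$R(\theta,\varphi) = \frac{A}{2\pi\sigma_\theta\sigma_\varphi\sqrt{1-\rho^2}}
\exp\!\left(-\frac{1}{2(1-\rho^2)}\left[
\frac{\Delta\theta^2}{\sigma_\theta^2} +
\frac{(\varphi-\mu_\varphi)^2}{\sigma_\varphi^2} -
\frac{2\rho\,\Delta\theta\,(\varphi-\mu_\varphi)}{\sigma_\theta\sigma_\varphi}
\right]\right) + B$$

with $\mu_\theta$ the preferred orientation, $\mu_\varphi$ the preferred
spatial frequency, $\sigma_\theta,\sigma_\varphi$ the tuning widths, $\rho$
the orientation–frequency correlation, $A$ an amplitude (integral)
parameter and $B$ the baseline event count. Because orientation is axial,
the residual $\Delta\theta$ is the wrapped difference mapped into
$(-90°, 90°]$, including inside the $\rho$ cross-term; the alternative
(raw linear differences) is available via `wrap = FALSE`. The exponent
uses the standard bivariate-Gaussian normalization $1-\rho^2$.

### Fitting and its numerical choices

`fit_tuning()` minimizes the squared error over *every single-trial*
observation (bounded Levenberg–Marquardt, `minpack.lm::nls.lm`), so the
resulting $R^2$ rewards trial-to-trial consistency, not merely the shape of
the trial-averaged map; single-trial $R^2$ values are accordingly much
lower than trial-averaged ones. Choices that matter:

* **Initialization.** $\mu_\theta$ starts at half the complex phase of the
  first circular moment on the doubled angle,
  $S=\sum_\theta \bar R(\theta) e^{2i\theta} / \sum_\theta \bar R(\theta)$
  (`init_orientation()`; undefined when the moment has zero magnitude, as
  for perfectly uniform responses). $\mu_\varphi$ starts at the grid
  frequency with the maximal trial-mean response at the nearest grid
  orientation, ties to the lower frequency (`init_sf()`). $B$ starts at
  the lower quartile of stimulus means, the amplitude at the observed peak
  above it, widths at 20° and 0.05 cycles/°, $\rho$ at 0.
* **Bounds.** $A \ge 0$ (the model describes excitatory peaks, not dips),
  $B \ge 0$ (events are counts), $\mu_\varphi$ within the presented range,
  $\sigma_\theta \in [1°, 180°]$, $\sigma_\varphi \in [0.001,
  \text{range width}]$ cycles/°, $\rho \in [-0.99, 0.99]$ (keeps
  $1-\rho^2$ away from zero). $\mu_\theta$ is optimized *unbounded* and
  reported mod 180, avoiding boundary artifacts for preferences near
  0°/180°.
* **Convergence.** `nls.lm` information codes 1–4 count as converged;
  non-converged fits are flagged and excluded from tuned pools rather than
  silently kept.

### Permutation significance

A neuron is *tuned* when its single-trial $R^2$ exceeds the 95th percentile
of a null distribution obtained by permuting stimulus labels jointly across
all (stimulus, trial) observations and refitting — 1000 permutations in the
full protocol (`n_perm`), scaled down in tests. Each permutation refit is
initialized from its own permuted data by the same data-driven rule as the
observed fit. This symmetry is essential: re-using the observed fit's
converged parameters to initialize the null refits looks harmless but
biases the null $R^2$ downward (the observed initialization has adapted to
the unpermuted noise pattern), and we measured a type-I error of ~25%
instead of the nominal 5% under that scheme. With symmetric
initialization the test is exchangeable under the null and holds its size
(~5%, verified in the acceptance suite).

### Bandwidths

Tuning bandwidths are reported as half-width at half-maximum. The default
`"as-printed"` mode uses $BW = 2\ln(2)\,\sigma$, the formula these
bandwidths are conventionally reported with in this analysis lineage; the
mathematically exact Gaussian HWHM, $BW = \sqrt{2\ln 2}\,\sigma$, is
available as `"hwhm-exact"` because the conventional formula is plausibly a
typeset loss of a square root. Both modes are linear in $\sigma$, so
between-condition *comparisons* of bandwidth changes are unaffected by the
choice.

## Preprocessing

* **Response window.** Responses are mean event counts over the frames in
  a 194–320 ms window after stimulus onset (`extract_responses()`). A
  frame belongs to the window when its *center* time lies in
  $[194, 320)$ ms; at the 15.5 Hz acquisition rate this selects the two
  frames starting ≈194 ms and ≈258 ms after onset. We chose the
  frame-center rule because the window bounds are printed in milliseconds
  while data arrive in frames, and a deterministic inclusion rule is
  needed; a start-time rule would exclude the ≈193.5 ms frame on a
  sub-millisecond technicality and reduce the window to a single frame,
  which contradicts the window's ≈2-frame width.
* **Trial exclusion.** Trials flagged for locomotion or eye blinks are
  removed (`filter_trials()`); a session in which any stimulus loses all
  trials is rejected with an error naming the stimulus. In the emulated
  design 36 trials are presented and roughly 25 survive exclusion, the
  floor used in the decoding analyses.
* **Responsivity.** A neuron is visually responsive when a one-way ANOVA
  of single-trial responses with stimulus as the factor gives
  $p < \alpha$. The default is $\alpha = 0.01$ (the analysis-level
  convention; exposed in `experiment_config()` because 0.05 is also in
  circulation for this screen). Degenerate all-equal data report $p = 1$.
* **Deconvolution.** For completeness of the synthetic path, `deconvolve()`
  inverts the generative fluorescence model $f = s \ast k + \beta p + b$
  by greedy matching pursuit with an L0 flavor: events (time, amplitude
  ≥ 0) are added one at a time at the position of maximal residual
  correlation with the kernel, $\beta$ and $b$ are refit by least squares
  after each sweep, and iteration stops when the residual variance reaches
  the noise-variance estimate (MAD of the first-differenced trace; the
  MAD of a differenced white-noise series divided by $\sqrt 2$ estimates
  the noise SD). The kernel is a causal single exponential with
  configurable $\tau$ (default 0.7 s, typical for GCaMP6f); only event
  amplitudes are fit, not the kernel shape — joint kernel estimation is
  out of scope. A hard cap of 5 sweeps per second of data bounds runtime
  on pathological traces.

## Population metrics

* **Signal correlation** between neurons $i,j$ is the Pearson correlation
  of their 180-long stimulus-averaged response vectors
  (`signal_correlation()`). Neurons with constant mean vectors have
  undefined correlations and are dropped with a warning.
* **Between-session similarity** of two signal-correlation matrices is the
  Pearson correlation of their vectorized *strict upper triangles*
  (`similarity()`); the diagonal of ones carries no information and would
  only inflate agreement.
* **Reliability** is the fraction of preferred-stimulus trials whose
  response is at least 2 SDs above the gray-screen baseline mean
  (`reliability()`). The preferred stimulus is the grid point nearest the
  fitted $(\mu_\theta, \mu_\varphi)$ — axial distance for orientation,
  linear for frequency. A zero-mean, zero-SD baseline degenerates the
  threshold to "any positive response".

## Decoding and drift

Population response vectors (one entry per neuron) are grouped into *sets*,
each containing exactly one trial of every stimulus (`make_sets()`); the
number of sets equals the number of trials used, with seeded random
subsampling when more are available. Cross-validation is leave-one-set-out:
the neighbors of a test vector are all vectors outside its set, so every
stimulus is equally represented in the neighbor pool. Classification is by
majority vote of the $k = 4$ nearest neighbors under Euclidean distance;
chance is $1/n_\text{stim}$ (0.0056 for 180 stimuli, 0.0167 and 0.0083 for
the 60-stimulus low- and 120-stimulus high-frequency splits at the
0.1 cycles/° boundary, inclusive on the low side). Ties are resolved
deterministically: distance ties by lower set index then lower stimulus
index; vote ties by the tied class whose nearest member is closest.

For cross-session comparisons, `subsample_match()` restricts sessions to
the shared tracked neurons (the identical subset everywhere) and matches
per-stimulus trial counts to the minimum across sessions.
`fixed_classifier_drift()` anchors a classifier to a training session:
`acc_X1` is its set-based cross-validated accuracy within that session;
`acc_X2` classifies every vector of a second session against *all*
training-session vectors (no set exclusion, since the test session shares
no sets with the training data); drift is `acc_X2 − acc_X1`. Testing a
session against itself uses self-exclusion and reproduces `acc_X1`
exactly.

Neuron identity across sessions comes from pre-aligned pixel masks
(`match_neurons()`): overlap is intersection-over-union — the stricter,
symmetric reading of "percentage of overlapping pixels", with
intersection-over-smaller available via `method = "min"` — thresholded at
0.75 and resolved greedily one-to-one by descending overlap.

## The synthetic generator

`generate_session()` emulates the statistical structure the analysis
assumes, not the raw imaging. Per neuron and trial:

* a tuned neuron is *responsive* on a trial with probability
  `reliability` (Bernoulli gating — an all-or-none model matching the
  reliability statistic's definition); responsive trials have mean
  $B + G(\theta,\varphi)$, others mean $B$; untuned neurons always $B$;
* counts are Poisson at that mean — the minimal noise model for event
  counts; trial-to-trial variance beyond Poisson is not constrained by the
  emulated experiments, so a variance-inflation factor (`dispersion`,
  default 1, negative-binomial above 1) is exposed rather than guessed;
* gray-screen baseline bins are Poisson at $B$; locomotion and blink flags
  are independent Bernoulli per presentation (defaults 0.2 and 0.1, so 36
  presented trials leave ≈26 — matching the ≈25-trial floor after
  exclusion);
* `noise = "none"` gives the deterministic mean surface, used by tests
  that need the noiseless limit.

`sample_population()` draws a population with a stated tuned fraction
(default 0.4, within the 30–50% responsive range typical of these
recordings), preferences uniform over stimulus space, widths 12–30° and
0.02–0.08 cycles/°, peak evoked responses of 2–6 events above baselines of
0.05–0.3 events per window, and reliabilities 0.6–0.9. These are the
package's standing defaults for "a realistic session"; tests and the
acceptance script use them unchanged.

`generate_experiment()` adds session-to-session structure: preferred
orientations drift between consecutive sessions by wrapped Gaussian jitter
(axial circle), reliabilities are scaled per session relative to the base
population, and a `reset = TRUE` session rebounds to first-session
parameters. The `default_schedule()` plants the qualitative dark-exposure
pattern: 12° control jitter (B1→B2), 4° jitter across dark exposure
(B2→pDE) with reliability scaled by 0.6, and recovery (Rec) back to full
reliability with 8° jitter. These planted effect sizes are the package's
chosen study conditions for end-to-end demonstrations; recovery tests
assert their *direction*, not their magnitude.

`generate_fluorescence()` closes the loop for the deconvolution path:
events convolved with the causal exponential kernel, plus scaled neuropil
(a slow AR(1) drift when none is supplied), baseline, and white noise.

## Statistics

`two_proportion_ztest()` implements the pooled two-sample proportions
Z-test (two-sided normal p-value; the one-sided variant is a trivial
halving and was not needed for any emulated contrast). `bh_adjust()` is
the Benjamini–Hochberg step-up via `stats::p.adjust`. `contrast()` adapts
`wilcox.test` / paired `t.test` into tidy records, reporting the exact
rank-sum statistic $U + n_1(n_1+1)/2$ alongside the Mann–Whitney $U$ for
small samples; identical paired samples (undefined t) are reported as "no
difference" rather than an error.

## The pipeline and reproducibility

`run_experiment()` chains every stage on a simulated four-session design
and emits a report (markdown, JSON, CSV tables). A single master seed fans
out to stage-specific child seeds by a stable string hash
(`child_seed()`), so any stage can be re-run in isolation and the whole
pipeline is byte-reproducible. Condition pairs follow the design: control
= B1→B2, DE = B2→pDE, LRx = pDE→Rec; drift is additionally computed for a
Rec-trained classifier tested on pDE.

Problem sizes in the shipped tests and acceptance script are deliberate
package choices balancing statistical resolution against a desk-scale run:
chance decoding uses 20 neurons × 12 trials on the full 180-stimulus grid;
the permutation-size simulation uses 500 null neurons × 200 permutations
on a compact 12-stimulus grid (the test's size property does not depend on
grid extent); orientation recovery uses 200 tuned neurons at the 25-trial
floor; drift calibration uses 20 replicate experiments of 24 neurons.

## What passing tests do and do not show

The generator reproduces the *assumed* statistical structure: Gaussian
tuning surfaces, Poisson-count noise, Bernoulli trial gating, independent
contamination flags, wrapped preference drift. Real recordings violate
several of these in known ways — correlated (noise-correlation) trial
variability across neurons, non-Poisson dispersion, slow within-session
drifts, eye-movement-linked response changes, and segmentation errors that
tracking inherits. Green recovery tests therefore certify the estimators
*given the model*, and calibration tests (type-I error, chance levels)
certify the inferential machinery; they do not certify that the model
captures any particular dataset. Known limitations: the tuning model is
unimodal in frequency and non-periodic (wrapped) in orientation, so
cross-shaped or bimodal receptive fields are summarized by a single peak;
the deconvolution fixes the kernel shape; mask matching assumes
registration upstream.
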