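---
title: "Sham-controlled TMS-EEG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sham-controlled TMS-EEG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-pulse transcranial magnetic stimulation (TMS) over a cortical target
evokes an EEG deflection time-locked to the pulse — the TMS-evoked potential
(TEP). The pulse, however, also clicks and taps: its auditory and
somatosensory side effects evoke a large peripheral evoked potential (PEP),
an N100–P200-like frontocentral complex that can dwarf the transcranial
response. A realistic sham condition that reproduces the peripheral
co-stimulation without stimulating cortex allows the PEP to be removed by
subtraction: the *cleaned* TEP is the active-condition evoked potential minus
the sham-condition evoked potential. `tepkit` implements the full sensor- and
source-level analysis chain around this design — simulation with known ground
truth, preprocessing, global field amplitude and time-window segmentation,
test–retest reliability mapping, cluster-based condition contrasts, and a toy
spherical-head source projection — so that every stage can be validated
against planted structure.

## The synthetic-data generator

`sim_config()` / `generate_dataset()` emulate a multi-participant (default
24), multi-session (3), two-condition (150 active + 150 sham trials) study.

Planted signals are separable Gaussian space-by-time components
(`make_component()`): a temporal Gaussian `exp(-(t - L)^2 / (2 w^2))` times a
spatial Gaussian in scalp distance from a center electrode, scaled to a peak
amplitude. Defaults:

* **PEP** (both conditions, identical within a session): N100-like −8 µV at
  100 ms (width 18 ms) and P200-like +6 µV at 200 ms (width 30 ms), centered
  at Cz with broad spatial scales (0.07–0.08 m). The premise that a matched
  sham saturates the peripheral response is encoded by using the *same* PEP
  realization in both conditions; an optional `pep_scale_sham < 1` models
  residual mismatch.
* **TEP** (active only): +3 µV at 30 ms, −2.5 µV at 45 ms, +2 µV at 60 ms,
  centered at the target electrode (default P3, a left-parietal site) with
  0.05 m spatial scale. All latencies are below 90 ms, before the peripheral
  complex peaks. Because the three components share a topography and
  alternate in sign, the combined waveform is biphasic with genuine
  near-cancellation times (around 45 ms at the defaults) where the planted
  field is weak — a property the reliability analysis has to live with, as
  real TEPs do.
* **Variability**: a log-normal per-participant amplitude scale (SD 0.2 on
  the log), a per-session latency shift (SD 2 ms) and a log-normal
  per-session amplitude jitter (SD 0.1), drawn once per participant/session.
* **Noise**: white sensor noise plus spatially correlated, temporally
  low-passed background (channel covariance Gaussian in inter-electrode
  distance, scale 0.04 m; temporal Gaussian kernel, SD 5 ms). The defaults
  (0.25 and 0.5 µV per trial) represent data *after* heavy artifact
  suppression, and are deliberately calibrated so that one default-size
  session recovers the planted TEP from the active-minus-sham difference
  with correlation above 0.9 over the 20–300 ms window — the package's
  stated recovery contract. Raw scalp EEG trial noise is one to two orders
  of magnitude larger; both SDs are ordinary configuration fields, and
  nothing downstream assumes their values.
* **Artifacts** (optional): an exponential decay `a exp(-t/tau)` (default
  30 µV, tau 50 ms) on channels near the target, emulating residual
  electrode polarization, and a random cubic drift per trial and channel.
* **Reproducibility**: one master seed; each participant-session consumes a
  deterministic substream, so generating any subset reproduces exactly the
  data that a full run would produce.

`simulate_evoked()` draws condition averages directly with noise SD divided
by `sqrt(n_trials)` — distributionally identical to averaging the trials (the
noise is Gaussian) and bit-identical in its templates, used where trial-level
structure is irrelevant and full trial simulation would dominate runtime.

Setting `shared_templates = FALSE` redraws component centers, latencies *and
polarities* per session. Randomizing polarity matters: with fixed signs, two
sessions' random topographies still correlate positively on average (both are
blobs of the same sign on the same head), which would bias the
no-reliability null.

What the generator does **not** emulate: ocular and muscle artifacts, the
TMS pulse artifact itself (the excision stage is exercised with synthetic
spikes), inter-trial dependence (ISI structure), reference drift, or any
cortical physiology. Passing tests therefore certify the statistical
machinery against the stated model, not performance on raw laboratory data.

## Preprocessing chain

`run_preprocess()` applies, jointly and identically to both conditions:
baseline correction (−1000..−5 ms), robust third-order polynomial detrending,
re-segmentation to −1000..1000 ms, decay removal, pulse excision (−4..17 ms,
cubic interpolation), anti-aliased resampling to 1 kHz, average
re-referencing, optional spherical-spline interpolation of listed bad
channels, condition averaging, and sham subtraction. All windows are
half-open `[start, end)`; the stage order and parameters are recorded in a
provenance log.

Numerical choices worth stating:

* **Detrending** fits by ordinary least squares to the samples outside the
  −20..600 ms evoked window and subtracts the polynomial everywhere. The
  robustness comes from the exclusion window, not from iterative
  reweighting; this keeps the stage deterministic and exactly removes its
  own model class.
* **Decay removal** profiles the time constant over a 120-point logarithmic
  grid in [1, 500] ms with parabolic refinement; amplitude and offset are
  closed-form given tau. By default one decay per channel is fitted on the
  trial average pooled across *both* conditions and subtracted identically
  from every trial. The alternative per-trial mode (`by = "trial"`) exists,
  but on data containing evoked responses the per-condition fits absorb
  evoked energy asymmetrically (the active condition contains the TEP, the
  sham does not) and can visibly distort the cleaned difference; a common
  subtraction cancels exactly in active-minus-sham, which is why it is the
  default. A fit is only applied where it improves the fit-window RMS by at
  least 5%, so decay-free channels pass through bit-identically.
* **Pulse excision** replaces the window by the Lagrange cubic through two
  anchor samples on each side: collinear anchors reproduce a line exactly,
  and all samples outside the window are untouched.
* **Resampling** uses a symmetric windowed-sinc FIR (cutoff 0.8 of the
  output Nyquist) applied centrally (zero phase), normalized to unit DC
  gain, with integer decimation keeping `t = 0` on the sample grid.
* **Spherical-spline interpolation** uses the standard order-4 spline with
  the Legendre expansion truncated at degree 7 and ridge regularization
  1e-5, on electrodes projected to the unit sphere.

## GMFA and time windows of interest

The global mean field amplitude is the population (divisor-K) standard
deviation of the voltage across electrodes at each sample. TOI segmentation
(`detect_tois()`) runs on the *mean* of the sham and active GMFA — a
selection statistic independent of the condition contrast later evaluated
inside the windows. Peaks need a minimum separation of 15 ms and a
prominence of at least 5% of the trace range (both configurable; the values
prevent 1 kHz noise ripple from spawning windows). If fewer than five peaks
are found, missing ones are recruited from extrema of the absolute
target-proximal evoked potential, mirroring the practice of reading early
deflections off electrodes near the target when they are invisible in the
global field. Window boundaries fall at the GMFA minima between adjacent
peaks; the first window starts at 20 ms and the last ends at 300 ms, so the
windows partition the analysis interval exactly. Ties in prominence break
toward earlier latency for determinism.

## Reliability mapping

Agreement between sessions is measured by Lin's concordance correlation
coefficient with divisor-n moments, `2*s12 / (s1^2 + s2^2 + (m1 - m2)^2)`;
unlike Pearson correlation it penalizes mean and scale shifts and satisfies
`|CCC| <= |r|`. Spatial maps take the CCC across electrodes at each time
point; temporal maps take it across time within each TOI (plus the whole
window) for each electrode. Values are Fisher z-transformed (`atanh`, inputs
clipped at `1 - 1e-12` so perfect agreement on noise-free fixtures stays
finite), averaged across participants and the three session pairs in
z-space, and back-transformed for display; per-pair group traces are also
returned, since figures conventionally plot them.

Group inference uses one-sample sign-flip permutation t-tests with t-max
family-wise correction: each of 2000 permutations flips whole participant
maps, preserving the within-map correlation structure, and contributes its
maximum |t|; corrected p-values get +1 smoothing so p is never zero. The
full sign-flip set is enumerated when `2^n` does not exceed the permutation
budget. Back-transformed group values are interpretable on the Shrout scale
(virtually no / slight / fair / moderate / substantial reliability).

## Cluster-based condition contrast

Within each TOI separately (large late responses would otherwise mask small
early ones), participant-paired t-maps over electrodes and time are
thresholded at the two-sided t critical value (p = 0.05, df = n−1);
supra-threshold elements of consistent sign are clustered under spatial
adjacency (electrode distance ≤ 5 cm at equal time) plus temporal contiguity
(adjacent samples at equal electrode), and each cluster's mass is its summed
t. The null distribution records, per sign family, the maximum cluster mass
over 2000 within-participant condition exchanges; positive and negative
families are each tested at alpha/2, and the per-tail level is further
Bonferroni-divided by the number of TOIs. The cluster statistic (maxsum) and
the connectivity rule are the conventional defaults of the nonparametric
cluster framework; both are explicit function arguments rather than
assumptions. Zero-variance elements are excluded from thresholding. The
per-permutation connected-components search is implemented in C++; the
observed-cluster path is plain R and is cross-checked in the test suite
against an independent graph library.

## Toy source projection

The forward model is the exact Legendre-series solution for a current dipole
inside three concentric spherical shells (inner skull 0.087 m, outer skull
0.092 m, scalp 0.100 m; conductivities 0.33, 0.0041, 0.33 S/m), truncated
when terms fall below 1e-8 relative; electrodes are projected radially to
the scalp sphere and the gain is average-referenced. In the
equal-conductivity limit it agrees with the closed-form homogeneous-sphere
solution (an independent derivation, also shipped) to better than 0.1%. The
radii are conventional adult-head values — a modeling choice of this
package, not a measured geometry.

The inverse is an l2-minimum-norm estimate with a distance-Gaussian source
covariance (`exp(-d^2/(2 lambda^2))`, lambda 0.01 m) and Tikhonov
regularization `lambda2 = trace(G C G') / (trace(N) snr^2)` with snr 3; the
noise covariance comes from the evoked baseline (−600..−100 ms), shrunk 10%
toward its diagonal, with an identity fallback when the baseline is exactly
silent. Estimates are z-scored against the baseline per source and averaged
within ROIs. The source space is a 200-point uniform random grid inside a
0.075 m ball with fixed random orientations — a desk-scale stand-in for a
cortical mesh. Minimum-norm solutions are depth-biased, and without depth
weighting (deliberately out of scope) deep sources localize poorly;
localization accuracy is therefore assessed at cortically plausible
eccentricity (about 0.065 m, i.e. 1–3 cm below the scalp), where the argmax
lands on the true source or one of its six nearest grid neighbors.

## Validation problem sizes

The shipped checks run at the following sizes, chosen as a balance between
statistical resolution and a suite that a maintainer will actually run:
oracle comparisons on 1000 random inputs; family-wise error of the t-max
procedure over 200 null experiments (400 in the acceptance script) of 20
participants by 100 elements; cluster calibration over 200 null and 50
effect experiments (20 participants, one 80 ms TOI, 2000 permutations each);
end-to-end TEP recovery over 4 participants at the full default trial count;
reliability discrimination at the full default study size (24 participants,
3 sessions) using direct evoked-level simulation. Binomial counting noise at
these sizes is the reason calibration checks accept rates up to 7.5% for a
nominal 5% procedure.

## Known limitations

* The generator's trial noise represents post-cleaning residuals; the
  package contains no ocular/muscle artifact handling (the corresponding
  laboratory-pipeline stages are out of scope here).
* Condition-blind stages are the only defense against processing bias; the
  decay fit is the one data-adaptive stage, and its default mode is
  condition-symmetric by construction.
* The spherical head model and random source grid support method validation,
  not anatomical inference.
* Temporal reliability within very short TOIs rests on few samples and is
  accordingly noisy; the whole-window column is the stabler summary.
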