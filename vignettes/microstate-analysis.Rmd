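---
title: "EEG microstate analysis with microstatr: model, choices, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG microstate analysis with microstatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Resting-state EEG spends most of its time in one of a handful of *microstates*:
periods of roughly 60–120 ms during which the spatial distribution of the scalp
potential (the *topography*) stays quasi-stable before switching abruptly to
another configuration. The topographies recur, and across healthy and clinical
cohorts four to seven template classes (conventionally labeled A–E) describe
most of the signal. Because the underlying generators oscillate, a topography
and its sign-flipped mirror are the same state: every comparison in this
package is *polarity-invariant*, i.e. uses the absolute spatial Pearson
correlation between maps.

The pipeline implemented here is the standard two-stage procedure:

1. **GFP peaks.** The global field power, `GFP(t) = spatial SD of the
   potentials at time t` (population formula, divisor = channel count), indexes
   the instantaneous topographic signal-to-noise. Clustering input is restricted
   to strict local maxima of GFP ([`detect_gfp_peaks()`]); peaks on or adjacent
   to artifact-masked samples are discarded.
2. **Polarity-invariant modified k-means** ([`modified_kmeans()`]). Maps are
   assigned to the template with the highest `|corr|`; each template is updated
   as the first principal component of its assigned maps, the polarity-invariant
   analogue of the centroid (the mean of sign-aligned maps is exposed to sign
   ambiguity; the dominant eigenvector is not). Convergence is declared when
   the global explained variance (GEV) changes by less than `tol` (default
   1e-7); the best of `n_restarts` random initializations by GEV is kept.
   Empty clusters are re-seeded from the worst-fitting map.
3. **Two-stage templates** ([`group_templates()`]). Each subject's peak maps
   are clustered first; the subject-level templates (unit-norm, hence
   GFP-normalized — each subject votes equally) are pooled and re-clustered to
   give group templates. Group solutions from different cohorts are compared
   with an exact assignment match ([`match_templates()`]).
4. **Back-fitting** ([`backfit()`]). Every sample of the full recording is
   labeled winner-takes-all with the template of highest `|corr|`, *provided*
   the correlation exceeds 0.5; otherwise the sample stays unlabeled. Masked
   samples are never labeled. "More than 50%" is read strictly: a correlation
   of exactly 0.5 stays unlabeled. Argmax ties break toward the lowest
   template index, deterministically. No temporal smoothing or
   minimum-duration rejection is applied by default.
5. **Temporal parameters** ([`temporal_parameters()`]). Per map:
   * `GEV` — `sum(gfp^2 corr^2)` over the map's samples divided by
     `sum(gfp^2)` over *all unmasked samples*, labeled or not. Keeping
     unlabeled samples in the denominator makes GEV a fraction of the total
     signal variance, so the per-map values sum to at most 1.
   * mean duration (ms) — average length of the map's runs; a run is a maximal
     constant-label stretch, terminated by unlabeled samples or mask
     boundaries. Runs truncated by a mask still count: dropping them would
     bias durations downward in artifact-rich recordings.
   * time coverage (%) — the map's share of unmasked samples ("percentage of
     total time", so the denominator is all unmasked time, not labeled time).
   * occurrence (1/s) — runs per second of unmasked time.
6. **Syntax** ([`transition_counts()`], [`observed_vs_expected()`]).
   Transitions are counted between *directly adjacent* labeled runs
   (`bridge = 0` samples by default): a transition across an excluded artifact
   or unlabeled gap is unobserved, not evidence. Observed row-stochastic
   probabilities are divided by the occurrence-expected ones,
   `E[i, j] = c[j] / sum(c[m != i])` with `c` the per-state coverage
   proportions; under a memoryless sequence the normalized matrix is exactly 1
   (property-tested), so departures from 1 isolate genuine sequential
   structure. Coverage is the default base measure; occurrence rates can be
   substituted (`base = "occurrence"`).

## Statistics

Group comparisons of the 20 map × parameter values use an unpaired test gated
by normality: Welch's t-test if both samples pass the D'Agostino–Pearson
omnibus test at alpha 0.05, Mann–Whitney otherwise, with Benjamini–Hochberg
FDR over the block of 20. (The omnibus test is implemented from the standard
skewness and kurtosis z-approximations and agrees with scipy's reference
implementation to 10 decimals on frozen fixtures.) The test's validity floor
is n = 8; smaller samples fall back to Mann–Whitney with a warning. Welch
rather than pooled-variance is the default wherever an unpaired t-test
appears, because group sizes and variances differ; pooled is available via
`var_equal = TRUE`. Transition edges are always compared with t-tests (one
block of K(K−1) FDR-corrected edges). Clinical correlations use Pearson or
Spearman by the same gate, pairwise deletion with a floor of 8 complete
pairs, and FDR within each instrument block (ADOS, MSEL, CBCL — block =
score-name prefix). Published tables that report only (mean, SD, N) are
re-checked with `welch_t_from_moments()`, which is exact: Welch's statistic
is a function of the moments alone.

`bootstrap_power_curve()` resamples n subjects per group *with replacement*
(the natural reading of "bootstrapped sub-samples", and the only choice that
allows n up to and beyond the group size) for n = 3..47, 500 replicates per
n, and reports the fraction of significant t-tests at alpha 0.05.
`detection_rate_from_moments()` is the moments-only counterpart: Gaussian
surrogate groups at published (mean, SD), used to re-check published
50%-detection sample sizes.

## The synthetic cohort generator

`simulate_cohort()` exists so every stage can be validated against known
ground truth. Its defaults are the study conditions of a published toddler
ASD/TD cohort: 110 channels, 125 Hz, 300 s per subject, five classes, group
sizes 66/47, 10% artifact-masked time. Baseline (TD) per-map mean durations
(71.9, 68.9, 83.9, 69.3, 69.6 ms) and relative entry rates (proportional to
the published TD occurrence rates) come from the same cohort's printed group
means, and the "ASD" effect multiplies map B's duration by 72.48/68.86 and
its entry rate by 2.398/2.092 — the published group-mean ratios.

Design choices that matter:

* **Semi-Markov, not first-order Markov.** Run durations are explicit
  (gamma, shape 2 — positive and right-skewed) and the next state is drawn
  from entry weights excluding the current state. Duration and occurrence are
  therefore independently controllable, which a plain transition matrix does
  not allow.
* **Dipole templates on a Fibonacci-sphere montage.** Maps are potentials of
  randomly placed dipoles inside a spherical head, redrawn until pairwise
  `|corr| < 0.7`; smooth, mean-zero, and free of real electrode coordinate
  files.
* **Carrier with an amplitude floor.** Each run's topography rides a 10 Hz
  sinusoid whose sign alternation exercises polarity invariance. The carrier
  magnitude is floored at 0.4 (`sign(sin) (0.4 + 0.6 |sin|)`): a pure
  sinusoid vanishes at every zero crossing, leaving pure noise below the 0.5
  labeling floor twice per cycle and fragmenting every run — an artifact of
  the toy waveform, not of real broadband EEG, where residual activity keeps
  the topography identifiable through oscillation nulls.
* **Spatially correlated noise** (exponential covariance over sensor
  distance) scaled so mean noise GFP = mean clean GFP / `snr` (default 3).
* **Between-subject variability** as lognormal jitter of per-map durations
  (cv 6%) and entry weights (cv 18%), plus additive topography jitter
  (sd 0.3 before renormalization) — magnitudes chosen so simulated cohorts
  show between-subject SDs of the same order as the published group summaries.
* **Clinical scores** are drawn per group at the published (mean, SD) with
  missingness matching the published assessed fractions, and selected scores
  are linearly coupled to true parameters (by default: affective problems ↔
  map-B coverage, fine-motor DQ ↔ map-D coverage negatively, social-affect
  severity ↔ map-E duration negatively) so correlation analyses have known
  effect directions.

What the generator does *not* emulate: 1/f broadband spectra, ocular/EMG
artifact waveforms, volume-conduction forward models, bad channels, or
montage reduction. Passing recovery tests therefore demonstrates the
correctness of the algorithms under controlled conditions, not robustness to
every nuisance of real recordings; preprocessing beyond band-pass, notch,
resampling and average-referencing (ICA, interpolation, spatial filtering)
is deliberately out of scope, with the artifact mask standing in for it.

## Numerical choices

* Filters: 4th-order Butterworth band-pass (1–40 Hz) and 2nd-order ±2 Hz
  notch (50 Hz), both forward–backward (`filtfilt`) so microstate boundaries
  are not shifted by filter latency. Resampling is zero-insertion polyphase
  with a zero-phase FIR anti-alias filter; the artifact mask is resampled by
  logical OR over each source window, so artifacts can only grow, never
  shrink. Masks are kept as masks — samples are never deleted — so run-length
  logic always sees one coherent timeline.
* GFP peaks use strict inequalities; equal-valued plateaus yield no peak
  (deterministic; ties are measure-zero in floating data).
* Cluster-number selection ([`select_optimal_k()`]) scores each k with five
  criteria — Krzanowski–Lai, the cross-validation criterion, mean silhouette
  on the `1 − |corr|` distance, Davies–Bouldin, and a GEV-elbow — and takes
  the median of the per-criterion optima, ties broken downward. This is a
  configurable approximation of the multi-criterion "meta-criterion" used by
  microstate toolboxes, whose exact seven constituent criteria are not
  standardized. Degenerate inputs (all maps identical up to sign) return
  `min(k_range)` with a warning.
* Restart seeds derive from one master seed; results are reproducible given
  `(seed, n_restarts)`.
* Template labels A–E are attached by matching against idealized canonical
  topographies on the sensor layout; labeling is cosmetic and never affects
  numerics.

## Validation scale

The test suite and acceptance script validate end-to-end recovery on a
reduced cohort — 12 + 10 subjects, 90 s each, at the default 110 channels,
SNR and effect sizes — where the pipeline recovers the generating templates
at `|corr| > 0.99` and all four temporal parameters at `r > 0.99` against
ground truth, and the criterion ensemble returns k = 5. Property tests use
smaller fixtures (20–60 channels, tens of seconds). Moment-based checks
(Welch tests from printed summaries, Gaussian-surrogate detection rates) run
at the published group sizes, since they need no raw data.

## Known limitations

* The meta-criterion ensemble approximates, but is not identical to, any
  specific published seven-criterion aggregate; on cleanly separated data
  all five constituent criteria agree.
* With between-subject variability at the published magnitudes, a weak
  effect (d ≈ 0.6) among 20 FDR-corrected comparisons is detected in a
  majority but not the near-totality of simulated cohorts; only the d ≈ 0.85
  effects are near-certain detections at n = 66/47.
* EDF support is a minimal continuous 16-bit codec for interchange of
  simulated data, not a general EDF+ reader.
* `match_templates()` solves the assignment exactly by enumeration for
  K ≤ 8.
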