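# microstatr

EEG microstate analysis for developmental cohorts: segmentation of
resting-state EEG into quasi-stable scalp topographies, their temporal
dynamics, and the group statistics used to compare clinical populations.

Resting-state EEG alternates among a small set of template topographies
("microstates", classes A–E) on a ~100 ms timescale. Differences in how long
a class persists, how often it appears, and which class follows which have
been reported as markers in neurodevelopmental conditions — for instance an
over-expression of microstate class B in toddlers with autism spectrum
disorder relative to typically developing peers. `microstatr` implements the
full analysis chain for such studies, plus a ground-truth cohort simulator
so every stage is testable without access to raw clinical recordings.

## What it computes

* **Preprocessing** — Butterworth band-pass (1–40 Hz) + notch, zero-phase;
  polyphase down-sampling (e.g. 1000 → 125 Hz); average re-referencing;
  artifact handling by mask, never by sample deletion.
* **Global field power** — `GFP(t) = sqrt(mean_i (v_i(t) − v̄(t))²)`, with
  clustering input restricted to strict GFP local maxima.
* **Polarity-invariant modified k-means** — maps assigned by maximal
  `|Pearson spatial correlation|`; templates updated as the first principal
  component of their members; best-of-restarts by global explained variance
  `GEV = Σ gfp²·corr² / Σ gfp²`. Subject-level templates are pooled into a
  second, group-level clustering; cluster number is chosen by a five-criterion
  ensemble (Krzanowski–Lai, cross-validation, silhouette, Davies–Bouldin,
  GEV-elbow; median of the per-criterion optima).
* **Back-fitting** — winner-takes-all labeling of every sample with a strict
  0.5 correlation floor; unlabeled and masked samples excluded.
* **Temporal parameters** — per map: GEV, mean duration (ms), time coverage
  (%), occurrence (1/s).
* **Markov syntax** — observed transition probabilities between adjacent
  runs, divided by occurrence-expected ones (`E_ij = c_j / Σ_{m≠i} c_m`);
  the normalized matrix is exactly 1 under memoryless switching.
* **Statistics** — D'Agostino–Pearson-gated Welch t / Mann–Whitney with
  Benjamini–Hochberg FDR (20 map × parameter tests); Pearson/Spearman
  clinical correlations FDR-corrected per instrument; Welch tests
  reconstructed from printed (mean, SD, N) summaries; bootstrap subsampling
  power curves (n = 3..47, 500 replicates).
* **Synthetic cohorts** — semi-Markov generator with dipole-based templates,
  polarity-alternating carrier, spatially correlated noise, group effect
  specs and clinically coupled score tables, all with exact ground truth.

## Worked example

```r
library(microstatr)

## simulate a small cohort (ASD-like effect on map B, known ground truth)
cfg <- sim_config(duration_s = 60, n_asd = 8, n_td = 8, seed = 42)
cohort <- simulate_cohort(cfg)

## two-stage clustering + back-fitting
res <- run_pipeline(cohort$recordings, k = 5, n_restarts = 10, seed = 42)
res$group_solution
#> <cluster_solution> k = 5, GEV = 0.928, 80 maps clustered

## recovered templates vs the generating ones (polarity-invariant match)
(m <- match_templates(res$group_solution$templates, cohort$templates))
#>   label_a label_b      corr
#> 1      M1       A 0.9969847
#> 2      M2       B 0.9977657
#> 3      M3       E 0.9972337
#> 4      M4       D 0.9976256
#> 5      M5       C 0.9967252

## group comparison of map-B dynamics, FDR over all 20 tests
params <- res$params
params$map <- m$label_b[match(params$map, m$label_a)]
asd <- params[grepl("^asd", params$subject_id), ]
td  <- params[grepl("^td",  params$subject_id), ]
cmp <- compare_groups_fdr(asd, td)
subset(cmp, map == "B", c(parameter, test, mean_a, mean_b, p, q))
#>          parameter test     mean_a     mean_b          p         q
#> 5              gev    t  0.1592803  0.1454819 0.11983190 0.4585873
#> 6 mean_duration_ms    t 71.9687632 65.4675364 0.04628204 0.2562350
#> 7     coverage_pct    t 18.9199879 17.2918522 0.13757618 0.4585873
#> 8 occurrence_per_s    t  2.6200060  2.6598212 0.72718309 0.9775115
```

The injected map-B duration elevation shows (71.97 vs 65.47 ms, raw
p = 0.046) but cannot survive FDR at 8 subjects per group — exactly what the
subsampling analysis predicts:

```r
bootstrap_power_curve(asd$mean_duration_ms[asd$map == "B"],
                      td$mean_duration_ms[td$map == "B"],
                      n_min = 4, n_max = 8, step = 2, reps = 500, seed = 1)
#>   n likelihood
#> 1 4      0.234
#> 2 6      0.436
#> 3 8      0.572
```

At the published full-cohort scale the effect is unambiguous; the printed
summary statistics alone settle it:

```r
w <- welch_t_from_moments(72.48, 4.748, 66, 68.86, 3.500, 47)
sprintf("Welch t = %.2f, df = %.1f, p = %.2g", w$t, w$df, w$p)
#> [1] "Welch t = 4.66, df = 110.8, p = 8.7e-06"
```

See `vignettes/microstate-analysis.Rmd` for the model, the design decisions
and the generator's assumptions.

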