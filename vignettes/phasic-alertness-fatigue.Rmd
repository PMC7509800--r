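---
title: "Methods: from phasic-alertness BOLD responses to a fatigue correlate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from phasic-alertness BOLD responses to a fatigue correlate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phasicfmri)
```

## The model

A warning cue that announces a possible upcoming stimulus produces a
short-lived rise in readiness — phasic alertness. In BOLD fMRI this shows
up as activation of task-positive frontoparietal cortex (central executive
network, CEN) and deactivation of the default mode network (DMN). The
question this package operationalizes is whether the *magnitude* of those
cue-evoked responses covaries, across patients, with self-reported fatigue
(MFI-20).

The analysis chain is:

1. an event-related design with cue-only (`CUE`) and cue-plus-stimulus
   (`CUE_STIM`) trials — only the cue-only trials isolate alertness-related
   activity uncontaminated by motor response and stimulus processing;
2. a voxelwise GLM whose two task regressors are event boxcars convolved
   with the canonical double-gamma HRF, with a discrete-cosine (DCT)
   high-pass basis and intercept as nuisance;
3. percent signal change (PSC) per voxel, averaged over the cubes of a
   systematic 15-mm grid parcellation, selected by a group-level hotspot
   rule and allocated to CEN (positive mean response) or DMN (negative);
4. Spearman rank correlation of per-subject network PSC with MFI-total
   under a two-main-test Bonferroni scheme with conditional follow-ups.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| trial duration | 4 | s | cue at t = 0 (1.5 s), stimulus at t = +2 (1.5 s); fixed sub-onsets |
| runs x trials | 4 x (20 + 20) | — | composition drives regressor statistics; run length is *derived* as trials x duration |
| rest blocks | 5 x 20 | s | runs are enveloped: n_runs + 1 rest blocks form the baseline |
| TR | 2 | s | volume acquisition time |
| HRF | delays 6/16, dispersions 1/1, ratio 6, 32 s window | s | canonical double-gamma defaults |
| high-pass cutoff | 128 | s | DCT order floor(2T/cutoff) |
| ROI edge | 15 | mm | 3375 mm^3 cubes, at most 125 voxels of 3 mm |
| selection threshold | \|T\| >= 4 | — | reproducible proxy for visual hotspot inspection at the customary display threshold |
| alpha | 0.05 | — | two main tests at alpha/2 |

Timing note: the published description of this paradigm is internally
inconsistent (112-s runs vs 40 trials x 4 s). Trial counts are treated as
authoritative; every timing field is configurable, and the default session
is 740 s (370 volumes at TR 2).

## The synthetic-data generator

`synthesize_cohort()` is a forward model of exactly the assumptions the GLM
makes, with known ground truth:

- voxel time series = 1000 x (1 + amp/100 x task + drift + AR(1) noise),
  baseline 1000 arbitrary units;
- the planted regressor is **mean-centered**, so "amp" is a percentage of
  the voxel's temporal mean — the same denominator the PSC transform uses.
  Without this the planted response would shift its own baseline and the
  noiseless forward-inverse identity would hold only to ~amp^2;
- AR(1) noise: stationary SD `noise_sd_pct` (default 1% of baseline),
  lag-1 coefficient 0.3;
- drift: a slow cosine (default period 300 s, amplitude 0.5%) with a
  **voxelwise** random phase and a period jittered by +/-25% per voxel. A
  single session-global drift phase would induce a common GLM error across
  all voxels of an ROI that does not average out and visibly attenuates
  cohort-level correlation recovery; spatially varying drift is also the
  physically realistic choice;
- planted amplitudes: +0.10% (CEN) and -0.10% (DMN) of baseline, the scale
  of the observed group means; between-subject SD 0.08% (an SEM of 0.01% at
  n = 63);
- fatigue coupling: per-subject DMN amplitude and MFI-total are drawn from
  a Gaussian copula. The copula's Pearson parameter is calibrated so the
  *expected sample* Spearman correlation at the cohort's n equals
  `planted_rho` (exact bivariate-normal expectation, inverted numerically),
  rather than using the asymptotic 2 sin(pi rho / 6) map, which would leave
  a ~1% downward bias at n = 63. CEN amplitudes are drawn independently
  unless `cen_rho` is set;
- MFI-totals are rounded to the 20..100 integer scale (latent mean 55,
  SD 15 — a wide, realistic spread) and decomposed into 20 item responses
  that score back *exactly* under the configured key;
- tumor masks are ellipsoids rasterized on the voxel grid; volumes follow
  from voxel counts exactly.

What the generator does **not** emulate: physiological (cardiac or
respiratory) noise, subject motion, spatial noise correlations, anatomical
variability, susceptibility dropout. A green recovery test therefore
establishes that the estimator chain is correct and well calibrated *under
its own assumptions*, not that it is robust to everything real scanners do.

## Numerical and design choices

- **PSC convention.** The analysis names no formula; the implemented
  convention is unit-peak task regressors with `psc = 100 beta / mean(y)`,
  the dominant convention for this kind of pipeline. Voxels with
  non-positive baseline are excluded and reported.
- **OLS without prewhitening.** Noise autocorrelation is not whitened
  (none is described for the source analysis); with AR(1) of 0.3 the betas
  are unbiased and only their nominal variances are off. A limitation, not
  a bug.
- **High-pass reality check.** A pure 300-s-period sinusoid is *not*
  annihilated by the finite DCT basis: worst-case leakage into a task beta
  is about 6% of the drift amplitude (23% without the basis). Tests assert
  the truthful contract (< 10% and at least a threefold reduction).
- **Regressor collinearity.** With trials stacked back-to-back inside
  runs, the two task columns are intrinsically anticorrelated (|r| ~ 0.6
  at the default composition). Randomizing trial order reduces |r| relative
  to a blocked ordering and keeps the GLM well conditioned, but full
  decorrelation is unattainable in this paradigm; tests assert the former.
- **Grid anchoring.** The grid origin is snapped per axis to a multiple of
  the edge length at or below the minimum voxel-center coordinate, which
  puts x = 0 on a grid plane. That makes the mirror rule exact: reflecting
  an ROI center x -> -x lands on another ROI center whenever the mask is
  symmetric. Sheared affines are rejected. The full-brain reference count
  of 628 ROIs is mask-dependent and intentionally not enforced.
- **Selection rule.** "Visual inspection of hotspots" is replaced by the
  reproducible rule: ROI-mean group |T| >= 4 (the display threshold),
  followed by mirror completion. Group-level maps (not per-subject maps)
  drive both selection and the mirror decision.
- **Degenerate group variance.** Identical maps across subjects give
  SEM 0; the t map then reports a signed infinity sentinel (p = 0) for a
  nonzero mean and 0 (p = 1) for an all-zero voxel.
- **Tie at zero.** An ROI whose group-mean PSC is exactly 0 is allocated
  to neither network and flagged.
- **Per-subject tumor overlap.** The published denominator is garbled; the
  implemented statistic is
  100 x (tumor voxels inside selected ROIs) / (total voxels of selected
  ROIs), bounded in [0, 100] and monotone in mask growth.
- **Conditional correction.** All follow-ups of one main test form one
  family: domains, subgroups, and member ROIs are uncorrected (alpha) when
  that main test survives its alpha/2 test, and Bonferroni-corrected within
  the family when it does not. The exploratory per-ROI table additionally
  flags significance at alpha / n_rois regardless of parent outcome —
  across many ROIs an uncorrected 0.05 threshold would make "all
  significant ROIs lie in the DMN" vacuously fragile.
- **Subgroup df.** Reports always use df = n - 2 with the subgroup's own
  n; published r(df) values for subgroups are internally inconsistent and
  are not reproduced.
- **P-values.** Spearman p-values use the t approximation (adequate at
  n = 63); a seeded permutation option exists for small samples.

## Scaled-down validation runs

The Monte-Carlo acceptance tests run on 1 CPU inside a test-time budget, so
they scale *replication counts and scene size* down, never thresholds:

- recovery of planted rho 0.47 (n = 63): 120 cohorts (nominal 500), 30-mm
  geometry, a 3 x (15 + 15) design, planted seed networks (`select =
  FALSE`). Recovery is defined conditional on correct network labels;
  data-driven hotspot selection is separately power-tested at the full
  design scale with 12-mm smoothing, where it has the SNR the full paradigm
  provides. The band [0.42, 0.52] is unchanged.
- family-wise type-I control: 350 null cohorts (nominal 1000) with the
  95% binomial interval computed at 350.
- DMN selectivity: 50 runs (nominal 100), subset condition unchanged.

The remaining attenuation of the recovered correlation (about 0.44
recovered for 0.47 planted, within the stated band) is the genuine
signature of GLM measurement error at the scaled-down design, plus the
finite-sample bias of the Spearman estimator itself.

## Known limitations

- No realignment, coregistration, normalization or slice-timing: synthetic
  sessions are generated aligned, and real-data preprocessing is out of
  scope.
- OLS variance estimates ignore temporal autocorrelation (see above).
- The NIfTI-1 reader/writer covers the little-endian single-file subset
  this package writes; it is not a general NIfTI implementation.
- Partially missing questionnaires are rejected, not pro-rated.
- The MFI-20 item key ships as editable YAML; the scoring engine treats the
  key as configuration and validates only its structure (20 items, five
  4-item domains).
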