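---
title: "Discovering and evaluating plasma lipid biomarker panels"
author: "lipidscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and evaluating plasma lipid biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscreen)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) is usually detected late, and the one
approved serum marker, CA19-9, is too insensitive for screening. Tumor lipid
metabolism leaves a signature in the plasma lipidome, which motivates a
screening strategy built on targeted lipid quantitation: find lipid species
whose plasma concentration separates cancer patients (PC) from healthy
controls (NM), verify that the separation holds up in an independent cohort,
and combine the survivors into a multivariable classifier, with and without
CA19-9 as a covariate.

`lipidscreen` implements that workflow end to end:

1. **Non-targeted screen.** Metabolomic features (accurate mass, retention
   time, ionization mode, log10 peak areas) are scored per feature by ROC
   AUC in human and in mouse plasma; features discriminative in both species
   are matched across species by accurate mass (ppm tolerance) and retention
   time, which nominates the lipid classes worth quantifying.
2. **Targeted quantitation.** MRM panel tables (samples × lipids,
   internal-standard-normalized concentrations, platform annotations) are
   cleaned by ordered exclusion rules; missing values are excluded, never
   imputed.
3. **Concordance selection.** Each lipid's AUC is computed in cohort A, in
   the independent cohort B, and in the pooled set C; only lipids with
   AUC at or above a threshold (default 0.75) *simultaneously in all three*
   survive. Lipids that pass within each cohort but fail the pooled set are
   flagged as batch effects. The panel is then restricted to the modal
   platform and ordered by descending pooled AUC.
4. **Panel modeling.** The pooled set is split 7:3 by class; logistic
   regression models are fit cumulatively — top two markers, then top three,
   and so on — recording the validation AUC at every step, once without and
   once with CA19-9. The panel's performance is summarized as the mean
   validation AUC over the steps with 11 or more markers (the plateau).

## The statistics underneath

**AUC.** For marker values $x$ and class labels, the package computes the
normalized Mann–Whitney statistic
$\mathrm{AUC} = \Pr(X_{PC} > X_{NM}) + \tfrac12 \Pr(X_{PC} = X_{NM})$
via midranks; ties contribute 1/2 (the standard convention). Markers may
discriminate in either direction, so the per-marker screen uses
`direction = "auto"`, reporting $\max(a, 1-a)$ together with the resolved
orientation; model probabilities always use the fixed `higher_in_PC`
direction. The empirical ROC curve sweeps every distinct cutoff and
integrates by trapezoids, which reproduces the midrank AUC exactly — no
binormal smoothing. For a marker that is normal in both classes with unit
variance and standardized mean shift $d$, the population AUC is
$\Phi(d/\sqrt{2})$; this identity is the backbone of the generator's
calibration and of the recovery tests.

**Exclusion rules.** Order matters and is fixed: (1) a sample missing an
entire platform (assay failure) is dropped; (2) a sample missing CA19-9 is
dropped when the analysis uses CA19-9; (3) a lipid still missing in more
than `lipid_missing_frac_max` (default 0) of the *remaining* samples is
dropped. Evaluating lipid missingness after the sample drops is what keeps
one platform-failure sample from dragging its platform's entire lipid list
out of the panel.

**Split.** Within each class, the training count is round-to-nearest
(half-up) of `train_fraction` × class size. With 164 NM and 180 PC at 0.7
this gives 115/126 training and 49/54 validation samples — the unique
rounding rule that reproduces those printed counts. Only class is
stratified; stage is not (stage-stratification is not needed to reproduce
the counts, and the split seed is recorded in every report).

**Logistic regression.** The headline classifier is implemented natively:
iteratively reweighted least squares maximizing the Bernoulli log-likelihood
minus a ridge penalty $\lambda/2\,\lVert\beta\rVert^2$ on the standardized
slopes (intercept unpenalized), $\lambda = 10^{-6}$ by default — just enough
to keep separable fits finite without materially biasing coefficients.
Predictors are standardized with training-set statistics only, so no
information leaks from the validation set and predictions are invariant to
affine rescaling of the raw inputs. Convergence is declared when the largest
coefficient change drops below $10^{-8}$ (cap 100 iterations; a
non-converged fit warns and flags its convergence record). The test suite
checks the fitted coefficients against an independent BFGS optimizer of the
same penalized likelihood to $10^{-4}$. Random forest and RBF-SVM adapters
sit behind the same interface (`classifier = "RF"` / `"SVM_RBF"`) but are
deliberately thin — they are comparison baselines, not the workflow's core.

**Predictor transforms.** Lipid concentrations are log10-transformed before
modeling (`log_lipids = TRUE`): concentrations are positive and right-skewed,
and the non-targeted arm of the workflow analyzes log10 peak areas for the
same reason. CA19-9 also enters log10-transformed — its range spans orders
of magnitude. Both transforms are configurable.

## Key tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `ppm_tol` | 10 | ppm | accurate-mass window for cross-species matching |
| `rt_tol_min` | 0.1 | min | retention-time window; the reference pairs differ by at most 0.023 min, so 0.1 is safely permissive |
| `human_auc_min` / `mouse_auc_min` | 0.60 / 0.75 | AUC | "discriminative" screen thresholds; the weakest reference features sit just above these |
| `panel_threshold` | 0.75 | AUC | simultaneous three-set pass threshold |
| `lipid_missing_frac_max` | 0 | fraction | any sporadic missingness drops the lipid |
| `train_fraction` | 0.7 | — | the 7:3 split |
| `prob_cutoff` | 0.5 | probability | operating point for confusion summaries |
| `ca199_cutoff` | 37 | U/mL | clinical CA19-9 positivity cutoff |
| `plateau_first_step` | 11 | markers | first step of the plateau average |

The ppm reference mass is always the first (human) argument; at 10 ppm the
asymmetry is negligible, but fixing it keeps matching deterministic.
Cross-species matching is greedy one-to-one by ascending ppm error, ties
broken by retention-time gap and then by feature id, so the result is
independent of input row order.

## What the synthetic generator emulates

`generate_panel()` draws two cohorts — A: 70 NM + 103 PC, B: 100 NM + 80 PC —
over a 102-analyte roster (13 acylcarnitines, 13 fatty acid amides, 12
sphingolipids, 64 phospholipids, 6 of the phospholipids relatively
quantified). Concentrations are log-normal: on the log scale each lipid has
unit variance and a planted PC-vs-NM shift $d$, so its population AUC is
exactly $\Phi(|d|/\sqrt{2})$ and parameter-recovery tests have an analytic
target.

Planted structure, all recorded in the returned ground truth:

* **The panel.** The 18 reference phospholipids carry negative shifts
  (lower in PC) spanning analytic AUCs 0.90 down to 0.76, echoing the
  published range without claiming to reproduce any single printed AUC. One
  acylcarnitine (C10-carnitine) and one ceramide (C24) are planted at 0.85,
  so the majority-platform restriction reproduces the 20-passers →
  18-phospholipid step.
* **Batch effect.** Cohort B's acylcarnitines are shifted by −3 on the log
  scale (B measured in a lower concentration range). Four acylcarnitines
  (C3/C4/C8/C12) are additionally planted discriminative within each cohort
  (analytic 0.82), so they pass A and B but collapse in the pooled set —
  the A-pass/B-pass/C-fail signature the concordance filter must flag.
  C10-carnitine is exempted from the shift (configurable): its quantitation
  is range-consistent across cohorts, which is what lets one acylcarnitine
  legitimately pass all three sets while its platform-mates are flagged.
  The shift's sign matters: shifting B's acylcarnitines *down* makes the
  pooled AUC collapse (≈0.62 analytically for the planted batch lipids),
  whereas an upward shift of the same size would leave it near 0.75.
* **CA19-9.** Log-normal with group-specific parameters — NM: meanlog 2.45,
  sdlog 1.0; PC: meanlog log(37) ≈ 3.61, sdlog 1.4 — chosen so the analytic
  AUC is ≈0.75 and the sensitivity at the 37 U/mL cutoff is ≈50%, matching
  the covariate's published operating characteristics. Stage labels
  reproduce the reference stage tables exactly among the samples that
  survive exclusion (the excluded PC samples are assigned stage I); stage is
  independent of the lipid values by default.
* **Coupling.** The 20 planted panel analytes receive a −0.10 loading on the
  sample's latent CA19-9 z-score, giving the weak negative lipid–CA19-9
  correlation the selection stage reports. Pearson correlation on
  *untransformed* concentrations (the default) is strongly attenuated by the
  log-normal skew, which is why the pooled coefficients come out near −0.1
  even though the latent group structure is much stronger. At the study's
  sample sizes the sign of a true −0.1 correlation is not reliably
  observable per lipid; the sign property is therefore tested at
  n = 2000/2000.
* **Correlation among lipids.** Within-platform equicorrelation 0.3 via a
  per-platform latent factor. The true covariance of the phospholipids is
  not identifiable from published summaries; 0.3 is a modeling choice,
  exposed as a knob.
* **Missingness.** One PC sample in A loses its whole phospholipid platform;
  CA19-9 is missing for 2 NM in A and 4 NM + 2 PC in B; the published
  sporadically-missing lipids (4 in A, 6 in B) lose three measurements each,
  always in samples that survive the sample-level rules. This plan makes the
  exclusion arithmetic land exactly on 170 samples × 98 lipids (A) and 174 ×
  96 (B).

`generate_nontargeted()` plants the eight reference cross-species features
(species-specific masses and retention times, shifts sized to their
per-species AUCs) among decoys kept at least 50 ppm from every planted mass,
with human 99 NM + 103 PC and mouse 7 NM + 22 tumor-model samples.

**What it does not emulate:** chromatograms, isotopes and MS/MS spectra;
instrument drift within a batch; non-log-normal concentration distributions;
stage-dependent lipid effects (an optional knob, off by default); and any
dependence structure beyond one factor per platform. Tests passing on this
generator therefore validate the *procedure* — its arithmetic, its filters,
its invariances — not the clinical performance of any real panel; the
published real-data AUCs are not reproducible without the deposited
measurements and are never asserted.

## Numerical and design choices

* Ties in the AUC contribute 1/2; `direction = "auto"` resolves an exact
  0.5 to `higher_in_PC`.
* Undefined ratios (0/0 PPV or NPV at degenerate cutoffs) are reported as
  `NA`, never 0.
* Panel ordering ties (equal pooled AUC) break lexicographically by lipid
  name; the reference table has no ties, so any deterministic rule serves.
* An exact tie for the modal platform is an error demanding explicit
  configuration rather than a silent arbitrary pick.
* The pooled set C is a plain concatenation of the cohorts over shared
  lipids — no re-scaling or batch correction — because the concordance
  filter depends on pooled AUCs being *sensitive* to cohort-level range
  shifts.
* No multiple-testing correction is applied across lipids; the selection is
  a concordance filter, not an inference, and adding a correction would
  change the published procedure being implemented.
* Split rounding is half-up with a small epsilon guard against floating
  representation of fractions like 0.7·n.
* Every random step (generation, split, decoy placement) takes an explicit
  seed and restores the caller's RNG state; identical seeds give
  byte-identical outputs.

One acceptance-grade contract deserves a note. The covariate contract —
"adding an informative independent covariate does not reduce the plateau
mean in at least 80% of paired seeds" — is tested with exactly such a
covariate: an equal-variance, uncoupled log-normal marker with analytic AUC
0.75. The generator's default CA19-9 is *deliberately less ideal* (weakly
coupled to the lipids and heteroscedastic between groups, which misspecifies
the linear logit), and with it the paired gain is smaller and noisier; the
pipeline reports that fraction as its own quantity rather than folding it
into the contract.

## Problem sizes used in validation

The package's own validation runs at the study's sample sizes (173- and
180-sample cohorts, 102 lipids): 1,000 random instances for the AUC oracle,
20 datasets for the logistic-regression reference, one 2,000 + 2,000 cohort
for analytic-AUC recovery, 50 generator seeds for selection/batch-flag
frequencies, and 20 paired seeds for the cumulative-curve shape contracts.
These sizes keep the full suite under a minute of compute while leaving the
stochastic contracts comfortable margins.

## Known limitations

* The logistic model is fit on log-concentrations with a linear predictor;
  markers whose group variances differ substantially are handled
  suboptimally (no quadratic terms).
* Random-forest and SVM adapters use their packages' defaults — no tuning —
  because they are baselines, not the product.
* The generator's equicorrelation and coupling are single-parameter
  summaries of an unknown dependence structure; conclusions that hinge on
  fine covariance detail should not be drawn from it.
* AUC confidence intervals are not provided; the workflow filters on point
  estimates, concordance across sets standing in for inferential control.
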