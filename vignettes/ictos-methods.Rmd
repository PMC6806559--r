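---
title: "ICTOS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ICTOS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictosr)
```

## The problem

In locoregionally advanced nasopharyngeal carcinoma (LANPC), adding induction
chemotherapy (ICT) before concurrent chemoradiotherapy (CCRT) improves
failure-free survival (FFS) on average, but the benefit is concentrated in a
subgroup. `ictosr` implements a pipeline that builds a *predictive* (not
merely prognostic) imaging biomarker from pre-treatment MR images: the
Induction Chemotherapy Outcome Score (ICTOS). A patient with ICTOS > 0 is
predicted to have a lower failure hazard under ICT+CCRT than under CCRT
alone; a patient with ICTOS ≤ 0 is not.

The distinction between prognostic and predictive matters everywhere in the
design: ordinary covariate effects tell you who does badly, while only
treatment-by-feature *interactions* tell you who does badly *unless treated
more aggressively*. Every modelling stage here therefore targets the
interaction structure.

## The score model

Let $x$ be a vector of standardized radiomic features, $T \in \{0, 1\}$ the
treatment arm (1 = ICT+CCRT) and $h(t \mid x, T)$ the FFS hazard. The
modified covariate method replaces each feature by
$W = x \, (2T - 1)/2$ and fits a Cox model on $W$ alone, without main
effects:

$$h(t \mid x, T) \propto \exp\{\gamma^\top x\,(2T-1)/2\}.$$

The per-patient treatment log hazard ratio is then $\gamma^\top x$,
regardless of the (unmodelled) main effects — this is the method's point:
it estimates benefit directly, with the working model misspecified for
prognosis but valid for the treatment contrast under randomization (or after
weighting). The score is reported in benefit orientation,

$$\mathrm{ICTOS}(x) = -\gamma^\top x,$$

so that positive values predict a lower hazard under ICT. The 0 cutoff is
the point of no predicted difference, not a tuned threshold.

The package ships the published three-feature model as a read-only fixture
(`ictos_paper_model()`):

```{r}
print(ictos_paper_model())
ictos_score(ictos_paper_model(),
            c(skewness = -2.02, GLCM_variance = -1.26, GLRLM_LRHGLE = 4.58))
```

The printed coefficients are rounded to three decimals, so scores computed
from them can differ from published score read-outs by a few hundredths
(3.784 here against a printed 3.80).

## Pipeline stages and their parameters

**Preprocessing** (`resample_inplane`, `normalize_intensity`,
`discretize`). In-plane bilinear resampling to 1 × 1 mm (configurable;
slices are never interpolated — the features are deliberately 2D, matching
the anisotropic slice spacing of head-and-neck MR). Intensity normalization
is a z-score over nonzero ("in-body") voxels of the whole volume, not the
ROI: ROI-only normalization would erase the first-order contrasts the model
uses. The population-SD (n denominator) convention is used for both image
normalization and feature standardization, and is recorded in the
standardizer object. Gray levels are discretized to a fixed bin *count* of
32 over the ROI range — the standard choice for MR, whose intensities have
arbitrary units (a fixed bin *width* would be meaningless across scanners).

**Feature extraction** (`extract_roi_features`,
`extract_patient_features`). 273 features per ROI: 19 first-order intensity,
10 two-dimensional shape (on the maximum-area slice), 24 co-occurrence
(GLCM) features at 4 directions × 2 distances reported *per offset* (192),
and 13 run-length (GLRLM) features at 4 directions (52). Texture matrices
are accumulated over slices and normalized once per ROI, giving one value
per feature per ROI. Three sequences (T1, T2, contrast-enhanced T1) give
819 features per patient. Whether one should average texture features over
directions instead of reporting them per offset is genuinely open; per-offset
reporting is declared in `feature_catalogue()` and can be swapped without
touching the formulas. The catalogue totals are asserted at runtime.

**Reproducibility screening** (`icc`, `icc_filter_features`). Features must
survive repeat segmentation. The estimator is the two-way random-effects,
absolute-agreement, single-rater ICC(2,1) from the ANOVA decomposition —
the form is a declared choice (the literature frequently names only "ICC");
absolute agreement is the right flavor here because a systematic offset
between raters *is* disagreement for a biomarker. Features with intra- and
inter-observer ICC ≥ 0.8 are retained (the AND rule; ≥ rather than > is
declared, the distinction being immaterial in continuous data).

**Treatment-arm balancing** (`fit_propensity`, `compute_weights`,
`balance_report`). Observational training cohorts are balanced by inverse
probability of treatment weighting on age, sex, EBV DNA (dichotomized at
2000 copies/ml, the split used throughout), nodal necrosis, tumor volume,
and N/T stage dummies. Weights are stabilized ATE weights truncated at
their 1st/99th percentiles — stabilization and truncation are declared
defaults rather than reconstructions; both are standard variance-control
devices and both are configurable. Balance is verified by standardized mean
differences (continuous: $|\mu_1-\mu_0| / \sqrt{(s_1^2+s_0^2)/2}$; binary:
the proportion analogue), with < 0.1 the conventional pass mark.

**Interaction screening and selection** (`screen_interactions`,
`redundancy_filter`, `backward_select`). Each feature is screened by the
Wald p-value of $\beta_3$ in the weighted Cox model
$h \propto \exp(\beta_1 T + \beta_2 x + \beta_3 T x)$; features are ranked
by $p_{interaction}$, then a greedy pass drops any feature correlated
(|r| > 0.8) with a better-ranked survivor. The top candidates (default cap
10 — the cap the original analysis used is unprinted, so it is exposed as a
parameter) enter the modified-covariate fit, followed by backward
elimination of the largest Wald p until all coefficients have p < 0.05.
Ties in p are broken by dropping the later-ranked feature, making the
procedure deterministic. Screening uses the IPTW weights by default
(`screen_weighted = FALSE` turns this off); whether the original screen was
weighted is not determinable, but using the weights keeps the screen and
the final fit consistent about what population they describe.

**Evaluation** (`km_weighted`, `compare_arms`, `interaction_test`,
`logrank_power`, `required_cohort_size`, `stratify_low_ictos`). Weighted
Kaplan-Meier curves with Greenwood variance and log-log confidence
intervals (log-log is declared; plain Greenwood is available). 3- and
5-year survival is read off at exactly 36 and 60 months using the step
function's left-continuous value. The weighted log-rank test is implemented
as the score test of the weighted Cox fit — the two are the same test at
unit weights, and the Cox machinery extends correctly to weights. Power for
the subgroup design uses the Schoenfeld approximation
$\Phi(\sqrt{D\,p(1-p)}\,|\log HR| - z_{1-\alpha/2})$: with 29 events, 1:1
allocation, HR 0.25 and two-sided α = 0.05 this gives 0.96. Scaling a
110-patient subgroup up by its 47% prevalence uses nearest-integer
rounding, giving 234 (a strict ceiling would give 235; the published design
number corresponds to rounding, so rounding is implemented).

Risk stratification of low-ICTOS patients counts four binary factors (N2–3,
T4, volume ≥ 34 ml, EBV DNA ≥ 2000 copies/ml) and calls a patient high-risk
at ≥ 3 factors. "More than two" is ambiguous between ≥ 2 and ≥ 3; the
literal reading (≥ 3) is the default and the threshold is an argument, so
the looser reading is one keystroke away. This ambiguity is surfaced here
deliberately rather than resolved silently.

## The synthetic data generator

No patient images are distributed with the pipeline, so `ictosr` ships a
generator whose ground truth is known, making every stage testable.

**Phantoms** (`phantom_spec`, `generate_phantom`). Each patient is a stack
of axial slices with a disk tumor ROI inside a homogeneous body disk on a
zero background, in three co-registered "sequences" differing by base
intensity. Three texture knobs map monotonically onto the three features
the published model uses:

* `target_skew` — the voxelwise intensity component is a standardized,
  sign-flipped gamma variate whose moment skewness equals the knob exactly
  in distribution;
* `run_structure` — square patches of side `1 + floor(run_structure)` are
  "solid" with probability 0.6, all voxels of a solid patch sharing one
  draw. This lengthens same-gray runs *without changing the marginal
  intensity distribution*, so the run-length knob does not contaminate the
  skewness knob;
* `heterogeneity` — a symmetric per-patch ±1 offset scaled by the knob
  separates the histogram into modes, raising co-occurrence variance.

Cross-talk remains in one direction: strong negative skewness concentrates
voxels near the top of the ROI range and thereby raises high-gray run
emphasis. This is accepted rather than engineered away — real radiomic
features are correlated in exactly this way, and the modelling stages must
cope with it (see "what recovery means" below).

**Re-segmentation** (`perturb_mask`). Repeat segmentations are emulated by
a random in-plane shift of up to `jitter_vox` voxels plus `jitter_vox`
random one-voxel dilate/erode passes; Dice overlap with the original
decreases in `jitter_vox`. Tumor-to-body contrast is mild (0.85 of the
tumor base intensity), so boundary voxels admitted by jitter perturb
features the way partial-volume boundary tissue does, rather than like
background air.

**Cohorts** (`cohort_spec`, `generate_cohort`). Failure-free survival is
drawn by inverse transform from an exponential proportional-hazards model
whose baseline is calibrated in closed form so the control arm's 60-month
event-free fraction equals `baseline_5yr_ffs` (default 0.65, the design
assumption for an unselected LANPC population). Three latent standard
normal features per patient drive both the phantom texture knobs and the
treatment effect: $\log HR_i = \mathrm{base\_effect} + c^\top z_i$ with
default $c = (+0.7, +0.45, -0.4)$ on the hazard side — the negation of the
published benefit-oriented coefficients, so patients with low skewness, low
co-occurrence variance and high run emphasis truly benefit, approaching the
HR 0.25 design target deep in the subgroup. Prognostic (both-arm) effects
of T4, N2–3, high EBV DNA and volume are included so that confounded arm
assignment (a logistic model on covariates scaled by
`confounding_strength`) actually biases the naive contrast: the weighting
stage has a real job. `confounding_strength = 0` is the randomized
validation scenario. Censoring combines exponential drop-out (calibrated so
the probability of drop-out before the administrative horizon equals
`censor_rate`, default 0.15) with administrative censoring at
`admin_censor_time` (default 84 months — the accrual/follow-up pattern of
the original cohorts is not recoverable, so a single explicit horizon is
used instead of a guessed accrual distribution). Time is in months; the
event is the composite FFS endpoint.

**What the generator does not emulate.** MR physics (bias fields, coil
profiles, k-space artifacts), anatomy, registration error between
sequences, non-proportional hazards, informative censoring, and multi-center
protocol differences beyond a global intensity scale. Tests passing on this
generator therefore demonstrate that the *statistical machinery* is correct
and recovers planted structure; they do not demonstrate clinical validity
on real images.

**What "recovery" means under collinearity.** The extracted 819 features
are heavily correlated, by construction and in reality. The redundancy
filter keeps one representative per correlated cluster, and *which*
representative survives is essentially arbitrary (a 90th-percentile feature
is nearly as good a skewness proxy as the skewness statistic itself). The
end-to-end tests therefore check identifiable claims: every selected
feature is a strong proxy (|r| ≥ 0.4) of a latent texture feature, the
fitted score correlates positively with the true per-patient benefit, and
the high-ICTOS group shows the smaller arm hazard ratio in independent
validation data. Feature-name identity is not an identifiable target and is
not asserted.

## Numerical choices

* Cox fits: Efron tie handling, convergence tolerance 1e-9, at most 100
  iterations. Non-convergent screening fits are assigned p = 1 and logged
  rather than aborting a 689-feature screen.
* Degenerate inputs are explicit: constant volumes are rejected with a
  "zero variance" error; constant ROIs discretize to level 1 with a
  degeneracy flag; degenerate co-occurrence matrices yield zero features
  with a flag; zero-SD features are excluded from standardization with a
  warning and recorded; an all-censored cohort fails at the modelling stage
  with "no events"; a cohort whose scores all fall on one side of the
  cutoff produces a single-group report and skips the interaction test with
  a notice.
* Scoring refuses missing features — no imputation anywhere.
* All generators are deterministic under a fixed seed, and a training rerun
  under the same seed and configuration reproduces its model file
  byte-identically (`write_ictos_model`).

## Problem sizes used in the tests

The test suite exercises the pipeline at desk scale, chosen to keep the
full run in minutes while leaving the statistical checks well-powered:
phantoms of 3–4 slices at 40 × 48 voxels; oracle equivalence on 200 random
8 × 8 maps; ICC calibration at n = 2000 pairs; weighting at n = 500 over
200 replicates; sign recovery of the modified-covariate fit at n = 2000
over 100 replicates; screen type-I error over 500 null replicates at
n = 300; and an image-to-model end-to-end run with 300 training and 250
validation patients, 30 of them doubly re-segmented for the ICC stage.

## Known limitations

* The exact preprocessing recipe, feature list and propensity specification
  of the original analysis are not recoverable from public text; the
  defaults here are explicit, versioned stand-ins chosen to reproduce the
  published structural totals (273/819) and to be swappable.
* 3D features, filtered (wavelet/LoG) features and the GLSZM/NGTDM families
  are out of scope, as are competing-risks analyses and efficiency-augmented
  variants of the modified covariate method.
* The weighted log-rank p-value uses the Cox score test; at extreme weight
  concentrations this can differ from permutation-based alternatives.
* ICC confidence intervals are not computed (the filter uses point
  estimates, as the screening rule is a point threshold).
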