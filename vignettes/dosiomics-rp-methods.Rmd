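---
title: "Modeling radiation pneumonitis risk from dose and CT texture: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling radiation pneumonitis risk from dose and CT texture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Radiation pneumonitis (RP) is an inflammatory lung toxicity of thoracic
radiotherapy, graded 0–4 by symptom and intervention severity. Classical risk
models summarize the planned dose with dose-volume histogram (DVH) scalars —
the mean lung dose (MLD) and the volumes Vx receiving more than x Gy. Those
scalars discard all spatial information: two plans with identical DVHs can
deposit dose in very different spatial patterns, and the lung parenchyma
itself (visible on the planning CT) also modulates risk. *Dosiomic* features
treat the 3-D dose distribution as an image and quantify its texture;
*radiomic* features do the same for the pre-treatment CT inside the irradiated
lung. This package implements the full comparison pipeline — dose
accumulation, feature extraction, feature selection, and cross-validated
logistic risk modeling with class balancing — together with a synthetic
phantom cohort generator so every stage can be exercised and tested without
access to protected patient data.

## Dose accumulation: EQD2

Radiotherapy is delivered in fractions, and the biological effect of a voxel
dose depends on the dose *per fraction*: under the linear-quadratic model, a
voxel receiving its dose in few large fractions is damaged more than one
receiving the same total in many small fractions. Because different fractions
may be delivered with different beam arrangements, dose per fraction varies
voxel by voxel, so the correction must be applied voxel-wise before summing:

$$ D_{\mathrm{EQD2}}(k) \;=\; \sum_{i=1}^{N}
   \frac{d_{i,k} + d_{i,k}^2/(\alpha/\beta)}{1 + 2/(\alpha/\beta)} $$

where $d_{i,k}$ is the dose of fraction $i$ in voxel $k$ and $\alpha/\beta$
is the tissue fractionation sensitivity, defaulting to 3 Gy (the conventional
late-lung value; it is a config parameter). The transform has three exact
properties the tests pin down: 2 Gy fractions are a fixed point (a uniform
2 Gy-per-fraction course leaves the physical total unchanged), the transform
is additive over fractions, and it converges to the plain physical sum as
$\alpha/\beta \to \infty$. Accumulation happens on the native planning grid,
*before* resampling to the analysis grid, so each fraction is interpolated
only once; the package also exposes a physical-sum mode behind the same
interface.

## Geometry and ROIs

All volumes are resampled to an isotropic 1.5 mm analysis grid: scalar
volumes (dose, CT) with a smooth cubic-spline interpolant, masks with
nearest-neighbour (which can never invent fractional mask values). The cubic
interpolant is separable and passes through every sample; with natural end
conditions it reproduces constant and linear fields exactly, which is what
the resampling tests assert. The target grid keeps the origin and covers the
source extent to within one voxel; no extrapolation is performed. Negative
spline undershoot of the dose is clipped at zero.

Three ROIs drive extraction. `lung_eval` is the bilateral lungs; for
lung-cancer patients the gross tumor volume is subtracted (the tumor is not
lung parenchyma at risk). `lung_gt10` and `lung_gt20` restrict `lung_eval`
to voxels with total dose strictly above 10 and 20 Gy; these are the CT
radiomic extraction regions — the idea being that parenchymal texture
matters most where meaningful dose is deposited. Thresholds are strict
(`>`): a uniform 10 Gy lung has an empty `lung_gt10` and V10 = 0. Many
planning systems use `>=`; the choice changes results only on
exact-threshold voxels but is documented prominently for reproducibility.
Sub-ROI thresholds are applied to the accumulated EQD2 dose by default (the
same total that all dose features use); a config flag switches to the
physical total, since either convention is defensible.

## The feature catalog

Each patient contributes exactly 249 features in three groups:

* **DVH (15)** — MLD plus V5 … V70 in 5 Gy steps, as percentages of the
  evaluation lung volume.
* **dosiomic (78)** — the first-order + texture catalog computed on the
  accumulated dose within `lung_eval`, after discretizing dose with a fixed
  1 Gy bin (left-closed bins anchored at 0, capped at 100 levels).
* **radiomic (156)** — the same 78-feature catalog computed on the CT within
  `lung_gt10` and `lung_gt20` (78 each), after clamping HU to
  [−1000, 100], shifting by +1000 and binning with width 50 (at most 23
  levels; the top-of-range value joins the top bin).

The 78-feature catalog per context is 17 first-order features (the standard
set *minus the mean*), 24 GLCM, 16 GLRLM, 16 GLSZM and 5 NGTDM features.
The mean is excluded in every context, not only for dose: for dose it
duplicates MLD exactly, and using one identical catalog everywhere keeps the
per-context count at 78 and the radiomic total at 156. First-order `entropy`
and `uniformity` are histogram-shape features of the discretized levels;
all other first-order features use raw intensities, with population moments
(denominator $n$), linear-interpolation percentiles, and skewness/kurtosis
of a constant region defined as 0.

Texture matrices follow the merged-aggregation convention: GLCM pairs are
counted at distance 1 along the 13 unique 3-D directions and summed into one
symmetric matrix before features are computed; GLRLM runs are enumerated per
direction and the 13 matrices summed; GLSZM zones are 26-connected
components; the NGTDM neighbourhood is the 26-neighbour set intersected with
the ROI. Merged (rather than per-direction-averaged) aggregation makes every
feature exactly invariant under axis permutations of the grid, a property the
tests assert. Conventions that the literature leaves open are fixed
bit-exactly and mirrored by the brute-force oracles in the test suite:
run percentage divides the run count by $13 N_v$ (one run ceiling per
direction), zone percentage by $N_v$; the `Ng` appearing in the normalized
inverse-difference GLCM features is the number of *distinct levels present*;
degenerate single-level input yields correlation = MCC = 1, IMC1 = 0, and
NGTDM features with empty difference sums are 0 (rather than an arbitrary
large coarseness cap).

The per-patient extraction can fail to produce radiomic features when a
dose-thresholded sub-ROI is empty or has a single voxel (conceivable for a
very low-dose lung); the block is emitted as missing and the patient is
excluded listwise from models that use it, with a logged count.

## The synthetic phantom cohort

The generator emulates the *statistical structure* the analysis assumes, not
anatomy. Each phantom has two ellipsoidal "lungs" (HU −700 ± 30) in a
soft-tissue background (HU 40 ± 15), an optional spherical GTV for
lung-cancer phantoms, and a per-fraction dose series built from a broad
Gaussian-profile beam through the target — alternating between an
antero-posterior and a lateral arrangement on odd/even fractions, so
per-voxel doses genuinely differ across fractions and the voxel-wise EQD2
accumulation has something to correct. Default cohorts mirror the emulated
study: 101 esophageal phantoms with 62% positive at grade ≥ 1 (positives
split ~92/8 between grades 1 and 2) and 93 lung phantoms with 17% positive
at grade ≥ 2 (positives split ~88/12 between grades 2 and 3); prescriptions
center on 50.4 and 59.4 Gy over 25–30 fractions. The default grid is a
32 × 32 × 24 voxel, 3 mm schematic thorax — deliberately coarse, since the
pipeline consumes only masks and intensities and test runtimes scale with
voxel counts.

Outcomes follow a logistic model:
$\mathrm{logit}\,P(\mathrm{RP}{+}) = a + \beta_{\mathrm{MLD}}\,\mathrm{MLD}
 + \beta_{\mathrm{tex}}\, z(h) + \varepsilon$,
with the intercept $a$ calibrated numerically so the expected prevalence hits
the target. Two planted effects make recovery testable. The MLD effect
(log-odds per Gy) acts on the mean lung EQD2, which varies across phantoms
through beam width, target position and prescription — this is the signal a
DVH model sees. The heterogeneity score $h$ is the within-lung variance of
the *discretized CT*: a single latent per-patient factor drives both the
multiplicative dose texture and the burden of small high-HU lesions seeded
in the lungs, so $h$ is visible to texture features but — by construction —
invisible to the DVH, whose inputs are dose-only. (The within-lung variance
of the *dose* would be a poor choice here: a dose-histogram variance is
largely recoverable from the 14-point Vx curve, which would leak the
"texture" signal into the DVH model and make the qualitative model ordering
unidentifiable.) Default effects are mild
($\beta_{\mathrm{MLD}} = 0.15$/Gy, $\beta_{\mathrm{tex}} = 0.8$/SD,
$\varepsilon \sim N(0, 0.5)$); recovery experiments use the planted
condition $\beta_{\mathrm{MLD}} = 0.2$/Gy (about one log-odds unit per MLD
standard deviation), $\beta_{\mathrm{tex}} = 2.0$/SD and noise SD 0.2 —
a texture-dominant condition chosen once so that the expected ordering of
models is identifiable at cohort size 101, and frozen.

What the phantoms do **not** emulate: real anatomy and contouring
variability, TPS dose calculation (no heterogeneity corrections, no
penumbra modeling), respiratory motion, scanner-dependent CT noise
characteristics, and clinical covariates. Passing tests therefore
demonstrate that the *pipeline machinery* is correct and that planted
effects of known form are recovered — not that any particular feature is
prognostic in real patients.

## Feature selection

Selection runs per feature group on the full cohort (the design of the
emulated analysis): a univariate logistic screen drops features with Wald
$p \ge 0.1$ (likelihood-based p-values differ negligibly here; the Wald
choice is the common default), then survivors are ranked by the mean
held-out ROC AUC of a univariate unregularized logistic model over 50
repetitions of stratified 5-fold CV, and the top 10 per group are kept.
Folds are stratified so both classes appear in each fold at 62/38 or 83/17
prevalence; ties in mean AUC break by smaller screening p, then name, so
selection is fully deterministic given the seed. Zero-variance features are
excluded with a warning; a perfectly separating feature is kept with p = 0.
Because this selection sees the whole cohort, downstream test AUCs on the
*same* cohort are optimistically biased — the transfer evaluation on a
second cohort is the unbiased read-out, which is exactly why the pipeline
carries features from cohort A to cohort B.

## Model evaluation

Each model (DVH, dosiomic, radiomic, dosiomic+radiomic — 10, 10, 10, 20
features) is evaluated by nested Monte-Carlo cross-validation: 500 outer
stratified 80/20 train/test splits; within each outer training set, 250
inner Monte-Carlo 80/20 splits choose the L2 strength from 13 log-spaced
values ($10^{-3}$ … $10^3$) maximizing mean validation ROC AUC; the model is
refit on the full outer training set at the chosen strength and scored on
the held-out test set by ROC AUC and PR AUC (PR AUC matters at 17%
prevalence, where ROC AUC flatters). Standardization statistics and SMOTE
synthesis are computed strictly inside each training portion — a leakage
audit test perturbs held-out rows and asserts that training artifacts are
unchanged. SMOTE synthesizes minority points as convex combinations
$x + u\,(x_{nn} - x)$ of 5-nearest minority neighbours and is applied to
each inner training set and, symmetrically, to the final refit set (the
emulated analysis describes balancing only for the inner sets; symmetric
treatment avoids a distribution shift between tuning and refit and is
flagged in the config). Ties in the strength search prefer the strongest
regularization.

The ridge-logistic solver is a damped Newton iteration with a backtracking
line search on the penalized deviance; the intercept is unpenalized, the
objective is strictly convex for positive strength, and the tests check
agreement with an independent BFGS optimization of the same objective to
1e-6. ROC AUC is computed as the Mann-Whitney statistic (ties count 1/2);
PR AUC integrates a step-wise precision envelope with tied scores entering
together, with no linear interpolation between PR points.

Models are compared by a two-sample Z-test on the per-split AUC lists, as
literally specified in the emulated analysis — despite the splits being
shared, which makes the unpaired test conservative; a paired variant is
available behind a flag. Transfer evaluation re-trains on the target cohort
using only the feature identities selected on the source cohort, plus a
DVH-selected-on-target baseline that deliberately biases the comparison in
favour of DVH.

Degenerate small-sample corners are handled explicitly rather than left to
chance: an inner validation draw lacking a class is dropped from the grid
mean; an inner training set with fewer than two minority samples skips
balancing for that draw; evaluation requires at least two patients per
class.

## Determinism and numerical choices

Every stochastic stage takes an explicit integer seed; the pipeline fans a
single global seed out to per-stage seeds, and per-outer-split seeds are
pre-drawn so the split sequence is identical across models under one
config (enabling paired comparisons and the leakage audit). Cohorts are
bit-reproducible from their spec. Intercept calibration solves the
monotone mean-sigmoid equation by bisection to 1e-10 and reports the
achievable range if the target prevalence cannot be reached.

## Problem sizes used by the test and verification runs

The shipped verification runs scale the study down to keep full runs
tractable on a single CPU, and state so here as the package's own choice:
phantom grids of 16 × 16 × 12 voxels at 4 mm with native-grid extraction
for modeling experiments; a null-calibration check pooled over several
independent 200-phantom zero-effect cohorts at 50–80 outer / 25 inner
splits each with a 5-point strength grid (two design points matter here:
PR AUC's stepwise integration is biased upward under chance ranking on
small test splits — about +0.05 at a 21-patient split, +0.03 at 40 — so
each cohort is sized to keep that metric bias well inside the band; and
one cohort's mean test AUC is itself a random quantity because its outer
splits share patients, so the read-out averages cohorts rather than
trusting one); 50 outer / 25 inner splits per seed for the 20-seed
ordering experiment; and the texture oracle comparison on one hundred
≤ 5×5×5 grids. The statistical structure —
stratification, SMOTE, nested selection of the strength, planted effect
recovery — is identical at full scale, which the defaults
(500 outer / 250 inner, 13-point grid, 1.5 mm analysis grid) implement.

## Known limitations

Phantom realism is deliberately minimal (see above). The GLSZM uses
26-connectivity only; 2-D slice-wise extraction, filtered (wavelet/LoG)
feature classes and the GLDM family are out of scope. The univariate screen
ignores feature correlation, so selected sets can be redundant — faithful
to the emulated design, not a recommendation. The full-cohort selection
mode is optimistic on the selection cohort; use the transfer read-out or
per-split selection for honest within-cohort estimates.
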