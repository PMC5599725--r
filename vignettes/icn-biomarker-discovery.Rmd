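---
title: "Methods: ICN biomarker discovery for minimal hepatic encephalopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ICN biomarker discovery for minimal hepatic encephalopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icnmhe)
```

This vignette is the package's own account of its models, conventions and
numerical choices: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic generator does
and does not emulate, and where the design was genuinely open.

## Problem setting

Minimal hepatic encephalopathy (MHE) is a subclinical cognitive
impairment of cirrhotic patients, diagnosed when a patient is impaired on
at least two of four neuropsychological tests (trail-making A > 68 s,
trail-making B > 156 s, digit-symbol < 23, block-design < 16;
`diagnose_mhe()`). Resting-state fMRI organizes into large-scale
intrinsic connectivity networks (ICNs), and the hypothesis behind this
package is that a small number of ICNs carry regions whose connectivity
state separates MHE from NMHE patients well enough to serve as an
imaging-side complement to the behavioural criteria. The pipeline takes
preprocessed, template-space 4-D scans — acquisition and preprocessing
(motion correction, nuisance regression, filtering, smoothing,
registration) are out of scope and assumed done by standard tools — plus
a set of ICN template maps and a clinical table.

## Dual regression

Stage 1 regresses each time point's volume (over the analysis mask,
intercept included) on the K template maps, giving per-ICN time courses;
stage 2 regresses each voxel's time series on those time courses
(intercept included), giving per-ICN beta and standard-error maps. The
connectivity z map is `beta/se` with the per-regressor residual standard
error, the per-voxel t-like statistic.

Conventions that vary between dual-regression dialects, fixed here and
isolated behind the stage functions:

* **Intercepts in both stages; no variance normalization** of the
  stage-1 regressors. Variance-normalized variants exist in the
  literature; they change the scale of the time courses but not the z
  maps' spatial structure.
* **Per-regressor residual SE** for z, not a global map standardization.
  The choice is isolated in `temporal_regression()`/`zscore_map()`.
* **Analysis mask** = union of template supports dilated by one voxel
  (26-connectivity). Outside the mask z is defined 0 and no regression
  is run.
* **z cap**: z is clamped to ±10 (`z_cap`). The clamp exists for voxels
  with numerically zero residual variance (synthetic noise-free voxels
  have `se ~ 1e-16` and would otherwise produce z ~ 1e15); it applies
  globally because every analysis threshold is at most 3, so the clamp
  never interacts with discretization. A consequence worth knowing: on
  high-SNR synthetic data the z map saturates at the cap inside template
  cores, so template-recovery checks are asserted on the beta maps,
  which are the unstandardized quantity the regression estimates.

With T time points and K regressors the residual has T − K − 1 degrees
of freedom; pure-noise voxels have z distributed as that t, which the
test suite checks at the 2.3% upper-tail level.

## GAMMA

At each threshold of the ladder `threshold_grid()` — exactly 1.00 to
3.00 in steps of 0.25, nine values — each subject's z map is binarized
with a **strict** inequality (`z > thr`), giving the high-connectivity
map `D`. The original description of this analysis leaves the internals
of the ROI search under-specified, so this module fixes a concrete,
fully documented variant; every constant below is a `gamma_params()`
key, and the defaults are this package's convention.

* **Score.** For a candidate binary state vector s over subjects and the
  class labels C, the score is the log marginal likelihood of C given s
  under a model where the class depends on the state, with a Dirichlet
  prior of equivalent sample size `alpha_ess = 2` placed on the class
  distribution within each state (count 1 per (state, class) cell — a
  uniform Dirichlet(1, 1) per state). It equals the log product of
  sequential predictive probabilities (Pólya urn) run within each state,
  which is how the tests oracle it, to 1e-9, over every state vector up
  to n = 8. Useful structure: the score depends on the data only through
  the 2×2 counts, is invariant to subject order, and — because the
  marginal likelihood cannot tell a state from its complement — is
  symmetric under s → 1−s. That symmetry means "sharpening" a state
  vector toward the label vector is only guaranteed not to lower the
  score when the vector already agrees with the labels on a majority of
  subjects; the property test asserts exactly that regime.
* **Representative voxel.** The arg-max of the score over the current
  mask, ties broken by smallest linear (x-fastest) index —
  reproducibility over arbitrariness.
* **Region growing.** Candidate voxels agree with the representative
  voxel's state vector in at least `kappa_sim = 0.9` of subjects
  (Hamming similarity); the ROI is the 26-connected component of the
  candidate set containing the seed. Whether the original method grew
  regions by vector similarity, score contribution, or a Markov-blanket
  criterion is not determinable from the main text; similarity-based
  growing was chosen as the simplest rule that preserves the seed's
  discriminative pattern.
* **ROI state.** Majority vote with `tau = 0.5`, ties counting as 1.
* **Validation.** A label-permutation test with `B = 199` draws. Each
  permutation reruns the representative-voxel search over the same mask
  and records the best score; `p = (1 + #{perm >= observed}) / (B + 1)`.
  The observed statistic is the *seed voxel's* score — the same max-type
  statistic the permutations compute — rather than the aggregated ROI
  score. Matching the two statistics keeps the test exchangeable and
  hence calibrated; validating the ROI-level score against voxel-level
  permutation maxima was measured to be several-fold conservative. A
  candidate with `p >= 0.05` stops the search; at most `max_rois = 5`
  ROIs are extracted, each masked out before the next iteration, so ROIs
  are disjoint by construction.
* **CPT.** `P(class | state) = (N + 1) / (N_state + 2)` — add-one
  smoothing, rows summing to 1.

Two practical notes on the permutation test. First, its p-values live on
the grid `k/(B+1)`, so the smallest attainable value is `1/(B+1)` and a
perfectly separating planted effect reaches exactly that. Second, with
few subjects the max-score statistic is *discrete* — on 16-subject null
cohorts it took ~14 distinct values, and tie mass makes the plus-one
estimator conservative (≈1% of null cohorts validated instead of ≈5%).
This is a known artifact of permutation tests with discrete max-type
statistics, not a miscalibration of the implementation; at the package's
default cohort size (32/42) the count space is rich enough that the
validated-model rate on null cohorts is ≈5%, which is how the
calibration suite checks it.

## Classifiers and the performance grid

ROI states are the features. The three classifier families are the
standard library implementations a practitioner would use, behind the
package's surface: `e1071::svm` with a degree-1 polynomial kernel and
C = 1 (an SMO-trained SVM), `nnet::nnet` with one hidden layer of
`(features + 2) / 2` units and weight decay 0.01, and `rpart` with the
information (entropy) splitting criterion and complexity-parameter
pruning as the C4.5 surrogate (gain-ratio splits and error-based pruning
differ in detail; behavioural equivalence on separable fixtures is the
tested surface, bit-compatibility with any particular toolbox is a
non-goal). Evaluation is stratified 10-fold cross-validation with
predictions pooled over folds; MHE is the positive class; accuracy,
sensitivity and specificity are reported in percent. Stratification is a
package choice (it guarantees both classes in every training fold);
fold assignment and MLP initialisation derive from the master seed, so
grids rerun identically.

`run_grid()` covers the full ICN × threshold × classifier factorial.
Cells where GAMMA validates no ROI — or any cell-level failure — are
recorded as the always-majority baseline (with a warning), never
dropped: an incomplete factorial would silently change the ANOVA and
stability denominators downstream.

## Grid statistics and ICN selection

* **Pairwise classifier tests**: metrics are first averaged over
  thresholds within (ICN, classifier); classifier pairs are compared by
  paired two-sided t-tests across ICNs (df = number of ICNs − 1). An
  all-zero difference vector is flagged degenerate with p = 1.
* **Factorial ANOVA**: fixed-effects, three factors (threshold,
  classifier, ICN) with all two-way interactions; the three-way term is
  the residual. This is the only reading of a "two-factor" label
  consistent with a df column of 8/2/19/16/152/38 on a 9 × 3 × 20 grid,
  and the df identities `df_main = L − 1`,
  `df_int = (L_i − 1)(L_j − 1)` are property-tested for arbitrary
  complete grids.
* **Stability**: per ICN, the fraction of its 27 (threshold, classifier)
  cells with accuracy **strictly** above 85 ("above"), in percent to one
  decimal; selection keeps ICNs at or **at least** 70% (a reported
  selection at 70.4% only makes sense with an inclusive cut).
* **Best thresholds**: cells maximizing accuracy, ties broken by
  sensitivity then specificity, reporting *all* co-optimal thresholds —
  multiple co-optimal thresholds per ICN are the expected outcome on
  strongly separable data.

## Biomarker evaluation

For subject i and ROI j of ICN k, the two functional integration
patterns are the overlap count `N = |{v in ROI : D_i(v) = 1}|` and the
mean connectivity `FC = mean_v∈ROI F_i(v)` with F the unthresholded z
map. Because D shrinks monotonically as the threshold rises, N is
monotone non-increasing in the threshold for every subject — a property
the suite asserts. Group differences use pooled-variance two-sample
t-tests (Welch is deliberately not the default, matching the uncorrected
conventions of the demographic tables this mirrors; the pooled form is
also what `ttest_from_summary()` can reproduce from published
mean ± SD rows). Partial correlations regress both variables on the
covariates (movement, age, gender coded 0/1, education; constant
covariate columns are dropped) and correlate residuals, with
`df = n − k − 2`; the precision-matrix identity is the test oracle at
1e-9. Bonferroni correction defaults to the family of the selected ICNs
(m = 3 when three networks are selected) per clinical measure and
pattern.

## The synthetic cohort generator

The generator's defaults are the study conditions the package is
exercised under, not tuning knobs:

* **Cohort**: 32 MHE / 42 NMHE (the demographic table's sizes; the
  abstract's 33/43 differ by quality-control exclusions and the table is
  taken as authoritative).
* **Scans**: T = 115 retained volumes (120 acquired minus 5 discarded)
  at TR = 2.5 s, on a 30 × 36 × 30 grid — a coarse stand-in for 3 mm
  template space that keeps a 74-subject run on one CPU in tens of
  seconds. Voxel coordinates are 0-based in all serialized artifacts.
* **Templates**: 20 Gaussian blobs placed on disjoint lattice cells,
  binarized at a fixed kernel level and weighted by the kernel —
  compact, mutually low-overlap supports mimicking real ICN templates
  without shipping data. Blob width scales with the lattice cell
  (`sigma = min(cell)/5`, at least 1.2 voxels).
* **Planted deficit**: the core of the first ICN's template (weight
  ≥ 0.6, ~38 voxels at default scale), where MHE subjects' spatial gain
  is multiplied by `1 − delta` with `delta = 1` — a complete,
  fully separable loss. The deficit is multiplicative on gain rather
  than additive noise so it propagates into the dual-regression betas
  exactly the way the analysis assumes.
* **Noise**: i.i.d. Gaussian, SD 0.2 against unit-variance loadings.
* **Clinical table**: scores drawn from group-conditional normal
  distributions with the demographic table's means and SDs, shifted by
  `coupling × direction × (integration − 1) × SD` so that a planted
  deficit pushes trail-making times and Child-Pugh up and
  digit-symbol/block-design down; age, gender (80% male), education and
  movement (log-normal mean framewise displacement around 0.12 mm) are
  drawn independently of group.

What the generator does **not** emulate: hemodynamic response shapes,
physiological or motion artifacts, registration error, spatial noise
correlation, graded within-group deficit heterogeneity. Consequently,
passing tests certify the machinery — recovery of planted structure,
calibration under the null, determinism — and not performance on real
scans; with `delta = 1` and noise 0.2 the planted ROI state is perfectly
separable by construction, which is why 100% cross-validated accuracy is
the expected output of the acceptance run rather than an empirical
claim about patients.

## Numerical choices and degenerate inputs

* Seeds: every stochastic step (templates, loadings, noise, clinical
  draws, permutations, folds, MLP initialisation) derives its stream
  from a master seed through a 32-bit LCG-style mix, so whole runs are
  bit-reproducible and cell-level reruns are independent of grid order.
* Tie-breaks: representative voxel by smallest linear index; ROI-state
  majority ties count as 1; best-threshold ties resolved by
  sensitivity then specificity, keeping all co-optimal cells.
* Degenerate inputs: single-class labels, empty masks, empty ROIs,
  zero-margin contingency tables and rank-deficient covariates raise
  typed errors; zero pooled variance and all-zero paired differences are
  flagged with p = 1 rather than NaN; models with zero validated ROIs
  signal a typed condition that the grid converts into the
  majority-class baseline.
* Problem sizes in the test suite are the package's own choices for a
  thorough-but-quick check: 12³ grids with 2 templates and 14–22
  subjects for module tests, study-sized (32/42) cohorts for the
  null-calibration and the full-scale separable run.

## Known limitations

* The GAMMA variant is a documented reconstruction; alternative region
  growing rules (score-based, Markov blanket) could yield different ROI
  boundaries on real data.
* The permutation validation is conservative for very small cohorts
  (discrete max statistics); below ~20 subjects its nominal 5% level is
  not attained.
* No hyperparameter tuning, nested cross-validation or probability
  calibration for the classifiers; no mixed-effects alternatives to the
  fixed-effects ANOVA; no effect-size reporting beyond t, r and p.
* Published demographic p-values that cannot be reproduced from printed
  summaries (age, education) are out of scope for the summary t-test
  helper, which reproduces only what pooled-variance arithmetic can.
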