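---
title: "Multi-kernel SVM classification of multimodal MRI features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-kernel SVM classification of multimodal MRI features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromkl)
```

## The problem

Group-level contrasts of structural and resting-state functional MRI report
where patients differ from controls on average, but a clinically useful
marker must classify *individual* subjects. neuromkl implements a
whole-brain multivariate classifier for that setting: three voxelwise
feature maps per subject — gray matter volume (GMV) from structural MRI,
the amplitude of low-frequency fluctuations (ALFF) and regional homogeneity
(ReHo) from the resting-state series — are combined through a
multiple-kernel linear support vector machine (SVM) whose per-feature
kernel weights are learned from the training data, and performance is
estimated by leave-one-out cross-validation (LOOCV). Because the modalities
carry complementary information (morphometry, oscillation amplitude, local
temporal synchrony), a learned combination can outperform the best single
modality.

## The features

All features live on a common voxel grid restricted to a brain mask with
`D` voxels, and each subject contributes one row per feature to a
subjects-by-voxels matrix in a single fixed voxel order (column-major,
first axis fastest), shared by every feature so that classifier weights can
be scattered back into volumes.

**ALFF.** For a voxel's series of `n` points sampled every `tr` seconds,
the series is linearly detrended, Fourier transformed, converted to
single-sided amplitudes `a_k = 2 |X_k| / n`, and averaged over the bins
whose frequencies `k/(n tr)` fall in the band 0.01–0.08 Hz (inclusive at
both edges). The exact spectral convention (detrend, then mean single-sided
amplitude over in-band bins) is a package choice, fixed here and verified
against direct DFT summation in the tests; conventions differ across
toolkits mainly by constant factors, which the later z-scoring removes.
Functional volumes are smoothed *before* the spectral analysis.

**ReHo.** Kendall's coefficient of concordance `W` of a voxel's series with
its 26 neighbors (a 27-voxel cluster): each series is ranked over time
(average ranks for ties), the ranks are summed per time point, and
`W = 12 Σ_t (R_t − R̄)² / (K²(n³ − n))`. No tie-correction factor is
applied in the denominator, matching the common form used by resting-state
toolkits. At mask edges the neighborhood is intersected with the mask (the
statistic uses however many in-mask series exist, minimum 2). ReHo is
computed on unsmoothed series; the finished `W` map is then smoothed.

**Smoothing.** Separable Gaussian with `σ = FWHM/(2√(2 ln 2))`, default
FWHM 4 mm on 3 mm voxels, implemented with half-sample mirror boundaries.
Mirroring folds kernel mass that would leave the grid back inside, so the
image total and constant images are both preserved exactly — the two
properties that make the operation safe at mask edges.

**Scaling and normalization.** ALFF and ReHo maps are divided by their
within-mask global mean, giving every subject unit mean for those features
(GMV is left on its native modulated scale, as is conventional for
volume estimates). We apply the global-mean division as the last step of
map production, after map smoothing, so the unit-mean property holds
exactly; the alternative order differs only by a near-unity constant
factor that the z-scoring removes. Each feature matrix is then z-scored
per voxel — population variance convention (divide by `n`) — with means
and SDs estimated on the *training* subjects only and applied to the
held-out subject, so no information leaks across cross-validation folds.
Constant training columns are flagged and mapped to zero. Whether the
normalization should be fold-wise or global is genuinely open in this
design; fold-wise is the default because it is the leak-free choice, and
`loocv(..., normalize = "global")` provides the alternative.

## The classifier

With feature vectors `x^(f)` for `f = 1..F`, per-feature linear Gram
matrices `k_f(x_i, x_j) = ⟨x_i^(f), x_j^(f)⟩` are combined as

```
K(x_i, x_j) = Σ_f β_f k_f(x_i, x_j),   β_f ≥ 0,  Σ_f β_f = 1,
```

and the soft-margin SVM dual is solved on the combined kernel:

```
max_α  Σ_i α_i − ½ Σ_ij α_i α_j y_i y_j K(x_i, x_j)
s.t.   Σ_i α_i y_i = 0,   0 ≤ α_i ≤ C.
```

The kernel weights and the SVM are optimized *alternately*: at the current
`β` a full dual solve yields `α`; then `β` takes a descent step using the
gradient of the optimal-value function, whose components are
`−½ Σ_ij α_i α_j y_i y_j k_f(i, j)` (Danskin's rule — the optimal `α` can
be treated as fixed when differentiating in `β`). The step is a
golden-section line search along the simplex-projected path
`β(t) = Π_simplex(β − t g)`; Euclidean projection keeps `β` exactly
feasible after every update. Iteration stops when both the largest weight
change and the relative objective decrease fall below `tol = 1e-4`, or
after 100 rounds. Only improving steps are accepted, so the objective
trajectory is non-increasing by construction; at convergence the relative
duality gap of the final combined-kernel SVM is checked in the tests to be
below 1e-4.

Numerical choices that matter:

* **Inner solver.** The dual is solved by compiled sequential minimal
  optimization (maximal-violating-pair working-set selection), warm-started
  along the line search from the incumbent `α`, which is feasible for any
  kernel. Variables within `1e-12·C` of a box bound are treated as bounded
  during selection so a numerically tiny free coefficient can never stall a
  step. The bias `b` is the KKT average over unbounded support vectors
  (`1e-6 < α_i < C − 1e-6`), falling back to the midpoint of the final
  violating-pair bounds.
* **`β` initialization** is uniform `1/F`, the standard start for this
  alternating scheme.
* **Kernel preconditioning.** Each Gram matrix is divided by its mean
  diagonal before weighting (optional flag, on by default) so kernels of
  differently scaled features compete on an even footing and the learned
  `β` is interpretable as relative feature importance.
* **`C` is fixed at 100** for every fit, with no inner grid search; linear
  whole-brain SVM performance is famously flat in `C` over a wide range,
  and a fixed `C` keeps the cross-validation outer loop honest. The kernel
  weights are learned on each training fold from the MKL objective itself.
* **Tie-break**: a decision value of exactly 0 predicts the patient class
  (+1), a documented deterministic convention.

For linear kernels the decision function decomposes voxelwise,
`f(x) = Σ_f ⟨w^(f), x^(f)⟩ + b` with
`w^(f) = β_f/s_f Σ_i α_i y_i x_i^(f)` (`s_f` the preconditioning scale),
which is what makes discrimination maps possible; the primal–dual identity
is asserted to 1e-8 in the tests.

## Evaluation

LOOCV holds out each subject once: normalization, Gram matrices, kernel
weights and the SVM are all re-fitted on the remaining subjects, and the
held-out subject is classified from its kernel columns against the fold.
From the pooled fold results the package reports sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy `(TP+TN)/n` (patients
are the +1 class; reported percentages are rounded half-up to 2 decimals,
full precision is kept internally), plus an ROC curve swept over the pooled
decision values and its AUC computed as the Mann–Whitney statistic
(patient–control pairs with ties counted ½). Pooling the LOOCV decision
values into a single curve is the standard construction when each fold
contributes one prediction. `improvement_over_best_single()` reports the
accuracy gain of the combined classifier over the best single feature, in
percentage points.

## Discrimination maps

A full-data fit (all subjects; one map per comparison) yields per-feature
weight vectors; voxels with `|w| ≥ θ · max |w|` (default θ = 0.30) are
retained. Retention depends on absolute weight only, signs are preserved in
the weight volume, and lowering θ can only add voxels (monotone nesting).
Because the classifier is multivariate — every voxel contributes to the
decision — retained voxels mark contribution to the whole-brain pattern
and must not be read as local statistical inferences. Per-fold weight
averaging is a conceivable alternative to the full-data fit; the full-data
fit is the default because it answers "which voxels drive *the* classifier
for this comparison" with a single well-defined model.

## The synthetic cohort

No subject scans ship with the package; every downstream stage is instead
exercised on synthetic cohorts from `generate_cohort()`. The default
configuration mirrors the emulated study design: 17 patients and 20
controls, a 12×12×12 grid of 3 mm isotropic voxels (D = 1728, chosen so a
full pipeline runs in seconds while keeping D ≫ n, the regime whole-brain
classification lives in), 200 functional volumes at TR = 2 s with the
first 10 discarded downstream, and unit-SD Gaussian noise. Three
mechanisms inject group differences, each in its own box:

* **volume** — patients' structural values in the box are shifted by
  `effect_size` noise-SDs (default 1.0); structural values are clipped at
  0 since tissue volume cannot be negative;
* **amplitude** — both groups receive a 0.05 Hz sinusoid (an exact DFT bin
  of the 190-point retained series, inside the 0.01–0.08 Hz band) with
  per-voxel random phase and control amplitude equal to the noise SD;
  patients get a fractional amplitude increase (default +50%);
* **synchrony** — a shared latent series is mixed into the box voxels with
  variance-preserving coefficient `m` (`√(1−m²)·noise + m·latent`),
  default 0.8 for patients and 0 for controls, raising inter-voxel rank
  concordance.

Effect sizes are free parameters: nothing about them is calibrated to the
published cohort, so synthetic accuracies characterize the pipeline, not
the paper's data. The defaults were chosen once from signal-to-noise
reasoning — e.g., the amplitude default makes the per-voxel ALFF shift
roughly one ALFF-noise SD, comparable to the 1-SD volume shift — and give
mid-range single-modality separability at these group sizes. The
functional baseline is temporally white by default (the simplest null
under which the amplitude and synchrony effects are injectable and
analyzable exactly); AR(1) noise is available via `ar_coef`. Patients
(label +1) receive the altered value by convention; direction is
irrelevant to the classifier.

What the generator does *not* emulate: MRI physics (no k-space, no
T1/T2 contrast), motion, physiological noise, spatial autocorrelation of
real tissue, registration error, or site effects. Passing tests therefore
demonstrate that the implementation is correct and that the pipeline
recovers known injected structure — not that any particular accuracy is
attainable on real scans.

## Problem sizes used in the shipped checks

The package's own experiments run LOOCV at the full emulated scale
(n = 37, D = 1728, 190 retained volumes) — about 10–15 s per cohort on one
core — and repeat cohort-level claims over 20 seeds (kernel-weight
recovery, permutation null, map enrichment). Unit tests use smaller grids
(4³–6³) where an exhaustive oracle is feasible. Statistical assertions use
binomial chance bands at n = 37: under label permutation the mean LOOCV
accuracy must lie inside the two-sided 95% band, and with signal present
it must exceed the one-sided 95% bound. LOOCV accuracy under a permuted
null is known to sit slightly *below* 50% (each held-out subject's class
is under-represented in its training fold, and margin classifiers lean
toward the fold majority); the n = 37 binomial band is the appropriate
scale for this bias, whereas a band computed as if all 20 × 37 fold
decisions were independent would be artificially narrow, since decisions
within a cohort share 35 of 36 training subjects.

## A worked example

```{r example, eval = FALSE}
cfg <- default_cohort_config(seed = 42)
cohort <- generate_cohort(cfg)
mask <- cohort_mask(cfg)
features <- extract_features(cohort, mask)

folds <- loocv(features, participants(cohort)$label, C = 100)
report <- metrics_report(folds, "patients-vs-controls")
report          # sensitivity / specificity / accuracy / AUC
autoplot(report)  # pooled-fold ROC curve

full <- fit_full_and_map(features, participants(cohort)$label, mask)
full$beta       # learned kernel weights
autoplot(full$maps$GMV)
```

## Known limitations

* Pairwise (two-class) classification only, as in the emulated design.
* Linear kernels only; `extract_weight_vectors()` is meaningful only for
  them, and the package refuses nonlinear configurations by construction.
* The LOOCV point estimates at n = 37 have wide sampling bands; the
  package deliberately reports no confidence intervals rather than
  suggesting false precision.
* No nuisance regression, motion scrubbing, fALFF variant, or bandpassed
  ReHo; no atlas labeling of discrimination maps, and no statistical
  inference on map weights.
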