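---
title: "PCAT radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCAT radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design points were settled the way they were. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The analysis in one paragraph

Per vessel, the pericoronary adipose tissue (PCAT) is segmented on each
axial slice of a straightened coronary CT angiography volume; a 1356-value
radiomic signature summarises its shape, attenuation distribution and
texture; a five-stage cascade reduces the signature to at most ten
features; and a ridge-protected logistic model over those features is
scored by repeated stratified 3-fold cross-validation against vessel-level
binary labels (TCFA, MC, or their conjunction), reported as mean AUC ± SD
over repeats with a vertically averaged ROC curve.

## Segmentation rules

PCAT on a slice is the intersection of two rules:

* **Annulus**: voxels strictly outside the filled outer-wall region whose
  Euclidean distance to the nearest wall voxel centre is at most one vessel
  diameter. The distance is computed in millimetres, so anisotropic
  in-plane spacing is honoured; it is evaluated exactly (minimum over wall
  boundary voxels) rather than by a pixel-grid distance transform, and the
  tests compare it against an exhaustive per-voxel oracle.
* **HU window**: attenuation in `[-190, -30]` HU, *inclusive* at both ends.
  We read "between −190 and −30 HU" inclusively, matching common
  fat-attenuation-index practice; the endpoint behaviour is pinned by a
  test.

Two genuinely open points were settled as follows. The *vessel diameter* is
nowhere defined for irregular walls; we use the equivalent-disc diameter
`2 * sqrt(area / pi)` of the filled outer-wall region because it is
rotation invariant, stable for non-convex walls and standard in image
analysis. And the radial distance is measured per slice in 2D (not 3D along
the straightened centreline) because the entire analysis operates on
straightened axial slices; 3D distance would differ only near abrupt
diameter changes and cannot be resolved from the published description.
An optional `exclude_proximal_mm` argument drops the ostial segment
(used for right coronary arteries in clinical practice); phantoms default
to no exclusion.

## The 1356-feature signature

113 base features are computed per slice: 21 shape, 17 first-order and 75
texture features (24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM, 5 NGTDM). Each is
evaluated at three equal-width discretizations of the adipose window — 8,
16 and 32 bins, i.e. bin widths of 20, 10 and 5 HU — and aggregated across
the retained slices of the range by minimum, maximum, mean and sample
(n−1) SD, giving `113 × 3 × 4 = 1356` values named
`{stat}_{family}_{feature}_{bins}b`.

Design notes:

* **Aggregation axis.** The published feature counts (252 shape / 204
  intensity / 900 texture) are only reachable if the per-slice feature
  distributions are summarised by four statistics and the shape features
  are replicated across the three bin settings (shape is bin independent:
  21 × 3 × 4 = 252). Slices are the only axis that yields a distribution
  per vessel, so per-slice 2D computation with across-slice aggregation is
  used throughout.
* **Exact base lists.** No published list of the 21 shape and 17
  first-order names exists; the lists in `SHAPE_FEATURES` and
  `FIRSTORDER_FEATURES` were fixed once to satisfy the counts, using
  standard 2D descriptors. Entropy and uniformity are the two first-order
  features that depend on the bin setting; all others are replicated across
  bins, and a test asserts exactly that.
* **Discretization range.** Fixed to the PCAT window (−190, −30) rather
  than per-mask min/max, for cross-vessel comparability ("equal HU
  ranges"). The lower bound maps to level 1, the upper to level `n_bins`.
* **Texture conventions.** GLCM: distance 1, four 2D angles, symmetric,
  angle-summed, normalised to 1. GLRLM: features per angle, averaged over
  the four angles. GLDM: α = 0, distance 1, 8-neighbour dependence.
  GLSZM: zones are 8-connected components of equal level (labelled via the
  pixel adjacency graph). NGTDM: in-mask 8-neighbour means. These are the
  common library defaults for 2D texture work; every matrix is validated
  against a brute-force enumeration oracle on ≥ 200 random masks ≤ 8×8
  (counts exact, derived features to 1e−9 relative).
* **Degenerate-mask guards.** Single-gray-level masks: GLCM correlation and
  the maximal correlation coefficient return 1 (perfect-correlation
  convention), information measures 0. Constant first-order input:
  skewness/kurtosis/entropy 0, uniformity 1. Constant NGTDM input:
  contrast 0, coarseness capped at 1e6. Single-pixel masks produce
  dependence 0 and one zone. Slices with fewer than `min_fat_voxels`
  (default 10) fat voxels are excluded from aggregation and logged — tiny
  PCAT slices occur and must not crash or dominate the SD statistics.
* **Shape measurement conventions.** The perimeter is the total length of
  exposed pixel edges (exact for axis-aligned rectangles); the convex hull
  is taken over pixel corners; circularity is the perimeter of the
  equivalent-area disc divided by the hull perimeter (1 for a disc, ~0.89
  for a square), while compactness uses the pixel-edge perimeter. Axis
  lengths come from the moment-matched ellipse with the 1/12-pixel
  variance correction, so single-pixel masks remain well defined.

## Selection cascade

1. **Correlation pruning** at `|r| > 0.95`, scanning columns in a fixed
   canonical order (statistic, family, feature, bins) and dropping the
   later member of each offending pair — deterministic, and equal to the
   brute-force all-pairs filter by construction (tested). Constant columns
   have undefined correlation; they are kept with a warning.
2. **Univariate screen**: per feature, a single-feature logistic model
   (standardised on the training folds, light ridge) scored by stratified
   3-fold CV; out-of-fold scores are pooled per repeat into one AUC and
   averaged over repeats. The screen is vectorised across features (a
   shared 2-parameter Newton solver), which is what makes 1000-repeat
   screening of hundreds of features tractable.
3. **Per-family pooling**: the 15 best features by mean AUC within each of
   the seven families, ties broken by name → at most 105 candidates.
4. **mRMR** with the mutual-information difference criterion (first pick:
   maximal relevance `I(f; y)`; then maximal
   `I(f; y) − mean I(f; s)` over the selected set), features discretised
   into 3 levels at mean ± SD. The variant and discretisation are the
   classical defaults for continuous inputs; ties break on candidate
   order. Applied twice: to 50, then to ≤ 10 — the published wording
   conflates the refinement with the elimination step, so the boundary is
   explicit and configurable here.
5. **Recursive elimination**: fit the ridge-logistic model on all
   candidates (standardised), drop the smallest `|coefficient|`, record
   the mean CV AUC at every size, return the subset with the best mean
   AUC, ties toward the smaller subset.

## Cross-validated evaluation

Folds are stratified by class; each fold then contains at least one member
of each class whenever each class has at least `n_folds` members.
Non-stratified shuffles that produce a single-class fold are redrawn, so
the number of repeats is always preserved. Per repeat, out-of-fold scores
are pooled and the AUC is computed as the Mann–Whitney statistic with
midrank ties — an exact identity with the trapezoidal area under the
empirical ROC, asserted in the tests. The mean ROC curve is the vertical
average of the per-repeat curves on a 101-point FPR grid. The reported SD
is the sample SD over repeats (the repeat-level spread; fold-level spread
is not separately reported).

All logistic fits carry a small ridge penalty, `lambda = 0.01` on
standardised features (intercept unpenalised). At n ≈ 30 with selected
features quasi-separation is routine; the penalty keeps the IRLS solver
defined without materially changing coefficients (the fit converges to
`glm` as `lambda → 0`, tested).

Two estimation caveats are deliberate properties of the protocol rather
than bugs, and both are documented by tests:

* **Pooling pessimism.** Pooling out-of-fold scores from differently
  calibrated fold models is slightly pessimistic on null data, so
  permutation nulls of a *fixed* feature set centre a little below 0.5.
* **Selection optimism.** The univariate screen, mRMR and elimination run
  on the full table (mirroring common radiomics practice and the published
  Manhattan plots), so the final model's CV AUC is optimistic — severely so
  on null data, where selecting the best-looking of ~400 noise features at
  n = 30 can yield apparent AUCs far above chance. `evaluate_nested()`
  re-runs the entire cascade inside every training fold and is the
  protocol used for null calibration; on label-permuted phantom cohorts
  its mean AUC returns to chance level, which is what the acceptance
  checks assert.

## The phantom: what it does and does not emulate

Each vessel is a stack of axial slices (default 40 slices of 64×64 voxels
at 0.5 mm isotropic spacing — a typical CCTA reconstruction) containing a
contrast-filled lumen (~400 HU, radius 1.5 mm varying ±15% sinusoidally
along the vessel), a soft-tissue wall annulus (~50 HU, 0.75 mm thick,
masks exact by construction), an adipose field of spatially correlated
Gaussian noise (mean −80 HU, SD 15 HU, FFT-generated so the marginal
variance is exactly stationary), and scattered soft-tissue voxels (8% of
peri-vessel pixels, 0–80 HU) so the HU window genuinely filters. The LOI
is the central 20% of the vessel range — no published LOI length exists,
so this is a package default, not an inferred value.

The class effect is two-channel: label-positive vessels (driven by the
`effect_on` label, default TCFA) receive a +15 HU shift of the adipose
mean and a doubled texture correlation length (0.8 → 1.6 mm). The
attenuation shift emulates inflammation-related water retention; the
correlation-length change gives the texture families a signal that is
independent of the mean shift, so tests can separate intensity from
texture channels. Label prevalences default to 14/30 (TCFA) and 12/30
(MC), drawn independently, emulating a small clinical cohort.

Not emulated: IVOCT imaging and registration (labels are taken as given,
frame ranges are registered by construction), cardiac motion, beam
hardening, calcification blooming, slice-to-slice noise correlation, and
wall-segmentation error. Passing tests on the phantom therefore
demonstrate the pipeline's internal correctness and calibration — not
clinical performance: the +15 HU default effect is far stronger relative
to noise than any plausible biological effect, which is why the phantom
models reach AUC ≈ 1 while clinical models do not.

## Problem sizes and determinism

The test suite and acceptance script run cohorts of 30 vessels with
100-repeat CV for cascade-level checks, 10–20 repeats for nested
evaluation, and 10 phantom seeds for the recovery rate — sizes chosen so
the full suite completes in minutes while keeping the binomial noise on
each asserted quantity well inside its assertion band. Every random draw
(labels, fields, folds, permutations) flows from explicit integer seeds
through a splitmix-style derivation, so cohorts, traces and models are
bit-reproducible; rerunning any pipeline with the same config yields an
identical config hash and identical per-repeat AUCs.

## Known limitations

* 2D per-slice processing throughout; no 3D texture matrices and no
  filtered (wavelet/LoG) feature classes — the 1356-value layout excludes
  them by design.
* The univariate screen's AUC is a pooled-score CV AUC, not the in-sample
  Mann–Whitney AUC of the raw feature; for mid-strength features the two
  differ by a few hundredths (pooling attenuation).
* `mRMR` uses 3-level discretisation; very fine-grained dependence
  structure between features is invisible to it.
* The plain pipeline's final AUC inherits selection optimism (see above);
  use `evaluate_nested()` when an unbiased estimate matters.
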