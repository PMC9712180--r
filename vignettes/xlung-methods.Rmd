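---
title: "Methods: cross-domain lung CT radiomics with xlung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-domain lung CT radiomics with xlung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`xlung` implements a transfer study for CT radiomics of interstitial lung
disease (ILD): a signature of intensity and texture features is extracted in a
source acquisition domain (microCT-like), filtered for delineation stability,
screened univariately, and carried as trained classifiers into a target
domain (HRCT-like), where frozen-weight testing is contrasted with
re-optimization of the same feature signature. This vignette documents the
models, the parameters that matter, what the synthetic data do and do not
emulate, and the numerical decisions baked into the implementation.

## Image preparation

A subject is a Hounsfield-unit volume plus a binary lung mask (left and right
lungs merged by voxelwise OR into one organ). Preparation is three steps:

1. **Isotropic resampling** (`resampleIsotropic`). Trilinear interpolation of
   the image; the mask is linearly interpolated and thresholded at 0.5, which
   avoids the aliasing that nearest-neighbour assignment produces on thin
   lung margins. The target spacing is per-domain (`extractionConfig`,
   defaults 0.2 mm microCT-like / 1.0 mm HRCT-like) and is chosen, as in the
   underlying study design, to give the two domains a comparable ratio of
   voxel size to organ size. The interpolation kernel is a configuration
   point: only trilinear is implemented, as the one standard choice.
2. **Re-segmentation** (`resegment`). The ROI is restricted to voxels in
   [−1000, 200] HU, both bounds inclusive. This removes dense non-parenchymal
   structure and out-of-range artifacts. Idempotent by construction.
3. **Discretization** (`discretizeFBS`). Fixed bin size of 50 HU with bins
   anchored at the lower re-segmentation bound: level = ⌊(x + 1000)/50⌋ + 1.
   Anchoring at −1000 HU (rather than at the per-subject minimum) keeps level
   k meaning the same attenuation band for every subject and domain, which is
   what makes cross-domain texture comparison meaningful. Bins are half-open
   [edge, edge) except the last, which is closed: x = 200 falls in level 24,
   and the level count (24) is derived from the full range, not from the
   values present.

## The 154-feature signature

17 histogram features are computed on the raw HU values of the prepared ROI;
137 texture features come from six gray-level matrices built on the
discretized ROI. The registry (`featureRegistry()`) is a declarative table
fixing identifiers V1…V154, family and name; the counts per family
(17/26/26/16/16/16/16/16/5) are asserted structurally at registry
construction. Anchored codes: V1 mean, V2 SD, V4 skewness, V5 kurtosis,
V16 root mean square (histogram); V108 gray level non-uniformity normalized
(GLSZM); V141 dependence count non-uniformity (NGLDM).

Conventions that needed a decision:

* **Neighbourhood.** All matrices use 26-connectivity (Chebyshev distance 1);
  GLCM/GLRLM use the 13 unique 3D directions. Distances > 1 and 2D
  aggregation are out of scope.
* **Aggregation.** GLCM/GLRLM features exist in two variants: *averaged*
  (features per direction, then averaged over the 13 directions) and *merged*
  (directional matrices summed, then featurized). Both are part of the
  signature; the redundancy step below can drop one.
* **Skewness/kurtosis.** Fisher moment skewness and non-excess (Pearson)
  kurtosis — a normal distribution scores 3. This matters when reading the
  direction of the kurtosis shift from healthy to ILD.
* **GLCM set.** 26 features: the standard co-occurrence set (joint, difference
  and sum statistics, information correlations) plus the maximal correlation
  coefficient. Degenerate single-level matrices take defined limits —
  entropies 0, uniformities 1, correlation 1 — never NaN.
* **GLDZM distance.** Chebyshev distance of a zone to the nearest non-ROI
  voxel, out-of-grid counting as non-ROI, minimum 1. Other metrics exist in
  the literature; one was fixed so that golden tests are exact.
* **NGLDM.** The dependence count of a voxel is the number of in-ROI
  neighbours within gray-level tolerance α (default 0); the centre voxel is
  never counted, so the count ranges 0…26. Feature weights use count + 1,
  keeping low-dependence emphasis finite at zero. The dependence-count energy
  analogue is excluded, giving 16 features.
* **Normalization.** Feature formulas use probability-normalized matrices;
  the count-based non-uniformities use raw counts.

All six builders are verified against independent brute-force enumeration
oracles on randomized 4×4×4 ROIs, and the GLCM/GLSZM formulas against
hand-computed stripe and checkerboard fixtures.

## Delineation stability

Robustness to re-delineation is measured by the two-way mixed, consistency,
single-rater intraclass correlation ICC(3,1) = (MS_R − MS_E)/(MS_R + (k−1)MS_E).
The consistency form ignores additive rater bias, which is the right choice
here: a systematically tighter observer should not destabilize a feature that
ranks subjects identically. The one-way variant ICC(1,1) is available as a
configuration option. Intraobserver grids use repeated delineations of one
observer as "raters" in the same formula (2 repeats by default; the number of
repeats is a study-design choice, not derivable from first principles).

A feature is retained iff ICC ≥ 0.75 in all four cells (intra/inter ×
both domains). Edge cases: if all ratings are identical the ICC is taken as 1
(perfect agreement — this arises for genuinely constant features such as the
NGLDM dependence-count percentage); if between-subject variance is zero but
raters disagree, the ICC is undefined and the feature counts as unstable.

**Aggregation redundancy.** The averaged and merged variants of each
GLCM/GLRLM feature are z-scored per feature across reference scans, stacked,
and compared as a two-rater consistency ICC per family. When the ICC reaches
0.8 the merged variants are dropped (the averaged variant is kept; which one
to keep is not determined by the analysis, so it is a configurable choice).
The z-scoring prevents scale-heterogeneous features from inflating the
between-row variance and hence the ICC.

## Univariate screening and cross-domain agreement

The per-feature AUC is the Mann–Whitney probability with mid-rank tie credit,
reported *directionally*: no flipping below 0.5. A feature with AUC 0.3 in one
domain and 0.7 in the other has comparable discriminative power but opposite
effect direction, and collapsing that distinction would hide exactly the
cross-domain disagreements the analysis is looking for. Ties get 0.5 credit;
the implementation is rank-based and is property-tested against exhaustive
pair enumeration. Cross-domain agreement is Pearson's r between matched
per-feature AUCs, overall and per family. The positive class is ILD
throughout.

## Models and transfer

Three architectures, all ending in a linear (logistic) classifier:

* **MEAN** — histogram mean only; **MSSK** — mean, SD, skewness, kurtosis.
  Both bypass feature selection entirely.
* **ML** — inside every CV fold: (1) correlation pruning at a sampled
  threshold (greedy; features are ranked by training-fold |AUC − 0.5| and a
  feature is kept iff its absolute Pearson correlation with everything
  already kept stays below the threshold, so of a correlated pair the more
  discriminative member survives — the tie-break had to be fixed by design);
  (2) an L1-penalized logistic path ranks the surviving features by
  regularization entry order; (3) the top k enter a ridge-penalized logistic
  classifier fit by IRLS (iteration-capped so separable folds stay finite and
  deterministic; the intercept is unpenalized).

Hyperparameters — correlation threshold ∈ {0.60, 0.61, …, 0.99}, k ∈ 1…10,
ridge strength log-uniform on [10⁻³, 10³] — are drawn as 500 randomized
samples in total and scored by mean AUC over 4×-repeated 5-fold stratified
CV; the winner is refit on the full source data. Standardization statistics
are always computed on the training fold only and frozen into the model;
the tests verify per-fold centers against the training rows by direct
recomputation. Target-domain data never touch source tuning.

**Testing** applies the frozen model — including its source standardization —
to the target cohort and reports the directional AUC with a stratified
bootstrap percentile CI (2000 resamples by default; the bootstrap flavour is
a design choice, the underlying study reports only "bootstrap").
**Re-optimization** freezes the selected feature signature and refits only
classifier weights in the target domain under the same CV layout, isolating
how predictive the signature itself is once the covariate shift is absorbed
by refitting. **Diagnostics** (TPR, TNR, PPV, NPV, LR+, LR−) are evaluated at
the cutoff maximizing Youden's J over all observed score thresholds, ties
resolved toward higher specificity; the cutoff is estimated on the target
test scores themselves, which is the convention of the reported table this
mirrors — and is documented here as optimistic. LR+ at TNR = 1 is reported as
+Inf; bootstrap CIs use the inverted-ECDF quantile so infinite resample
values propagate cleanly. The cutoff is re-estimated inside every bootstrap
resample.

## The synthetic data

Two generators provide all inputs.

**Image phantoms** (`generatePhantom`, `generateCohort`). A two-lobe
ellipsoidal lung inside a uniform soft-tissue background (40 HU). Healthy
parenchyma draws HU from a shifted gamma with mean −700 HU, SD 120 HU and
skewness +1.2 — the positive skew of aerated lung. ILD shifts the mean by
+150 HU, scales the SD by 1.5, and replaces 20% of lung voxels with
spatially correlated high-attenuation blobs (Gaussian-smoothed noise
thresholded to the target rate, filled with N(−100, 50) HU) — this creates
genuine zone/dependence texture rather than a mere histogram shift, and
lowers skewness and kurtosis. The two domains differ in grid (64³ vs 96³),
voxel spacing (0.14–0.18 vs 0.55–0.8 mm), noise (45 vs 20 HU) and a global
−40 HU calibration bias in the HRCT-like domain. Grid sizes are desk-scale
choices; the phantom parameters themselves are calibration choices of this
package, not values reported anywhere.

Observer variability is simulated by a smooth random boundary displacement
bounded by `boundaryJitterMm`, optionally followed by a regional single-voxel
erosion/dilation. The default study conditions use 0.15 mm jitter and no
morphological step: at that setting the stability stage reproduces the
qualitative outcome the analysis expects — a handful of texture features
unstable in the high-resolution domain, everything stable in the clinical
one. The morphological step is implemented and tested but off by default: on
step-edged phantoms (no partial-volume transition at the lung boundary) even
a regional one-voxel dilation swaps in implausibly large amounts of
soft-tissue signal. If the perturbation would push the Dice overlap with the
input mask below 0.5, the jitter is halved and the morphological step
skipped; if the bound still fails, it is an error.

**Tabular cohorts** (`simulateFeatureCohort`). For transfer experiments at
scale, feature tables are generated directly: 7 informative features (named
by their V-codes, so MSSK finds its moments) plus 13 pure-noise features.
Subjects carry two latent disease-severity axes — densitometric and
texture-like — separated by 2 SD between arms; features load on one axis
with fixed signs reproducing the healthy-to-ILD directions (mean and SD
rise, skewness and kurtosis fall). Because the axes are independent,
combining features from both beats any single feature, so the multivariate
architectures genuinely outperform the univariate one in the source domain.
The target domain applies a fixed per-feature distortion: axis-2 features
lose most of their effect (attenuation to 0.1–0.25 of the source loading,
two of them reversing direction — cross-domain direction flips are a
documented phenomenon for this kind of data), and every feature gets a scale
change and additive bias. Frozen-weight transfer therefore degrades while
re-optimization of the same signature recovers, which is the pattern the
transfer analysis is designed to detect.

What the phantoms deliberately do **not** emulate: airway/vessel anatomy,
partial-volume boundary transitions, respiratory motion, scanner
reconstruction kernels, or any spatial disease gradient. Passing tests
therefore demonstrate correctness of the machinery and the qualitative
behaviour of the statistics under controlled shifts — not clinical
performance on real CT.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; cohort members derive
per-subject seeds from the master seed, and `withSeed` restores the caller's
RNG state. Two runs of the same configuration produce byte-identical feature
tables and summary reports, which the test suite checks by file hash.

Sizes used by the shipped experiments (chosen as desk-scale study
conditions): the end-to-end image study uses 91 + 98 subjects at 64³/96³
with 15 stability cases per domain; the test suite exercises the same
pipeline at 16³/24³ with 8 + 8 subjects per domain; the feature-level
transfer experiment uses 10 cohorts of 40 + 40 subjects per domain with the
full 500-sample hyperparameter search; matrix-builder oracles run on 100
randomized 4×4×4 ROIs and the AUC oracle on 1000 fuzz cases.

## Known limitations

* The ML selector is the L1-logistic path variant; a tree-boosting selector
  with an extra-trees classifier is a plausible alternative architecture and
  is not implemented.
* ICC confidence intervals are not computed; the stability decision is a
  point-estimate threshold, as in the analysis this follows.
* The Youden cutoff is estimated on the target test set (see above), so the
  reported diagnostics are optimistic relative to a held-out operating
  point.
* Image-level phantom cohorts at the default effect size are nearly
  separable, so their model AUCs saturate; the graded transfer pattern is
  carried by the tabular cohorts, whose shift is parameterized explicitly.
* The command-line surface is the R API (`runPipeline` plus stage
  functions); there is no shell executable.
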