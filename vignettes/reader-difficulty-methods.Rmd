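---
title: "Modelling cohort-level reader difficulty from mammographic texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cohort-level reader difficulty from mammographic texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When a panel of radiologists reads the same set of screening mammograms,
some cases are missed (or over-called) by most of the panel and others by
almost nobody. If the *proportion of readers* who err on a case can be
predicted from the image alone, difficult cases can be mined from image
archives to build cohort-tailored self-assessment test sets. `readiff`
implements that pipeline end to end: per-case error proportions from a
reader panel, tertile difficulty labels, breast segmentation and ROI
delineation, a 203-feature radiomic bank, nested cross-validated random
forests with view fusion, and the ROC statistics used to evaluate and
compare the resulting models.

Real reading-study data of this kind are institutionally restricted, so the
package ships a synthetic cohort generator with a *known* texture-to-error
link. Everything downstream is exercised, and its recovery behaviour
verified, without any external data.

## The synthetic cohort

A case consists of four views (LCC, RCC, LMLO, RMLO), each a clustered
lumpy background: `n ~ U{30..60}` Gaussian blobs inside a half-disc breast
silhouette on a dark background, on a tissue baseline of 0.6 with additive
detector noise (`noise_sd = 0.02`). MLO views additionally contain a bright
triangular pectoral wedge in the chest-wall top corner, with inclination
drawn inside the 10–80° band that the segmentation stage accepts. Cancer
cases carry one Gaussian lesion (contrast 0.5, sigma 3 px) in the CC and
MLO views of one side, placed so that the whole localization annulus stays
on-breast.

Two generator choices matter most:

* **Case-level blob width.** One blob width `sigma_case ~ U(2, 8)` px is
  drawn per case and shared by all its blobs. The latent difficulty is its
  standardized value, `d_c = (sigma_case − 5) / (6/√12)`. This makes
  texture coarseness vary meaningfully across cases; drawing every blob
  width independently instead would make the case mean vary by only a
  fraction of a pixel, leaving nothing for a texture feature to recover.
  Because `d_c` is a function of generator parameters — not of extracted
  features — recovery is a genuine end-to-end test of segmentation,
  extraction and modelling together.
* **The reader link.** Reader `r` errs on case `c` with probability
  `plogis(α + β·d_c + b_r)`, `b_r ~ N(0, reader_bias_sd²)`. Defaults:
  `α = logit(0.3)`, `β = 2`, `reader_bias_sd = 0.5`. No empirical
  per-reader performance distribution is available for studies of this
  kind, so the bias SD is an arbitrary but documented choice; `β = 0` is the null condition used for
  calibration tests. On cancer cases an error is, with probability
  `loc_error_frac = 0.5`, a localization error: a positive rating whose
  annotation is displaced uniformly on the annulus `(r, 2r]` around the
  lesion, guaranteeing failure of the localization rule while staying
  on-breast. Otherwise it is a miss (rating ≤ 2, no annotation).

The localization radius defaults to 7% of the image side (13 px at the
default 192 px scale). The conventional 250 px criterion applies to
full-resolution DICOM; at synthetic scale the radius must shrink with the
image, and `difficulty` functions take it as a parameter (default 250 for
full-scale data).

What the generator does **not** emulate: photorealistic parenchyma,
vendor post-processing, reader fatigue or reading order, multi-lesion
cases. A pipeline that passes the recovery tests is demonstrated to work
when difficulty truly is a monotone function of global texture; on real
data that relationship is an empirical hypothesis, not a guarantee.

## Preprocessing

All processing assumes the chest wall on the left; right-sided views are
mirrored first. Segmentation is Otsu thresholding, largest connected
component, morphological opening (disc radius 5 px, configurable), hole
filling. On MLO views a straight-line Hough transform over inclinations
10–80° from vertical runs on a Sobel edge map restricted to the chest-wall
upper quadrant of the mask interior (the breast/background border would
otherwise dominate the edge map). The winning accumulator cell is refined
by a total-least-squares fit to its inlier edge points; the fitted line
must still fall inside the inclination band, otherwise no line is claimed
and the mask is returned unchanged. Accepted lines zero out the chest-wall
side of the mask.

Three ROIs per view: the largest inscribed axis-aligned square (summed-area
binary search, ties to the smallest top-left corner), the retroareolar
square (side 0.25 × breast depth, centred on the nipple point — the
contour point farthest from the chest wall; both choices are modelling
conventions, the source protocols do not specify them), and the whole
breast bounding box. Out-of-mask pixels are excluded from all statistics
rather than zero-filled, so background never contaminates histogram or
texture features; texture matrices treat them as invalid neighbours.
Z-scoring uses the population (1/n) SD over valid pixels; both the
normalized and raw tracks are kept, since the effect of normalization is
itself a question of interest. Coordinates are 1-based `(row, col)` with
inclusive bounding boxes, the native R convention.

## The 203-feature bank

Family sizes are fixed API: histogram 28, GLCM 88, GLRLM 7, GLSM 6,
GLDS 15, NGTDM 15, SFM 8, Laws 18, fractal 2, Gabor 6, RFS/MR8 8,
Fourier 2 (28 + 159 + 16 = 203). `feature_registry()` freezes names and
order. The per-family statistic lists are this package's own registry —
the source literature fixes the counts but not the formulas — and every
definition is written out in the function documentation. Choices worth
calling out:

* Quantization: equal-width binning to `Ng = 32` levels between the valid
  min and max (configurable). This makes all quantized families invariant
  to affine intensity rescaling even without z-scoring.
* GLCM: symmetric co-occurrence at distance 1, four offsets kept separate
  (required to reach 88 = 22 × 4). The 22 statistics are Haralick 1–13
  plus autocorrelation, cluster shade/prominence, dissimilarity,
  homogeneity, IDN, IDMN, maximum probability, and a joint grey-level
  variance; since Haralick 4 *is* "sum of squares: variance", the extra
  variance slot uses the joint form `Σ((i−μ)² + (j−μ)²)/2 · p(i,j)`.
  Grey levels enter all formulas 1-based.
* Degenerate-input guards are explicit and documented: correlation-type
  statistics return 0 when a marginal SD vanishes; the histogram CV is
  computed on min-shifted intensities so it stays finite on z-scored
  (zero-mean) patches; NGTDM coarseness carries an ε = 1e-12 in the
  denominator.
* Laws: the nine direction-averaged 5×5 mask pairs, mean and SD of the
  absolute response over pixels with fully valid support.
* Fractal: support-restricted differential box counting (blocks flat at
  the patch minimum are not counted unless the whole patch is constant),
  so a solid uniform patch has dimension 2 while sparse dots fall below 2;
  lacunarity is the normalized second moment of block masses at box 4.
* Gabor: two wavelengths (3, 6 px) × three orientations, zero-DC complex
  kernels with circular truncation (square truncation makes the bank
  measurably anisotropic). RFS/MR8: 3 anisotropic scales × 6 orientations
  × {edge, bar} collapsed by per-scale orientation-max, plus Gaussian and
  LoG; mean energy per map. The largest filter support is 19 px, and
  patches smaller than that raise an error rather than silently shrinking
  the bank.
* `extract_all()` first crops to the valid bounding box, which makes the
  whole vector invariant to padding with invalid pixels.

Every matrix-based family is verified against an independently written
naive double-loop oracle on random 8×8 patches (with and without invalid
pixels) in the test suite.

## Difficulty labels

A rating of 1–2 is a negative call, 3–5 positive. FP errors are positive
calls on cancer-free cases; FN errors negative calls on cancer cases; a
localization error is a cancer-case reading without a correct localization
— by default counted over *all* readers (a reader who misses the case
cannot have localized it), with a positives-only denominator available.
The localization boundary is inclusive (distance ≤ radius), a documented
choice. Cases are sorted by error proportion (ties broken by case id, so
labels are permutation-invariant) and cut into easy/median/difficult
groups whose sizes differ by at most one, the extra cases going to `easy`
then `difficult`; the median group is excluded from modelling.

## Models and evaluation

Per view, a probability random forest (ranger) classifies easy vs
difficult. The FP basis uses all four views; FN/location use the two
lesion-side views. Nested cross-validation: leave-one-case-out outside,
3-fold × 3-repeat label-stratified inside, with embedded feature selection
(impurity importance, ties by registry order) refit inside every inner
training set — the held-out case never touches selection or tuning, which
the fold plan exposes for auditing. The grid spans trees {50, 100, 500,
1000}, sampled fraction {0.1, 0.5, 1}, depth {1, 5, 10} and selected
features {8, 16, 32, 64, 203}; tuning is scored by mean inner view-level
AUC per view model (whether fusion happened inside tuning is ambiguous in
the source design; the view-level criterion is the package default).
`min.node.size` is fixed at 1 — the probability-forest default of 10
disables splitting entirely at the 15–30-case training sizes this design
produces — leaving depth as the tuned complexity control. A single-cell
grid short-circuits the inner loop to plain LOO. Case probability is the
maximum over view probabilities; the pooled LOO predictions give one ROC
and one AUC.

Evaluation: Mann–Whitney AUC with half-credit ties; sensitivity /
specificity / accuracy at a 0.5 threshold (the operating threshold of the
source tables is unstated); 2000-replicate stratified percentile bootstrap
for 95% CIs, clipped to contain the point estimate; unpaired stratified
bootstrap z-test for across-cohort AUC comparisons; DeLong's structural-
components test for paired comparisons (ROI placement, normalization
effects). DeLong results are cross-checked against pROC in the tests, and
its empirical size verified on null simulations.

## Problem sizes and determinism

All randomness flows from one integer seed through named substreams (cases,
panel, fold plan, forests, bootstrap), so cohorts, labels and model outputs
are bit-reproducible. The desk-scale study conditions used by the analysis
scripts and recovery checks are 60 cases (40 cancer-free / 20 cancer), 20
readers, 192-px views, square-ROI features, and a reduced grid (100 trees,
depth 5, full sampling, k ∈ {16, 203}); at those sizes cohort generation
takes a few seconds, the full feature pass under a minute, and a nested-CV
run about half a minute. The oracle property suite runs on 8×8 patches,
and statistical calibration uses 500 DeLong null simulations and 200
bootstrap coverage simulations.

## Known limitations

* The per-family statistic registries are frozen conventions, not a
  reconstruction of any specific historical toolbox; only the family
  counts are normative.
* The retroareolar definition (nipple point, 0.25 × depth) is a modelling
  convention; whether whole-breast statistics should include segmented-out
  background is treated as settled (excluded) but flagged for sensitivity
  analysis.
* Recovery tests certify the pipeline mechanics, not the clinical
  hypothesis; synthetic textures are far simpler than parenchyma.
* Localization scoring uses only each reader's highest-rated annotation;
  free-response figures of merit (JAFROC) are out of scope.
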