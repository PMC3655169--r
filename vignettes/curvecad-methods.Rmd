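---
title: "Curvelet texture analysis of pulmonary nodules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvelet texture analysis of pulmonary nodules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvecad)
```

## The problem

A solitary pulmonary nodule (SPN) — a single well-circumscribed lung opacity
of at most 3 cm on CT — may be an early-stage lung cancer or any of several
benign lesions, and the two look alike to the eye. curvecad implements a
computer-aided diagnosis analysis for this setting: texture statistics are
extracted from multi-scale, multi-orientation curvelet sub-bands of each
nodule region of interest (ROI), combined with demographic and morphological
covariates, and fed to a radial-basis-kernel support vector machine (SVM).
Because a patient contributes several ROIs, per-ROI predictions are
aggregated into a per-patient *malignance rate* — the fraction of the
patient's ROIs called malignant — which serves as the continuous score for a
patient-level ROC analysis. A longitudinal arm asks whether a texture
statistic (the co-occurrence standard deviation) changes differently over
repeat scans in benign versus malignant nodules.

No CT archive accompanies this analysis, so the package is exercised
end-to-end on a synthetic cohort generator whose statistical structure
mirrors what the downstream stages assume. All conclusions the test-suite
draws are therefore statements about the pipeline's behaviour under this
controlled generative model, not about real CT data.

## Synthetic cohort generator

`gen_roi_image()` builds one nodule ROI: an ellipse with randomized semi-axes
(26–38 % of the image side) and orientation, placed at the centre of a
`side x side` grid (default 64). Inside the ellipse the intensity is a base
level plus a Gaussian-smoothed noise field rescaled so its standard deviation
equals `noise_sd`; `spicule_count` radial ridges of constant ~1.5-pixel width
are overlaid. Outside the ellipse, pixels are exactly 0 and the mask is 0.
The two class defaults (`texture_params()`) differ in noise level (benign 8,
malignant 18 intensity units), smoothing bandwidth (1.8 vs 0.8 pixels) and
spiculation (1 vs 8 ridges), so class membership is expressed through texture
— the signal the curvelet features are built to capture. The mechanism is a
stand-in chosen for controllability; it makes no claim about CT physics.

`gen_cohort()` draws demographics from the class-conditional marginals the
study population exhibits: benign ages normal(50.8, 13.26) and malignant
normal(62, 11.54) years (clamped to 18–95, with a logged message), smoking
probability 0.3962 / 0.4953 and male probability 0.5472 / 0.5991. The nine
morphological covariates are generated as Bernoulli variables — their real
coding is not documented anywhere we could follow — with spicule, lobulation
and vacuole at probability 0.2 (benign) vs 0.6 (malignant) and the rest at
0.5, all configurable.

`gen_longitudinal_cohort()` gives every patient `scans_per_patient` scans.
Total follow-up is lognormal with median 2.0 months and mean 6.9 months
(`meanlog = log 2`, `sdlog = sqrt(2 log(6.9/2)) ≈ 1.574` — the unique
lognormal matching both printed summaries), and at each later scan the
class's `noise_sd` is increased by `drift_per_month × months`. The benign
default drift is positive and the malignant default is 0, producing the
pattern the longitudinal analysis must detect: benign within-nodule
heterogeneity rises over follow-up, malignant stays flat. Because the
follow-up distribution is heavily right-skewed, the median patient is
observed for only two months; the benign drift default is sized so that even
a two-month increase is visible against the feature's per-image variability
(see *Numerical choices*).

## Background removal

`region_grow()` implements seeded region growing: starting from a seed pixel
(default the grid centre), frontier pixels are admitted when their intensity
differs from the running region mean by at most `tol`, processed
first-in-first-out with neighbours enqueued in a fixed order, making the
result deterministic. 4-connectivity is the default with 8-connectivity
available. The growing criterion and connectivity are our choices — the
procedure we re-implement names the method but not its parameters.
`apply_mask()` zeroes background pixels exactly and is idempotent. In the
pipeline the grown region *refines* the delineated mask (their intersection
is used) and is accepted only if it retains at least half of the delineation;
very heterogeneous nodules can stall the growth near the seed, and a
background-removal step must never erase the nodule it was asked to clean.

## The curvelet-style decomposition

`fdct_forward()` is a three-scale frequency-domain tight frame: one low-pass
*coarse* band, 32 oriented *detail* wedges, one high-pass *fine* band — 34
sub-bands under the default configuration (1 + 32 + 1; only the total of 34
is externally constrained, the 32-wedge split is our choice). Squared
radial windows are built from C¹ smoothstep ramps (coarse→detail transition
over normalized frequency 0.15–0.25, detail→fine over 0.35–0.50), and the
detail ring is split by 32 angular bumps of width π/32, cross-faded with
complementary smoothstep ramps and periodic in π. Because `S(t)+S(1−t)=1`
for the cubic smoothstep, the squared windows sum to exactly 1 at every
frequency: the transform conserves energy (Parseval) and the adjoint
`fdct_inverse()` is an exact inverse, both to machine precision — properties
the test-suite checks numerically on random images. Windows depend only on
|ω| and on orientation modulo π, so they are symmetric under ω → −ω and all
coefficients of a real image are real; this real-valued convention is fixed
throughout.

Sub-bands are kept at full `pad_to × pad_to` resolution (undecimated) rather
than wrapped to wedge-shaped grids. This costs memory but buys two things:
the Parseval and round-trip identities hold exactly without wrapping
bookkeeping, and — more importantly for what follows — the ROI *mask*
remains geometrically valid in every sub-band, so texture statistics can be
restricted to the nodule interior. Inputs smaller than `pad_to` (default 64,
a power of 2) are zero-padded centrally; images below 32×32 are rejected as
too small for three scales.

## Co-occurrence texture features

Each sub-band is quantized to `Ng = 64` gray levels and a symmetric
gray-level co-occurrence matrix (GLCM) is accumulated at each of the four
standard offsets (0°, 90°, 45°, 135°); the 14 statistics — entropy, mean,
correlation, energy, homogeneity, standard deviation, maximum probability,
inverse difference moment, cluster tendency, inertia, sum-mean,
difference-mean, sum-entropy, difference-entropy — are computed per offset
and averaged. Logs are base 2 with 0·log 0 = 0; correlation is defined as 0
when the marginal variance vanishes (a fixed convention chosen for
determinism). 34 sub-bands × 14 statistics give the 476-entry texture block;
appending age, sex, smoking and the nine morphology covariates yields the
488 model inputs. Every formula is validated against an independent
double-loop oracle to 1e-10 in the tests.

Two quantization decisions matter and both deviate from the most obvious
default:

* **Absolute (fixed-bin-width) quantization.** Binning each band between its
  own minimum and maximum makes every GLCM statistic invariant to the band's
  overall amplitude — yet amplitude is precisely what grows when nodule
  texture becomes more heterogeneous, and the longitudinal analysis is built
  on detecting that growth through the StdDev feature. The default is
  therefore radiomics-style fixed-width binning: bins of constant width
  centred on the within-mask median, clipped to 64 levels, with per-scale
  widths (`default_bin_widths()`: coarse 2.5, detail 0.2, fine 1.25
  intensity units) sized so 64 levels cover the within-nodule coefficient
  spread each scale exhibits under the generator's intensity scale (nodule
  base ≈ 100). Min-max binning remains available (`bin_widths = NULL`).
* **Mask-restricted pair counting with erosion.** Only pixel pairs lying
  inside the ROI mask eroded by 3 pixels are counted. The nodule boundary is
  a step of ≈ 100 intensity units, and its band-limited response otherwise
  dominates the detail-band statistics, drowning the interior texture that
  distinguishes the classes. Erosion by 3 pixels keeps the pair set clear of
  the boundary's main lobe while leaving enough interior pixels (≈ 150 of a
  typical ≈ 370-pixel nodule) for stable counts. If erosion empties a small
  mask the un-eroded mask is used; plain-matrix input uses the whole grid.

## Class balancing (SMOTE)

`smote()` is implemented from scratch: for every minority row,
`rate_percent/100` synthetic rows are placed uniformly at random on the
segment to one of its k = 5 Euclidean nearest minority neighbours
(deterministic under a seed; ties in the neighbour search broken by row
index). `balance_dataset()` reaches an arbitrary per-class target with the
smallest sufficient multiple-of-100 % rate followed by seeded subsampling of
the surplus, and accepts an explicit target for *both* classes: the source
analysis reports balanced counts (9393 + 9393) that exceed its majority
class (6977), implying the majority was also augmented, and the explicit
target mechanism reproduces those counts without asserting how the original
procedure did it. Original rows are never modified or removed, synthetic
rows are flagged in a provenance column, and binary covariates are
interpolated as continuous (no SMOTE-NC variant is attempted).

## Classifier and evaluation

`train_svm()` z-scores features with training-set statistics (population
standard deviation, so duplicating every row leaves the learned transform —
and hence the decision function — unchanged) and delegates the soft-margin
dual to the libsvm solver in e1071, with the convergence tolerance tightened
to 1e-7. The stored model is the kernel expansion itself — support vectors,
signed dual weights, bias, γ — and `decision_value()` evaluates
f(x) = Σᵢ αᵢyᵢ·exp(−γ‖xᵢ−x‖²) + b directly, oriented so positive means
malignant; tests verify this sum against libsvm's own decision values and an
explicit-loop oracle. Defaults C = 1 and γ = 1/d on z-scored features are
package choices, not inherited facts.

`kfold_cv()` uses stratified folds filled through one global rotating
counter (so leave-one-out works and class proportions stay within one row of
balance). The default grouping keeps all ROIs of a patient in one fold:
patient-level leakage across folds would otherwise inflate the malignance
rate evaluation, since same-patient ROIs are highly correlated. Per-ROI
folding is available for emulation of designs that ignore this.

`roc_auc()` sweeps thresholds over the unique malignance rates, integrates
by the trapezoid rule (with ties this equals Mann-Whitney U/(n₊n₋) with half
credit, an identity the tests check to 1e-10 against pair enumeration), and
reports a two-sided tie-corrected normal-approximation Mann-Whitney p-value.
`chi_square_2x2()` is Pearson's statistic without continuity correction —
the convention that reproduces the published demographic comparisons
(smoking 2.79, sex 0.78); the Yates-corrected values (≈ 2.41, ≈ 0.62) do
not match, which fixes the convention unambiguously.

The malignance rate itself is defined as
(# ROIs predicted malignant)/(# ROIs). The analysis we follow prints this
formula only as an inaccessible figure, so this reading is an assumption,
stated here prominently; patient-level class calls threshold it at 0.5.

## Longitudinal change

`feature_change()` averages a feature over each scan's ROIs, takes
last-minus-first per patient (patients with a single scan are excluded with
a warning), and summarizes per class with mean and t-based 95 % CI. The
default feature is the mean StdDev over the 32 detail sub-bands. Whether the
original "Standard Deviation" was a first-order sub-band statistic or a
co-occurrence moment is not documented; the co-occurrence reading is adopted
uniformly.

## Numerical choices and problem sizes

* Seeds: every generator and stochastic step takes an explicit seed; one
  root seed drives per-stage children via a documented hash
  (`derive_seed()`), and RNG state is always restored afterwards.
* The benign `drift_per_month` default (2.5 intensity units of `noise_sd`
  per month) is sized against the feature's measurement noise: a median
  (two-month) follow-up then shifts `noise_sd` by 5 units, which moves the
  detail-band StdDev feature by roughly its per-image standard deviation,
  so the rise is visible in most patients and unambiguous in the
  20-per-class cohort average — the qualitative pattern the longitudinal
  analysis exists to detect. Malignant drift is 0.
* Degenerate inputs have fixed conventions: constant grids quantize to one
  level; correlation at zero variance is 0; empty masks raise errors;
  region-growing refinements that lose over half the delineation are
  rejected.
* Test and demonstration cohorts use 40 patients (14 benign / 26 malignant,
  mirroring the 1:2 study imbalance) with 3–5 ROIs each at 64×64 pixels,
  and 20 + 20 longitudinal patients with two scans; these sizes give stable
  statistics while keeping a full run in the order of a minute.

## What passing tests do and do not show

The generator produces class-separated textures by construction, so
end-to-end discrimination results (patient-level AUC ≥ 0.9 on synthetic
cohorts) certify the plumbing — features carry class signal through
balancing, training, grouped cross-validation and patient aggregation
without leakage or inversion — not clinical performance. Real CT nodules
differ in ways the generator does not attempt: partial-volume effects,
scanner noise spectra, 3-D structure collapsed to 2-D slices, inter-reader
delineation variability, and class overlap far heavier than the defaults.
The published real-data results (AUC 0.949, 80 % → 97 % balanced-data
accuracy) are consequently out of reach of any synthetic reproduction and
are not targets of this package's tests.

## Known limitations

* 2-D only; no DICOM/volume handling and no scanner noise model.
* The 32-wedge detail layer is one of several splits consistent with a
  34-band total; results depend on it only through feature names.
* Fixed bin widths are tied to the generator's intensity scale; applying
  the pipeline to data on another scale requires re-sizing them (they are
  arguments, not constants).
* SMOTE interpolates binary covariates continuously; rounded variants are
  deliberately not defaulted.
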