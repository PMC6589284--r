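---
title: "Methods: lymphoblast image classification in blastclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lymphoblast image classification in blastclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastclass)
```

## The problem

Acute lymphoblastic leukaemia (ALL) screening from blood smears asks
whether a white blood cell is a mature lymphocyte or a lymphoblast, and if
the latter, whether it is of the pre-T or pre-B subtype. The two subtypes
respond to different chemotherapy, so the distinction carries prognostic
weight, yet their morphology overlaps heavily. `blastclass` implements the
two standard computational routes to this three-class decision — a
handcrafted-feature route (46 descriptors feeding a GA-optimized SVM
cascade) and a small convolutional network consuming raw pixels — together
with the split/metric protocol used to compare them and a synthetic cell
generator that stands in for real image archives.

Inputs are 256 × 256 RGB single-cell images; the handcrafted route also
requires two binary masks (whole cell, nucleus), which real datasets
provide by manual segmentation. Automatic segmentation is deliberately out
of scope: masks are inputs.

## Conventions

All modules share one coordinate convention: row-major arrays, origin at
the top-left, 0-based pixel coordinates in exported structures (contours,
centroids). Masks are logical matrices, foreground `TRUE`, stored on disk
as single-channel PNG with foreground 255. Non-conforming rasters are
rescaled on load: bilinear for images, nearest-neighbour plus re-threshold
for masks, because mask binarity must survive resampling.

## The 46 descriptors

The descriptor table has three groups. Choices the feature names do not
fully determine were fixed once, as follows.

**Geometry (1–15).** The nucleus ellipse fit uses second-order central
moments (semi-axes `2·sqrt(eigenvalue)`, so a disc of radius *r* gives
`a = b = r`). Perimeter is the chain length of the traced boundary with
diagonal steps weighted √2. *Form factor* is implemented literally as
area/perimeter, as the source table words it, although the conventional
dimensionless form factor is `4πA/P²`; the conventional variant is
available via `feature_options(conventional_form_factor = TRUE)`.
*Roundness* is `4A/(π·major²)` and *compactness* `P²/A` — the names are
standard and the definitions were left unstated, so the usual
region-property definitions are used. *Eccentricity* is the major/minor
axis ratio. *Fold symmetry* reflects the half of the nucleus on the
negative side of the major axis onto the positive side and reports overlap
over the larger half, in (0, 1]. The *hand-mirror proportion* is
`(a + c)/(b + c)` with `c` the maximum distance from the nucleus centroid
to a cell-contour point outside the fitted nucleus ellipse; when no
contour point lies outside (cell ≡ nucleus) `c` falls back to the maximal
contour distance, which makes the circular limit exactly 1. Note a
geometric consequence of this proportion: for a fixed elongated nucleus
(`a > b`) it *decreases* toward 1 as the protruding lobe extends `c`, and
for a circular nucleus it is 1 regardless of any lobe — the feature
measures the interplay of nuclear elongation and cell extent, not lobe
size alone. The *fractal dimension* is a box-counting estimate on the
inner boundary pixel set at box sizes 2–64, least-squares slope of
log count against log(1/size). *Contour moments* are population moments of
centroid-to-boundary distances; skewness is Fisher `m₃/m₂^1.5`, kurtosis
is non-excess `m₄/m₂²` (normal → 3).

**Texture (16–34).** All texture features are computed on the grayscale
(0.299 R + 0.587 G + 0.114 B) nucleus bounding-box patch; pixels inside
the box but outside the mask are filled with the mean nucleus intensity so
background never leaks into the statistics. The Haar transform is the
orthonormal separable 2-D transform; the level *n* of the reported bands
is not fixed by the source description, so it defaults to 1 and is
configurable. "H" is the horizontal-direction detail (high-pass across
columns, low-pass across rows): a vertically running step edge loads H.
The co-occurrence matrix quantizes gray to 8 equal bins over [0, 255],
accumulates symmetric pair counts at distance 1 for 0°/45°/90°/135°,
averages the four normalized matrices, and reports contrast, correlation
(defined as 0 for a single-level patch), homogeneity, energy and base-2
entropy with `0·log 0 = 0`. Fourier statistics use the unnormalized
forward DFT magnitude (DC included). Which array the "inverse transform"
statistics describe is ambiguous — the inverse of the full spectrum
reproduces the input exactly — so the package applies the 1/N²-normalized
inverse to the *magnitude-only* spectrum (phase zeroed), a phase-blind
autocorrelation-like summary. Zero-variance arrays get skewness 0 and
kurtosis 1 so every vector stays finite.

**Colour (35–46).** Mean R, G, B on the [0, 255] scale and mean H, S, V on
[0, 1] (hexcone conversion; achromatic pixels take hue 0), over the
nucleus and over the cytoplasm (cell minus nucleus).

## The GA-SVM cascade

The SVM solves the usual soft-margin problem (penalty C) with RBF kernel
`exp(−γ‖x − x′‖²)`; the quadratic program is delegated to libsvm via
e1071. Because the RBF kernel weighs all inputs equally, features are
standardized to zero mean and unit variance using training-set statistics
only, applied unchanged to validation and test data.

The GA encodes `g1|g2|g3` = C bits, γ bits, feature mask. C and γ decode
linearly over configurable ranges; the source settings fix population 100,
100 generations, crossover 0.80, mutation 0.06, elitism 0.05, and 20 bits
per parameter, but state no ranges — the defaults here are C ∈ [0.01,
10⁴] and γ ∈ [10⁻⁴, 10], recorded in every run record. With linear
decoding a random population's expected γ is mid-range, so on
high-dimensional standardized features (where useful widths are ≪ 1) small
GA budgets should narrow `gamma_range` to the task; the full reference
budget explores the default range adequately. Crossover is single-point,
drawn separately within the parameter region `g1|g2` and within the mask
region `g3` (the two regions have different semantics; cut points are
uniform within each region, and a cut at position 0 swaps the whole
region). An all-zero feature mask is untrainable and scores fitness 0
rather than being repaired; an all-zero-fitness population degrades
roulette selection to uniform. Elitism copies the top
`ceiling(0.05 · population)` unchanged, which guarantees the per-generation
best fitness is non-decreasing. Fitness is validation accuracy alone — the
lineage GA-SVM formulation also weighs feature count, but the adopted
description uses accuracy only.

Classification runs as a cascade: stage 1 separates normal lymphocytes
from blasts; only samples called "blast" reach stage 2 (pre-T vs pre-B),
which is trained on blast samples only. Each stage gets an independent GA
run.

Two related table constants deliberately disagree in the source material:
the descriptor table lists 46 features while the GA settings table sets
`n_f = 42`. The package does not guess which four features were dropped;
the mask length defaults to the number of feature columns presented and
`n_f` is configurable.

## The CNN

Three convolutional feature-extraction blocks (3 × 3 filters, zero-padded
"same", ReLU, 2 × 2 max-pool of stride 2) with 32/32/64 filters take a
256-px input through spatial sizes 256 → 128 → 64 → 32, flatten to 65536,
then dense-64 + ReLU, dropout 0.5, and a 3-unit output. The output
activation is sigmoid, as architected in the source — unusual for three
mutually exclusive classes — trained with per-class binary cross-entropy
against one-hot targets; a softmax switch exists for the conventional
choice. Prediction is the score argmax with ties broken toward the lowest
class index. The optimizer is not named beyond its learning rate (0.001),
so Adam is used, seeded and exposed in configuration. Every epoch
regenerates the augmented training set (horizontal flip with probability
½, counterclockwise shear uniform in [0, 0.2] rad, isotropic zoom uniform
in [0.8, 1.2]; 20 copies per image with the original as the first copy,
121 → 2420) with a fresh derived seed. Warped samples are bilinear with
edge clamping.

The implementation is vectorized base R: convolutions evaluate as im2col
plus GEMM through BLAS, gradients are exact backpropagation (verified
against central finite differences to ~10⁻⁹ relative error), and all
randomness — initialization, augmentation, shuffling, dropout — derives
from one integer seed, so training is bit-reproducible.

The operation-count model charges a convolutional sublayer
`n_{l−1}·s_l²·n_l·m_l²` operations. The published cost table counts the
input as a single channel (`n₀ = 1`, colour channels costed separately)
while the trained model consumes 3-channel input with filters spanning
channels; the package preserves both conventions side by side rather than
resolving the discrepancy — the cost model reproduces the published table
verbatim, the network trains on RGB. A training pass is costed at 3× a
forward pass (forward plus two backward gradient convolutions).

## The synthetic generator

The generator emulates the morphology cues that drive the real
classification: a cell body disc with an elliptical nucleus whose boundary
is `r(θ) = r_ellipse(θ)·(1 + roughness·Σ_{k=3..6} a_k sin(kθ + φ_k))` with
random phases and normalized amplitudes (so the perturbation amplitude
equals the roughness knob); a fold-symmetry defect that removes an angular
wedge of width `defect·π` from one half (the nucleus target area is
inflated by `1/(1 − defect/2)` to keep the N/C ratio on target); an
optional hand-mirror lobe (a disc of radius `strength·a` attached at the
cell boundary along the major axis ± 30°, with the nucleus area again
compensated for the added cytoplasm); granules as darker 1–2-px discs at a
set density per 1000 nucleus pixels; and per-pixel Gaussian colour noise
around class mean colours, clipped and rounded to 8-bit so written PNGs
round-trip losslessly. Per-cell seeds are `master seed + sample index`.

Two phenotype sets ship. `"realistic"` encodes the reported cytology with
overlapping classes: lymphocytes with round smooth nuclei and N/C ≈ 1.2;
pre-T with convoluted asymmetric rough nuclei, N/C ≈ 2.8 and dust-like
granulation; pre-B with N/C ≈ 2.4 and a frequent hand-mirror lobe.
`"separated"` exaggerates the same axes (including stain colour) and
exists for pipeline sanity checks, where a correct implementation must
score highly. What passing tests on synthetic data show is that the
pipeline recovers structure it is pointed at — not that real-smear
accuracy is reproduced; real staining variability, focus artefacts,
touching cells and segmentation error are not emulated.

The split protocol mirrors the reference experiment: stratified sampling
without replacement per class with one seed per split, partitions of
31/45/45 per class for train/validation/test (3 × 121 = 363 = the whole
pool, so each split is a permutation of the full dataset; pools larger
than 3× the counts give a bootstrap-like mode). Whether the original
protocol shared samples across its ten splits is not stated; both modes
are supported.

## Numerical and degenerate-input choices

Empty cytoplasm (cell ≡ nucleus) raises a degenerate-sample error for
ratio and colour features; masks with fewer than 8 boundary pixels refuse
fractal/contour estimates; single-row or single-column nuclei refuse the
symmetry fold. Aggregation uses the sample (n−1) standard deviation — the
convention under which the reference per-split accuracies reproduce their
printed average spread — and reports round half-up to two decimals while
full precision is retained internally. The accuracy denominator is the
full double sum of the confusion matrix (its printed form repeats an
index, which only this reading makes consistent with the printed
matrices). Report tables whose row sums disagree with the declared test
composition trigger a validation warning rather than silent acceptance, as
one published best-case table does.

## Problem sizes used by the test suite

The suite exercises the full-size (256-px) feature path but trains
networks at reduced scale, chosen once as the package's smoke scale: the
memorization check runs 12 well-separated 64-px cells for 10 epochs
(batch 3, lr 0.002 — at batch = n, 10 epochs give only 10 optimizer steps,
too few for any network to fit); the end-to-end comparison runs two splits
of a 102-cell 64-px dataset (10/12/12 per partition) with 4 augmentation
copies, 5 epochs, and a 20-chromosome, 10-generation GA, completing in
roughly a minute on one CPU with both methods above 80% accuracy on the
separated phenotypes. Monotonicity properties (symmetry defect ↓ fold
symmetry, roughness ↑ boundary dimension, lobe strength moving the
hand-mirror proportion toward 1) average over 20 seeds at 128 px.

## Known limitations

The hand-mirror proportion compresses lobe information once the nucleus is
near-circular (see above). The box-counting dimension on 64–128-px masks
uses few box scales and is a coarse roughness index rather than a
converged Hausdorff estimate. Linear gene decoding makes GA exploration of
wide hyperparameter ranges slow at small budgets (log-scale ranges can be
emulated by narrowing the range). The CNN is CPU-bound R; it is meant for
the protocol sizes here, not for GPU-scale training. Real-data accuracies
from the original archive are not reproducible without that archive; the
package instead verifies every desk-checkable published quantity and the
behavioural properties of each stage.
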