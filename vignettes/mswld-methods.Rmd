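---
title: "Multiscale spatial Weber descriptors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale spatial Weber descriptors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mswld)
```

## The problem

In computer-aided mass detection, segmentation of a mammogram produces
candidate regions of interest (ROIs) that mix true masses with suspicious
but normal parenchyma. The false-positive reduction step is a binary
texture-classification problem on those ROIs: mass versus normal tissue.
This package implements a complete desk-scale harness for that problem —
a multiscale spatial Weber local descriptor (MSWLD) for texture, a
margin-based local-learning feature selector, and an RBF-SVM evaluation
pipeline — together with a synthetic two-class ROI generator so that every
stage can be exercised and tested without access to clinical images.

## The descriptor

### Per-pixel Weber features

Weber's law says the just-noticeable intensity increment is proportional to
the background intensity, which motivates describing each pixel by relative
rather than absolute differences. For a pixel with intensity $I_c$ and the
$P$ neighbors $I_i$ on the square ring of radius $R$ around it, the
*differential excitation* is

$$\varepsilon = \arctan\!\Big[\sum_{i=0}^{P-1} \frac{I_i - I_c}{I_c}\Big]
  \in [-\pi/2, \pi/2],$$

positive when the pixel is darker than its surround. The arctangent bounds
the response and damps noise. Supported scales are $(P, R) \in \{(8,1),
(16,2), (24,3)\}$ — the ring of side $2R+1$ holds exactly $P = 8R$ pixels,
taken at integer offsets without interpolation.

The *gradient orientation* always uses the radius-1 cross regardless of the
excitation scale: with $I_{73}$ the left-minus-right and $I_{51}$ the
below-minus-above difference,
$\theta' = \operatorname{atan2}(I_{73}, I_{51}) + \pi \in [0, 2\pi]$, then
quantized to $T$ dominant orientations by
$t = \lfloor \theta'/(2\pi/T) + 1/2 \rfloor \bmod T$.

### Histogram assembly

Each valid pixel contributes one count to a $(T, M, S)$ histogram: $T$
orientation columns, with the excitation range $[-\pi/2, \pi/2]$ split
uniformly into $M$ segments of $S$ bins. Flattening is segment-major (all
orientations of segment $m$, then segment $m+1$), giving $T \cdot M \cdot S$
bins, and every histogram is L1-normalized. The package default
$(T, M, S) = (4, 4, 5)$ gives 80 bins per histogram.

The *spatial* descriptor (SWLD) partitions the ROI into an $r \times c$
block grid (remainder pixels distributed one per leading block), computes an
independent histogram per block and concatenates them row-major. The
*multiscale spatial* descriptor (MSWLD) repeats this at several $(P, R)$
scales and concatenates the per-scale descriptors in ascending radius. The
length is therefore $r \cdot c \cdot n_{\text{scales}} \cdot T M S$ — e.g.
1280 features for a $4\times4$ grid at one scale and 2000 for $5\times5$:

```{r dims}
descriptor_length(wld_params(4, 4, 5), "4x4", "24:3")
descriptor_length(wld_params(4, 4, 5), "5x5", "24:3")
```

### Numerical choices

* **Zero centers.** $I_c = 0$ uses denominator 1. For integer images this
  equals clamping the center to 1; unlike a blanket $\max(I_c, 1)$ it keeps
  the descriptor exactly invariant under multiplicative rescaling of
  strictly positive images, an invariance the test suite checks.
* **Flat crosses.** $\operatorname{atan2}(0, 0) := 0$, so perfectly flat
  neighborhoods land deterministically in the $\theta' = \pi$ bin.
* **Binning edges.** Excitation bins are uniform with the upper edge
  $\varepsilon = \pi/2$ closed into the last bin.
* **Borders.** No padding: a scale-$R$ histogram uses pixels at least $R$
  from the block border (the orientation cross needs only 1), and every
  block excludes its own border independently.
* **No resizing.** ROIs of different sizes are never resampled; per-block
  L1 normalization makes the spans comparable across sizes.

## Feature selection

MSWLD dimensionality (1280–2000 and up) invites overfitting, so features
are weighted by margin-based local learning. For sample $i$, soft
nearest-miss and nearest-hit distributions over the opposite- and
same-class samples are

$$P(r \mid w) \propto \exp(-\lVert x_i - x_r \rVert_w / \sigma),$$

with $\lVert \cdot \rVert_w$ the $w$-weighted L1 distance (the printed
source formula has a positive exponent, which would make the *farthest*
neighbor most probable; the negative sign is what "nearest" semantics and
the original algorithm require). The margin vector
$z_i = E_{\text{miss}} |x_i - x_r| - E_{\text{hit}} |x_i - x_r|$ is positive
along features that pull hits closer than misses, and the nonnegative
weights minimize the L1-regularized logistic margin loss

$$\frac{1}{n}\sum_i \log(1 + e^{-\langle w, z_i\rangle}) + \lambda \lVert w \rVert_1,
 \quad w \ge 0.$$

The fit alternates: freeze $w$ and compute all $z_i$ (compiled, $O(n^2 m)$);
then descend the frozen-margin objective with up to ten backtracking
gradient steps in the parameterization $w_j = v_j^2$ (which enforces
nonnegativity without projection). A single gradient step per outer
iteration was tried first; it leaves fully-regularized fits stranded
mid-decay, so the short inner descent — closer to the original algorithm's
per-iteration subproblem solve — is used instead. Iteration starts at
$w = 1$, is fully deterministic, and stops when
$\lVert \Delta w \rVert_2 < 10^{-4}$ or after 200 outer iterations
(a non-converged fit returns the current weights with a warning).

Features with $w_j > 10^{-4}\max(\max w, 1)$ are retained. The threshold is
relative to the largest weight but floored at $10^{-4}$ absolute: weights
start at 1, so a fit collapsed uniformly toward zero retains *nothing*
rather than everything, keeping the selected-feature count non-increasing
in $\lambda$.

$\sigma$ (kernel width) and $\lambda$ (sparseness) can be tuned by the
cross-validated wrapper `tune_feature_weights()` over default grids
$\sigma \in \{0.05, 0.1, 0.2, 0.3, 0.5, 1\}$,
$\lambda \in \{0.1, 0.3, 0.5, 0.7, 1, 2\}$, scored by validation-fold AUC of
an RBF-SVM on the selected features (fixed $C = 1$,
$\gamma = 1/m'$ — a full nested $(C, \gamma)$ search inside the wrapper
would multiply cost for little ranking benefit). The default *fixed* pair
used by `mswld_crossval()` is $(\sigma, \lambda) = (0.3, 0.1)$: features
are z-scored per training fold before selection (the same space the SVM
sees), and in that space margin magnitudes for block-histogram descriptors
are small, so the heavier $\lambda$ values appropriate for raw
mammographic descriptors prune everything; $\lambda = 0.1$ is the low end
of the standard grid and leaves a few dozen informative spans.

## Classification and evaluation

The classifier is a soft-margin SVM with RBF kernel
$K(u, v) = e^{-\gamma \lVert u - v\rVert^2}$ (libsvm via e1071 — the same
underlying library the original system used), with labels $y = +1$ for
normal and $y = -1$ for mass ROIs. $(C, \gamma)$ are tuned coarse-then-fine:
$C = 2^{-5}, 2^{-3}, \ldots, 2^{15}$ against
$\gamma = 2^{-25}, 2^{-23}, \ldots, 2^{3}$ by stratified 3-fold accuracy,
then half-exponent steps within $\pm2$ exponents of the coarse winner. Ties
prefer smaller $C$, then smaller $\gamma$ (the least-flexible model among
equals).

Evaluation is stratified five-fold cross-validation. Stratification is a
deliberate strengthening of plain random partitioning: it stabilizes
small-sample metrics while preserving the "different class ratios per fold"
spirit at the sample level. Inside every fold, and only on its training
split: features are z-scored, the selector is fitted and thresholded, and
the SVM is tuned and trained; the held-out fold contributes confusion
counts (mass = positive class), sensitivity, specificity, accuracy and the
ROC area Az. Az uses the Mann–Whitney formulation on raw decision values
(ties count one half) — ranking needs no probability calibration. Reported
aggregates are mean ± SD over exactly the $k$ folds. Whether the original
system tuned $(C, \gamma)$ once or per fold is not stated; this package
tunes per fold (no leakage) and accepts fixed values via configuration.

## The synthetic ROI generator

`synth_rois()` emulates the two texture classes the classifier must
separate, not breast physics:

* shared background: Gaussian white noise low-pass filtered at
  $\sigma_{\text{bg}} = \text{side}/24$, scaled to SD 1500 counts around a
  mean of 25 000 (16-bit range, mirroring 16-bit mammographic scans);
* **mass-like**: plus a centered Gaussian blob, radius
  $0.2$–$0.4\times$ side, $\pm5\%$ center jitter, axis-ratio jitter
  0.85–1.2, random rotation, amplitude `contrast` background-SDs;
* **parenchyma-like**: plus oriented streaks — white noise filtered with an
  anisotropic Gaussian ($\sigma_{\text{long}} = \text{side}/8$,
  $\sigma_{\text{short}} = 1.2$) at a random orientation, amplitude
  $0.5\times$ `contrast` background-SDs;
* additive Gaussian pixel noise at $0.2$ background-SDs (or multiplicative
  2% speckle).

Both classes share one background process and the class component scales
with `contrast`, so `contrast = 0` makes the generators distributionally
identical — the null case used to check that the descriptor pipeline does
not manufacture separation. Defaults are 100 ROIs per class with sides
drawn uniformly in 64–256 px (±8% aspect jitter) at `contrast = 5`,
deterministic from one master seed via derived child seeds. The minimum
side of 64 px keeps a $5\times5$ grid valid at scale $(24, 3)$.

What passing tests on this generator do **not** show: real parenchyma is
non-stationary, masses are often spiculated rather than Gaussian, scanner
characteristics vary, and class overlap is far larger than between these
two synthetic processes. The generator demonstrates that the pipeline's
machinery — descriptor sensitivity to blobs vs oriented texture, selection,
tuning, leakage-free evaluation — functions end to end; it says nothing
about clinical performance.

## Problem sizes

The shipped tests and the acceptance script use: descriptor oracle checks
on images up to $16\times16$; invariance properties over 200 random draws;
selector recovery on $100 \times 50$ problems over 10 replicates; and the
end-to-end study on 200 ROIs (100 per class) with
$\mathrm{MSWLD}_{24,3}(4,4,5,4\times4)$, five folds, per-fold selection and
per-fold coarse+fine SVM tuning, plus a label-permutation control. These
sizes exercise every code path while keeping a full run in the minutes
range on a single core.

## Known limitations

* Square-ring neighborhoods only — no interpolated circular (LBP-style)
  sampling, no rotation-invariant or uniform-pattern variants.
* Binary classification only; the selector and the evaluation harness
  assume labels in $\{+1, -1\}$.
* `tune_feature_weights()` scores candidate $(\sigma, \lambda)$ pairs with
  a fixed-parameter SVM; pathological data could rank pairs differently
  under a fully tuned classifier.
* The reported counts of retained features depend on the thresholding rule
  described above; no claim is made that they match any particular count
  obtained on clinical data.
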