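---
title: "Classifying dried-fruit geographical origin from NIR hyperspectral images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dried-fruit geographical origin from NIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oleasterHSI)
```

## The problem

Dried narrow-leaved oleaster (*Elaeagnus angustifolia*) fruits from
different growing regions (Gansu, Ningxia, Xinjiang) differ subtly in
composition, and therefore in their near-infrared reflectance. A
push-broom NIR hyperspectral camera (874–1734 nm, 256 bands, 320-pixel
scan lines) images trays of individual fruits; the task is to assign each
fruit to its origin from its averaged single-fruit spectrum. This package
implements the complete chain — calibration, segmentation, spectral
preprocessing, data-driven wavelength selection, and three classifier
families — and, because no public hyperspectral accession of such fruits
exists, a synthetic scene generator that emulates the instrument and
sample structure so every stage is testable end to end.

## The measurement model

Raw digital numbers are converted to relative reflectance with the
standard two-point calibration

$$I_c = \frac{I_r - I_d}{I_w - I_d},$$

where $I_d$ and $I_w$ are dark-current and white-panel reference frames.
References are stored per scan line (width × band) and broadcast along
the scan direction, which is how a line-scan camera is calibrated; a
full-frame reference is also accepted. Reflectance slightly outside
$[0,1]$ is *not* clipped: clipping would bias the area normalization that
follows. A guard tolerance of $10^{-9}$ on $I_w - I_d$ turns silent
division blow-ups into an explicit error naming the offending element.

## Segmentation and per-fruit spectra

Fruits lie separately on a black plate, so a single gray-scale band at
1119 nm separates foreground from background. The threshold rule is
Otsu's method by default (the band is prescribed by the acquisition
protocol; the threshold rule is not, so a fixed override is provided).
Connected components are 8-connected; components under 30 px are
discarded as specks. No morphological cleanup is applied by default —
on well-separated fruits it has nothing to fix, and leaving it out keeps
the default path minimal and documented.

Per-fruit preprocessing is applied in a fixed order:

1. **Band crop** to wavebands 31–230 (1-based inclusive), i.e. 200
   variables spanning 975–1646 nm, dropping the noisy spectrograph edges.
2. **Wavelet denoising** of each pixel spectrum: Daubechies-6,
   decomposition level 3, soft thresholding with the universal
   (VisuShrink) threshold
   $\hat\sigma\sqrt{2\log n}$, $\hat\sigma = \mathrm{median}|d_1|/0.6745$.
   Two deliberate choices here. First, the transform uses *periodized*
   boundary extension rather than symmetric extension: periodization
   keeps the filter bank exactly orthonormal, so a zero threshold
   reconstructs the input to round-off and the VisuShrink noise model is
   exact. Second, only the finest detail level is thresholded by
   default: white noise spreads its energy evenly across scales, but the
   ~10 nm absorption features live in the coarser detail levels, and at
   pixel-level SNR the universal threshold sits far above their
   coefficients — thresholding every level erases feature structure
   *identically in every pixel*, a systematic bias that the subsequent
   fruit averaging cannot undo (measured class-mean derivative extrema
   shift by 2–9 nm, independent of sample size). Thresholding the
   noise-dominated finest level removes about half the noise energy at
   near-zero feature bias, and the real denoiser of this pipeline is the
   averaging over hundreds of fruit pixels anyway. Classical all-level
   VisuShrink remains available (`threshold_levels = 3`).
3. **Area normalization** of each pixel spectrum (divide by its sum over
   the retained bands), removing intensity effects of fruit size and
   shape.
4. **Averaging** over the fruit's pixels. Averaging is convex, so the
   per-fruit spectrum still sums to one — a property the test suite
   asserts on every generated table.

Crop position (first) is the implementer's choice; doing it before the
wavelet step saves two thirds of the transform work and removes the
discarded noisy edges from the threshold estimate.

## Effective wavelength selection

Class-mean spectra are differentiated twice with a Savitzky–Golay filter
and the origin-discriminating wavelengths are read off the derivative
curves. The published procedure is manual ("peaks and valleys with
greater differences"); the automation here makes it explicit:

* candidates are interior local extrema of any class curve;
* each candidate is scored by its **between-class spread**, the max minus
  min across the three class curves at that band (this package's explicit
  operationalization of "greater differences");
* candidates below the median candidate spread are pruned
  (`spread_quantile = 0.5`);
* survivors are kept greedily in descending spread order subject to a
  minimum separation of 8 nm, up to `n_max = 22`.

Identical class curves yield an empty selection, not an error. A
`fixed_wavelengths()` path accepts an explicit nm list (for instance a
previously published 22-wavelength set) and bypasses selection.

The derivative window is 9 bands (~30 nm on the retained 3.37 nm grid),
polynomial order 2. A wider 13-band window was evaluated and rejected:
with absorption features of ~10 nm sigma spaced as little as 30 nm apart,
the 44 nm window systematically drags derivative extrema more than one
band off the feature center, which defeats ±1-band recovery; 9 bands
matches the feature scale, and class means averaged over hundreds of
fruits need little extra smoothing. Derivatives are taken with respect to
band index by default; the selection rule is invariant to that scale
choice.

The orchestrated pipeline adds one robustness rule: if the default
selection returns fewer than 11 bands — the minimum input the CNN's
no-padding conv/pool stack can accept — selection is repeated with the
pruning quantile set to 0 (ranking and separation rules unchanged).

## Classifiers

**PLS-DA.** Origin labels are dummy-coded 001/010/100 (Gansu, Ningxia,
Xinjiang) and the centered spectra are regressed onto the three dummy
columns by SIMPLS; a prediction is the argmax over the three predicted
columns, making the usual "certain rules" explicit. The latent-variable
count is chosen by leave-one-out accuracy on the calibration set, ties
broken toward fewer components. With all components, SIMPLS reproduces
least-squares regression onto the dummies to $10^{-8}$ — the test suite
holds it to that.

**SVM.** One-vs-one C-support-vector machines with an RBF kernel
$\exp(-g\lVert x-x'\rVert^2)$, solved by sequential minimal optimization
(first-order working-set selection, the standard dual algorithm) in
compiled code. Both $C$ and $g$ are searched exhaustively over integer
powers of ten spanning $10^{-8}$–$10^{8}$ (a 17 × 17 grid — the stated
range with no step implies decade steps), scored by stratified five-fold
cross-validation; ties resolve to the smallest $C$, then the smallest
$g$. The published optimum "(100, 108)" for the effective-wavelength
model is read as $(10^2, 10^8)$, almost certainly a typesetting loss.

**1-D CNN.** Two Conv1D blocks (64 then 32 kernels, size 3, stride 1, no
padding, each followed by ReLU, max-pooling of size/stride 2, and batch
normalization), then dense layers of 512, 128 and 3 units with softmax.
The no-padding arithmetic gives flattened widths 1536 (200 inputs) and
128 (22 inputs), which the tests assert. Training minimizes softmax
cross-entropy by mini-batch SGD, learning rate 0.0005, batch size 400,
400 epochs by default. Unstated details were fixed as follows:

* classical momentum 0.9 (the default of the deep-learning frameworks of
  the study's era; plain SGD at this learning rate cannot traverse the
  loss surface in the stated epoch budget);
* He-uniform weight initialization under the stated seed;
* per-band z-scoring of inputs with calibration statistics (batch
  normalization alone converges poorly on raw reflectance scales);
* the returned model is the epoch-best on the independent validation
  set: highest validation accuracy, ties broken by lower validation
  cross-entropy. The tie-break matters at desk scale, where a small
  validation set saturates at 100% accuracy within a few epochs and an
  accuracy-only argmax would freeze an immature checkpoint.

At desk scale the pipeline also scales the batch to a quarter of the
calibration set — the same batch-to-calibration ratio as the full-scale
setting (400 of ~1600) — and trains 100 epochs. The entire network
(forward, backward through conv, pooling and batch-norm, SGD) is
implemented in base R matrix operations and verified against numerical
gradients in the test suite.

## Evaluation

Samples are split per class into calibration / validation / prediction
at 0.5 / 0.25 / 0.25 — the study's ratios to within rounding (e.g.
539/291/275 of 1105) — by seeded stratified assignment. Confusion
matrices use rows = true origin, columns = predicted, in Gansu, Ningxia,
Xinjiang order, and accuracy is $100\times$ trace over total, kept at
full precision internally and rounded to two decimals only in reports.

## The synthetic world

The generator states one fixed world; its parameters are set from the
acquisition description where stated and from instrument realism where
not, and they are not revisited per experiment:

* **Geometry.** Scenes are 320 px wide (the camera's line width) with
  configurable length; fruits are axis-aligned ellipses with semi-axes
  8–14 px, placed by rejection sampling so they never touch (the
  acquisition protocol places fruits separately). Exceeding the packing
  capacity raises an error naming the limit.
* **Spectra.** All origins share a smooth seeded baseline (typical
  dried-fruit NIR reflectance, ~0.3–0.6) and 22 Gaussian absorption
  features at the candidate wavelength list. A seeded subset of centers
  carries origin-specific depth modulation: each such center modulates
  the three origins by a distinct permutation of $(-0.35, 0, +0.35)$
  relative depth. Permutations are cycled so the three class-mean curves
  are never collinear — three separable clusters, as the real data's PCA
  shows, not classes on a line (collinear means would break any
  regression-on-dummies classifier through the masking effect, a
  degeneracy the real data demonstrably lacked). Contrast centers are
  restricted to wavelengths at least 25 nm from every other feature and
  inside 1000–1620 nm; a contrast planted 13 nm from another feature or
  inside the derivative's edge-extrapolation margin is not localizable
  to ±1 band by any smoothed-derivative method, so without this rule the
  recovery tests would measure the world's identifiability, not the
  selector.
* **Noise.** Additive Gaussian pixel noise, sd 0.02 reflectance units (a
  typical InGaAs line-scan SNR; the study does not report one), a
  per-scan-line multiplicative illumination gain with sd 0.02 (push-broom
  striping), per-fruit relative depth jitter of sd 0.10 (biological
  fruit-to-fruit variation), dark level 120 and white level 3900 digital
  numbers stored as floating point (no camera bit depth is stated).
* **Ground truth.** A label image (fruit ids 1..n) plus per-fruit
  origins; with all stochastic terms set to zero, correcting the rendered
  raw cube recovers each origin signature exactly at every fruit pixel,
  which the tests assert to round-off.

What a green test on this world does establish: the pipeline's
bookkeeping, the correction/segmentation/preprocessing chain, the
selector's ability to localize genuine class contrasts, and that all
three classifiers separate distinct-but-overlapping classes at the
stated noise. What it does not establish: performance on real fruits —
real spectra have chemistry-driven covariance between bands, specular
and shading effects, shape irregularity and touching fruits, none of
which are modelled, and the published real-data accuracies are not
reproducible without the (undeposited) images.

## Numerical choices and degenerate inputs

* Reflectance correction guards $(I_w - I_d) \le 10^{-9}$ explicitly.
* The periodized wavelet transform requires the length to be even and
  at least 12 at every level; 200 → 100 → 50 satisfies this, and other
  lengths fail loudly.
* Area normalization rejects zero-sum spectra.
* Otsu thresholding rejects constant images.
* PLS-DA refuses more latent variables than the data rank and names the
  rank; PCA reduces an over-large component request with a warning.
* SVM grid ties resolve to smallest $C$ then smallest $g$; one-vs-one
  vote ties resolve to the smallest class code; pooling ties in the CNN
  take the first element.
* All stochastic stages (placement, noise, splits, fold assignment, CNN
  initialization and shuffling) derive their streams from one seed;
  fixed seed means bit-identical output, which determinism tests
  enforce.

## Known limitations

* The published preprocessing leaves the wavelet thresholding rule,
  boundary handling, binarization threshold and morphological cleanup
  unreported; the defaults here are explicit, documented stand-ins, and
  real-data results may differ for these reasons.
* The CNN is CPU-only by design; at full study scale (3272 fruits, 400
  epochs) training takes correspondingly longer.
* One published number is internally inconsistent: the
  effective-wavelength PLS-DA calibration confusion block sums to
  1619/1622 correct (99.82%), while its printed Total is 99.92%. The
  package reproduces the other seventeen printed Totals exactly at two
  decimals; the corresponding acceptance assertion is left failing on
  purpose rather than adjusted to the inconsistent value.
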