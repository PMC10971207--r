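---
title: "Label-free multimodal segmentation of oral epithelial dysplasia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free multimodal segmentation of oral epithelial dysplasia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Histopathological grading of oral potentially malignant disorders rests on
H&E staining and visual interpretation, which is slow, multi-step and
subject to inter-observer variability. A label-free alternative is to image
unstained sections with discrete-frequency infrared (DFIR) microscopy — a
quantum-cascade-laser source tuned to a handful of fingerprint-region
vibrational bands — paired with darkfield visible microscopy, which renders
the morphology of unstained tissue through scattered light. The chemical
contrast of the IR bands and the fine spatial texture of darkfield are
complementary: IR pixels are diffraction-limited at ~2 µm while darkfield
resolves sub-micron nuclear detail.

`dfirseg` implements the full analysis chain for this kind of data: three
single-band IR absorbance images (1238 cm⁻¹, Amide III/phosphate; 1546 cm⁻¹,
Amide II; 1658 cm⁻¹, Amide I) plus one darkfield image are fused on a common
1 µm grid and segmented per pixel into **non-epithelium** (connective
tissue, class 1), **dysplastic epithelium** (class 2) and **non-dysplastic
epithelium** (class 3) by a fully convolutional network. Because the
biopsy images such models are built on are not publicly distributable, the
package ships a synthetic tissue-phantom generator that reproduces the
relevant statistical structure of the real data, so that every stage — and
the claims made about it — can be exercised and tested at desk scale.

## Band-ratio normalization

Absorbance at band $b$ scales with both composition and the local optical
path: $A_b(x) \approx t(x)\,\mu_{c(x),b}$, where $t$ is a smooth
thickness/density field and $\mu_{c,b}$ the class-conditional absorptivity.
Dividing the two fingerprint bands by the Amide I band,

$$r_{1238} = \frac{A_{1238}}{A_{1658}}, \qquad
  r_{1546} = \frac{A_{1546}}{A_{1658}},$$

cancels $t(x)$ exactly, leaving two chemistry-only channels. The package
applies this per pixel (the plain reading of "normalized to the 1658 cm⁻¹
image"; a regression-based normalization would reintroduce a global fit we
see no need for). Two numerical guards matter:

* pixels with $A_{1658} < 10^{-3}$ AU are removed from the tissue mask
  before division — at near-zero Amide I the ratio amplifies detector noise
  without bounds;
* ratios are clipped to $[0, 3]$ inside the mask (class medians sit well
  below 1.5, so the clip only bounds outlier leverage) and set to exactly 0
  outside it.

Tissue is separated from background by Otsu's threshold on the Amide I
image — the strongest and most spatially uniform tissue band — with enclosed
holes below 64 px² filled. Rigid alignment between modalities uses
integer-pixel cross-correlation of mean-subtracted images via FFT; sub-pixel
refinement is deliberately out of scope, as the shared-grid resampling is
the dominant spatial uncertainty at 1 µm.

Resampling conventions (these determine all the index arithmetic): grids are
pixel-centered, row-major, 0-based in the C++ core; resampling preserves the
physical extent, intensity rasters are interpolated bilinearly and
label/mask rasters by nearest neighbor, so resampling can never invent a
label value.

## The tissue phantom

The generator emulates four properties of the real sections:

1. **Class-conditional ratio structure.** Per-class medians of $r_{1238}$
   and $r_{1546}$ follow the orderings observed in tissue: non-epithelium
   above both epithelium classes in both bands (collagen-rich stroma);
   dysplastic above non-dysplastic epithelium at 1238 cm⁻¹ (increased
   nuclear/DNA content); and a wider 1546 cm⁻¹ spread for non-dysplastic
   than dysplastic epithelium, with non-epithelium the widest in both bands
   (it aggregates many tissue subtypes). Published box plots for these
   distributions carry no absolute scale, so the default medians
   (0.78/0.60/0.45 at 1238; 0.95/0.62/0.60 at 1546) encode the orderings
   and plausible separations, not measured levels.
2. **A multiplicative thickness field.** $A_b = t \cdot \mu_{c,b}
   (1+\varepsilon_b)$ with $t$ lognormal and smooth (Gaussian random field
   passed through `exp`, correlation length 100 µm, CoV 0.15 by default).
   The ratio channels must cancel $t$ exactly; this is a tested invariant.
   The per-class spread enters as the multiplicative band noise
   $\varepsilon_b$ (sd = `sigma_ratio_*`, zero for Amide I so the ratio
   medians stay on target); setting `noise_sd` and all `sigma_ratio_*` to
   zero defines the *noise-free* phantom used by the invariance tests.
3. **Epithelial geometry.** A full-width tissue band covers
   `tissue_fraction` of the frame; its upper portion is epithelium whose
   lower boundary undulates as a sinusoid with random phase plus
   low-frequency jitter — the simplest shape that produces rete-peg-like
   protrusions, the boundary feature where segmentation errors concentrate
   in practice. One contiguous column range of the epithelium is dysplastic,
   mimicking the contiguity of a real lesion focus rather than scattered
   dysplastic islands.
4. **Darkfield morphology.** Rendered at 0.5 µm/px (finer than the IR, so
   the down-sampling path is always exercised): per-class base intensity
   plus Poisson-distributed nuclear speckle blurred to a ~0.75 µm point
   spread, with dysplastic epithelium twice as speckle-dense as
   non-dysplastic (0.012 vs 0.006 nuclei/µm²) and the two base intensities
   nearly equal (0.35 vs 0.33). This makes darkfield good at
   epithelium-vs-stroma but deliberately weak at the dysplastic/
   non-dysplastic distinction, which is carried by the IR chemistry — the
   regime in which the modality ablation is interpretable.

Measurement is simulated by sampling the underlying 1 µm field at 2 µm pixel
centers for the IR bands (nearest-point sampling, not area averaging — a
simplification that keeps noise-free bands exactly piecewise constant per
class) and adding detector noise at the measurement grid. Defaults:
1024 × 1024 µm frames (real sections are mm-scale; this is the desk-scale
compromise), `tissue_fraction` 0.70, epithelium depth 0.30 of the frame,
peg amplitude 20 px / period 150 px, dysplastic focus 0.40 of the width,
noise sd 0.01 AU.

What the phantom does **not** emulate: Mie scattering and dispersion
artifacts of transflection optics, baseline drift, stain-like appearance,
nuclear-scale IR structure, or inter-patient variability. Passing tests on
phantoms therefore demonstrates the correctness and internal consistency of
the pipeline — normalization invariances, data handling, optimization,
metric arithmetic — not clinical performance on real biopsies.

## Patch dataset and splits

Training uses non-overlapping patches tiled from the top-left corner in
row-major order; edge tiles smaller than the patch size are discarded
(padding would dilute the "non-overlapping" design), and a tile is retained
only if at least 50% of its pixels are tissue. "Tissue" here means the
tissue *mask*, not the annotation: the mask is what exists before a
pathologist annotates anything, which is the quantity available in
deployment. At acquisition scale patches are 256 px; the test suite and the
bundled runs use 128 px on 1024 µm frames to keep single-CPU times in
minutes.

Splitting is by whole section — no section contributes patches to two
splits — with counts honored exactly and a seeded, reproducible assignment.
The acquisition-scale design used the same 3 held-out sections for both
validation and blind testing out of 23; the package defaults to a genuine
3-way train/val/test split so that early stopping never sees the test
sections, and the 2-way design remains available by setting `val = 0`.

## Network and training protocol

The model is a fully convolutional network over a residual backbone with a
1×1 classification head and bilinear up-sampling back to the input grid.
Two backbones are provided:

* `resnet50` — the acquisition-scale architecture: 7×7/2 stem, 3×3/2 max
  pooling, bottleneck stages of 3/4/6/3 blocks at standard widths, output
  stride 32 (~25M parameters). Weights are randomly initialized by default
  (Kaiming-normal); no pretraining is assumed.
* `reduced` — a stride-2 stem (8 channels) followed by two basic residual
  blocks (16 channels, output stride 4) and the same head. At the phantom's
  near-piecewise-constant chemistry the task is close to pixel-wise
  separable, so this ~6k-parameter network reaches the same accuracy as far
  larger ones while training in tens of seconds on one CPU; it is the
  backbone used throughout the tests.

The engine (C++, single precision, im2col + BLAS GEMM) implements the
training protocol exactly as specified by the study design: Adam
(β₁ = 0.9, β₂ = 0.999, bias-corrected) with learning rate 2·10⁻⁴ and L2
weight decay 10⁻⁵ folded into the gradient; cross-entropy over the three
tissue classes with background (label 0) carrying zero weight — scores at
background pixels can be anything without changing the loss, a tested
invariant; a stepped schedule lr(e) = 2·10⁻⁴ · 0.5^⌊e/5⌋; early stopping on
validation loss with patience 10 and min-delta 10⁻⁴ (the study states only
that early stopping was used; these are our operating values), retaining
the best-validation weights; and random affine augmentation of every patch
in every iteration — rotation ±30°, translation ±10%, scale 0.9–1.1, shear
±5° (unreported at acquisition scale; declared defaults here) — with
bilinear channel interpolation, nearest-neighbor labels under the identical
transform, and out-of-frame regions filled with ignored background.
Channels are standardized per channel with mean/sd pooled over the masked
pixels of the *training* sections only; the stored statistics are reused
verbatim at validation, test and inference time.

Replication: `n_replicates` independent trainings (default 3) run on the
identical dataset, replicate $r$ seeded with `seed + r` for initialization,
shuffling and augmentation. The entire loop is single-threaded C++ with its
own Mersenne-Twister stream, so a fixed seed reproduces a training history
bit for bit on the same BLAS.

Whole-section inference tiles the stack (default tile 256, overlap 32),
averages softmax scores where tiles overlap, takes the per-pixel argmax
(first-class tie-break), and forces pixels outside the tissue mask to
background — the mask always wins over the network.

## Evaluation

All metrics exclude background pixels and evaluate only mask-covered pixels
whose true label is a tissue class. The confusion matrix is reported as
counts and as row-normalized percentages (each true-class row sums to 100;
an empty row is flagged rather than divided). Overall accuracy is
100·trace/total. F1 is macro-averaged over the three classes — the
averaging used for the study's single reported F1 is unstated, and macro is
the choice that penalizes failure on the minority dysplastic class, which
is the clinically important one; a class absent from the truth is excluded
from the macro mean and flagged. Replicate aggregation reports the mean and
the population standard deviation (divisor *n*), matching how a mean ± SD
over a small fixed set of replicate runs is conventionally quoted.

The modality ablation trains the same splits and seeds under three channel
configurations — darkfield only (1 channel), IR ratios only (2), combined
(3) — and compares them on the held-out sections. On phantoms built as
described above, the designed outcome (verified in the acceptance tests) is
that IR-only dominates darkfield-only on dysplastic recall, and the
combined model is at worst within one percentage point of the best single
modality.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use sizes chosen so a full run
fits in minutes on one CPU: 12 sections of 1024 × 1024 µm (test suite) or
8 of 512 × 512 µm (acceptance script), 128 px patches, the reduced
backbone, 3 replicates per modality and an 8-epoch budget — the validation
loss plateaus by epoch 4–6 on these phantoms. Where one training epoch
equals one optimizer step (single-patch memorization checks), the LR
schedule is held at its first step so that "200 steps" means 200 steps at
the nominal rate.

Other numerical details: batchnorm uses ε = 10⁻⁵ and momentum 0.1 running
statistics (batch statistics in training mode, running at inference);
softmax is max-shifted; probabilities are floored at 10⁻¹² inside the log;
float32 TIFF storage scales each raster into [0, 1] with the factor kept in
a JSON sidecar, so round-trips are exact to float32 precision (~10⁻⁷
relative) rather than bit-exact in doubles; Otsu operates on the image
rescaled to its own range.

## Limitations

Phantom realism is the binding one: results here validate the machinery,
not clinical claims. The concatenation fusion of IR and darkfield is the
simplest possible and known to be suboptimal; architecture work is out of
scope. The registration model is integer-translation only. Training
determinism holds for a fixed BLAS; exact histories can differ across BLAS
builds even with identical seeds, though the evaluation statistics are
stable to well within their replicate SDs.
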