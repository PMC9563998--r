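---
title: "Methods: involution U-Net for wheat lodging segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: involution U-Net for wheat lodging segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model and the design
choices behind it: what is computed, under which assumptions, which
parameters matter, and what the synthetic test bed does and does not
demonstrate.

## The segmentation problem

Lodged wheat — stems pushed permanently off vertical by wind, rain or
over-fertilization — appears in low-altitude aerial RGB imagery as
brighter, smoother patches inside a darker, textured canopy. The task is
binary semantic segmentation: for every pixel of an orthomosaic, decide
lodged (1) or standing (0). Two properties dominate the design:

* **class imbalance** — lodged area is usually a small fraction of the
  field, so an unweighted loss lets the network win by predicting
  "standing" everywhere;
* **scale** — orthomosaics are far larger than any network input, so
  training and inference both run on tiles that must be cut and stitched
  without seams.

## Network architecture

`network_config()` describes an encoder–decoder with `depth` pooling
levels and level widths `base_channels * 2^(l-1)`. Each encoder level
applies, in order:

1. a 3×3 convolution + batch normalization + ReLU;
2. an **involution layer** (+BN+ReLU);
3. a **dense block**;
4. 2×2/stride-2 max pooling whose argmax locations are recorded.

The decoder mirrors the levels: a 1×1 projection to the level's encoder
width, **index-preserving unpooling** (retained values land exactly at
their recorded argmax cells, zeros elsewhere), concatenation with the
level's skip feature, then two 3×3 conv+BN+ReLU stages. A 1×1 convolution
with one output map and a sigmoid yields per-pixel probabilities in
(0, 1). Setting `use_involution = FALSE, use_dense = FALSE`
(`unet_config()`) replaces stages 2–3 with a second 3×3 convolution and
gives the plain U-Net baseline used in comparisons.

### The involution operator

Where convolution shares one kernel over all positions, involution
generates a fresh K×K kernel at each pixel from that pixel's feature
vector and shares it across a channel group:

$$Y_{i,j,k} = \sum_{(u,v) \in \Delta_K} \mathcal{H}_{i,j,u,v,g(k)}\; X_{i+u,j+v,k},
\qquad \mathcal{H}_{i,j} = W_1\,\sigma(W_0\,X_{i,j})$$

with $W_0 \in \mathbb{R}^{C/r \times C}$, $W_1 \in
\mathbb{R}^{KKG \times C/r}$ and $\sigma$ = batch normalization followed
by ReLU. Channel $k$ (0-based) belongs to group $\lfloor kG/C \rfloor$:
consecutive blocks of $C/G$ channels share one kernel, so 32 channels
with 16 channels per kernel form 2 groups. This 0-based floor convention
is the same map as a 1-based ceiling and is pinned by a unit test.

The operator's hyperparameters are not dictated by the architecture, so
the package exposes them with defaults K = 7 (a large receptive field is
the operator's point), G = 1 (all channels of a pixel share one kernel,
the simplest sharing pattern), r = 4 (the customary bottleneck ratio),
stride 1. Strided involution is implemented (kernels generated on, and
output sampled at, the strided grid) but unused by the assembly, which
downsamples by pooling only.

Padding is zero padding of ⌊K/2⌋ everywhere, for involutions and 3×3
convolutions alike. Valid (shrinking) convolutions were considered and
rejected: the decoder's unpooling doubles sizes exactly and the skip
concatenation requires equal spatial dims, an arithmetic that only closes
when every stage preserves size. Tile sides must be divisible by
2^depth for the same reason, and the forward pass refuses inputs that are
not.

### Dense blocks

Layer $t$ of a block consumes the channel-concatenation of the block
input and layers $1..t-1$; the block output concatenates all of them, so
channels grow from $C$ to $C + L\,g$ ($L$ layers of growth $g$, default
$g = C/4$, $L = 2$). The full cross-linking is verified by a perturbation
probe: forcing layer 1's output to zero must change layers 2 and 3.

### What is deliberately not configurable

One involution layer and one dense block per encoder level, always
between the conv stage and the pooling. How many backbone convolutions to
replace with involutions is genuinely open in this architecture family;
one per level keeps the parameter count strictly below the convolution it
replaces (asserted by a parameter-count audit in the tests) while giving
every level spatial specificity.

## Loss and metrics

The Tversky loss over soft counts (sums of predicted probabilities over
positive/negative label pixels):

$$TL = 1 - \frac{TP + \epsilon}{TP + \alpha FN + \beta FP + \epsilon},
\qquad \alpha = 1 - \beta$$

Defaults $\alpha = 0.7$, $\beta = 0.3$, $\epsilon = 10^{-6}$: the common
imbalance-penalizing choice, weighting missed lodged pixels over false
alarms. The values are configurable because no single pair suits every
lodged-area fraction; $\alpha = \beta = 0.5$ recovers $1 - \text{Dice}$
exactly (a tested identity). The loss is computed per batch over all
pixels jointly rather than per image — soft counts from a whole batch are
stabler when individual tiles contain little or no lodging.

Evaluation metrics are Precision, Dice, Recall, Accuracy from hard
counts. A ratio with zero denominator scores 1 when the total error
count FP + FN is also zero (two empty masks agree vacuously) and 0
otherwise; this keeps "no lodging predicted, none present" a perfect
score without rewarding empty predictions on lodged fields.

## Data pipeline

* **Tiling**: row-major sliding window, default 256×256 with stride =
  tile (non-overlapping) for training data; overlapping strides are
  supported for inference, where stitching averages per-pixel scores
  before thresholding. Coordinates are 0-based (row, col) offsets with
  half-open extents; `tile -> stitch` on the non-overlapping stride is an
  exact round trip (tested on random sizes).
* **Augmentation**: rotations restricted to 90/180/270 degrees (arbitrary
  angles would change the tile footprint), flips, a small box blur
  (width 3) standing in for "filtering", and clipped additive Gaussian
  noise. Geometric ops are applied identically to image and mask;
  photometric ops never touch the mask — an invariant every pipeline
  stage preserves, because masks must remain exactly {0, 1}.
* **Splitting**: seeded uniform sampling without replacement;
  15,000 tiles at fraction 0.8 give exactly 12,000/3,000.
* **Altitude simulation**: ground-sample distance is proportional to
  flight altitude for a fixed camera, so 20 m imagery becomes simulated
  80 m / 120 m imagery by cubic-convolution (Keys, a = −0.5) downscaling
  with linear factors 1/4 and 1/6. Masks are never resampled with cubic
  kernels — nearest neighbor only. PSNR = 10·log10(255²/MSE) quantifies
  the information loss; when the degraded image is smaller it is first
  re-expanded bicubically to the reference grid (a documented convention;
  PSNR needs equal shapes).

## Synthetic scenes: what they do and do not show

`make_scene()` emulates the visual contrast the method exploits: a
band-limited noise canopy texture around irregular patches (thresholded
smoothed random bumps) that are ~22% brighter with most high-frequency
energy removed, plus Gaussian sensor noise (sd 6 on the 0..255 scale),
8-bit quantized. Patch geometry is drawn before any photometric sampling,
so the ground-truth mask depends only on geometry parameters and the
seed. The realized lodged fraction is held within ±20% (relative) of the
request by quantile thresholding with bounded retries.

Passing tests on these scenes demonstrates that the implementation
learns, that gradients flow everywhere, and that the pipeline is exact —
it does **not** demonstrate field-level accuracy. Real orthomosaics add
shadows, bare soil, weeds, growth-stage variation, stitching artifacts
and label noise that the generator deliberately omits; the accuracy of a
model on real lodging data must be established on real data.

## Numerical choices

* Batch normalization: biased variance, eps 1e-5, momentum 0.1 running
  averages; batch statistics in training, running averages in inference
  (inference is therefore deterministic).
* Initialization: fan-in-scaled uniform draws (±sqrt(6/fan_in)), zero
  biases, unit BN scales; all draws flow from `network_config(seed)` in a
  fixed creation order, so identical configs give identical models.
* Pooling ties: first scanned position wins, scan order (0,0), (1,0),
  (0,1), (1,1) within each window — fixed so round trips are bit-exact.
* Optimizer: Adam (β₁ 0.9, β₂ 0.999, eps 1e-8), defaults lr 0.001, batch
  10, epochs 100, matching the protocol this architecture family is
  trained with at full scale. The best-validation-loss epoch is
  checkpointed rather than the last — a guard against late-epoch
  overfitting that costs nothing; the held-out split doubles as the
  validation set for curve logging.
* Gradients: a small reverse-mode tape over dense arrays, with each
  operator's vector-Jacobian product hand-written and verified against
  central finite differences at smooth evaluation points (ReLU, max
  pooling and argmax selection make the loss piecewise smooth; finite
  differences are only meaningful away from the kinks).

## Problem sizes used by the verification suite

The package's automated checks run at desk scale, chosen once as the
smallest sizes that still exercise every code path meaningfully: operator
oracles on feature maps up to 8×8×8; smoke training on 200 synthetic
64×64 scenes with a depth-2, base-width-8 network, batch 10, Adam lr
0.001, 8 epochs, Tversky α 0.7 — enough for held-out Dice well above 0.85
on the synthetic contrast, in minutes on one CPU. The full-scale
configuration (depth 4, base width 64, 256×256 tiles, 100 epochs) is the
package default for real use.

## Known limitations

* CPU only; throughput is adequate for the desk-scale verification and
  small studies, not for training on tens of thousands of 256×256 tiles.
* GeoTIFF georeferencing tags are not propagated through prediction
  (no GDAL binding is used); outputs are plain rasters aligned
  pixel-for-pixel with their inputs.
* Binary head only (lodged / standing); no multi-class severity grading.
* Batch normalization uses true batch statistics, so training-mode
  forward passes depend on batch composition; inference mode does not.
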