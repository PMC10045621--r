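---
title: "Shear-transform deformable segmentation: methods and design notes"
author: "shearseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear-transform deformable segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by **shearseg**, the choices
that were genuinely open when building it, and what the synthetic phantom
benchmark does and does not demonstrate.

## The composite convolution block

The unit of the network is a convolution block consisting of two
convolution units, each followed by a ReLU. In the full variant each unit
computes

1. a **shear warp** of the incoming feature map,
2. a **deformable 3×3 convolution** on the warped map, and
3. the **inverse shear warp** back to the original frame.

The shear maps coordinates by `(x, y) -> (x + s*y, y)` for a horizontal
shear with factor `s` (vertical: `(x, y) -> (x, y + s*x)`); its inverse
negates `s`, and the matrix product of the two is exactly the identity.
The deformable convolution displaces each of the nine kernel taps by a
2-D offset that is predicted per output position from the same input by a
zero-initialized 3×3 convolution; displaced samples are evaluated by
4-neighbour bilinear interpolation with zero padding. Offsets are shared
across input channels (one `(dx, dy)` pair per tap per position), the
standard parameter-economical design for deformable convolutions. Each
convolution unit owns its own offset predictor.

The intent of the composition is geometric: speckle-laden ultrasound
boundaries are oblique, irregular and blurred; the shear re-orients
oblique structure so that the (deformable) kernel sees it in a canonical
frame, and the learned offsets let the sampling pattern follow local
boundary deformation. At shear factor 0 and zero offsets the block is
bitwise a plain double-convolution U-Net block — this reduction is tested
explicitly and is also why training is stable: the network *starts* as a
U-Net and departs from it only as the offset predictors learn.

## The network

The encoder has `depth` stages (default 4) of block + 2×2 max-pool with
channel widths doubling from `base_width` (default 64; the tests and the
phantom benchmark use 16); the decoder mirrors it with 2×2
transposed-convolution upsampling and skip concatenation, so the stage
counts and per-stage widths of encoder and decoder match exactly. The head
is a 1×1 convolution to 2 channels with a per-pixel softmax, trained with
per-pixel cross entropy, which for two classes equals binary cross
entropy; a 1-channel sigmoid head is available as an option. Same padding
is used everywhere so skip features concatenate without cropping.

The model `variant` maps every block of the network uniformly, giving the
ablation ladder `unet` (plain blocks), `st_unet` (shear only), `du_net`
(deformable only), `dsu_net` (both).

Choices that the block description leaves open, and what this package
does:

* **Shear factor schedule.** A single fixed horizontal shear of factor
  0.3 is used for every block (overridable via the configuration). Both
  0.3 and 0.6 are sensible lateral factors; 0.3 is the gentler default
  and nothing in our experiments favoured a per-layer schedule.
* **Batch normalization** is not implemented. Input images are
  per-channel normalized, the networks trained here are small, and an
  untested optional code path is worse than none.
* **Upsampling** is by learned 2×2 stride-2 transposed convolution rather
  than fixed interpolation, matching the deconvolution-based decoders of
  the U-Net family.
* **Offset sharing.** One predictor per convolution unit (not one per
  block): the two units of a block see different feature distributions.

## Numerical choices

* **Coordinates** are 0-based with `x` = column, `y` = row, origin at the
  top-left pixel centre. Feature maps are `H x W x C` arrays.
* **Resampling is backward**: every output pixel pulls from its
  inverse-mapped source location, which cannot leave holes. For a shear,
  the source offset `s*y` is constant along a row, so the bilinear warp
  is a two-tap blend per row and the nearest-neighbour warp is an integer
  per-row shift.
* **Nearest-neighbour tie-break.** The per-row shift is
  round-half-away-from-zero of the combined offset. Round-half-up would
  break the exact shear/inverse-shear identity whenever `s*y` lands on a
  half-integer (e.g. factor 0.3, row 5): half-away-from-zero is
  odd-symmetric, so forward and inverse shifts cancel exactly. With a
  lossless canvas this makes the nearest round trip bitwise exact and
  pixel-sum conserving, which the tests assert.
* **Lossless canvas.** Inside the network the sheared axis is widened by
  `ceil(|s| * (extent - 1))` so no border features are discarded; the
  inverse warp crops back. Bilinear interpolation is the network default
  (piecewise-linear, differentiable); nearest is reserved for exact
  geometry.
* **Zero padding** everywhere (convolutions, out-of-bounds bilinear
  samples, out-of-source shear samples), stride 1, dilation 1.
* **Gradients** of every kernel — including the offset gradient of the
  bilinear sampler, which is its piecewise-linear subgradient at integer
  sampling points — are analytic and are checked against central finite
  differences (relative error below 1e-3 on random small instances).
* **Binarization**: softmax head by per-pixel argmax with ties to
  background; sigmoid head by threshold 0.5, exact 0.5 to background.
* **Metrics** are averaged per image, unweighted, the convention of
  segmentation comparison tables; two empty masks score 1 (vacuous
  agreement avoids 0/0). For hard masks `jaccard = dice / (2 - dice)` to
  1e-12, which is tested.
* **Optimization**: Adam with learning rate 0.001, betas (0.9, 0.999),
  epsilon 1e-8, batch size 8 — the study's settings; betas and epsilon
  are the optimizer's standard defaults. Gradients are averaged over the
  batch. The best-validation-Dice checkpoint is retained (ties keep the
  earliest epoch). All randomness flows through R's RNG from the
  configured seeds, so runs are bitwise reproducible.

## The phantom generator

Real TRUS volumes of the kind this architecture targets are clinical data
and not redistributable, so the package ships a generator of
*ultrasound-like phantoms* that reproduces the properties the block is
designed to exploit, with exact ground truth:

* an **asymmetric, irregular contour**: a star-convex radius
  `r(theta) = r0 * (1 + sum_j a_j sin(j*theta + phi_j))`, harmonics
  `j = 2..5` by default, around a randomized interior centre;
* a **blurred boundary**: Gaussian blur of the two-level rendering
  (default sigma 1.2 px);
* **speckle**: unit-mean multiplicative gamma noise (default SD 0.25),
  the standard first-order model of ultrasound speckle;
* **intensity inhomogeneity**: a smooth multiplicative field (default
  amplitude 0.3) upsampled from coarse Gaussian noise;
* organ/background mean levels drawn from [0.55, 0.75] / [0.15, 0.30],
  area fraction constrained to [0.08, 0.35] of the frame.

The mask is the exact rasterized contour — a single 4-connected
component, which a labeling sweep over generated phantoms verifies.

What the phantoms do **not** emulate: directional speckle correlation and
attenuation shadows, acoustic artifacts (reverberation, refraction),
neighbouring anatomy that mimics organ texture, probe-dependent field
inhomogeneity, and annotation noise. Passing the benchmark therefore
demonstrates that the implementation trains and segments correctly — not
that the architecture's clinical advantage transfers; on these compact
bright-on-dark phantoms even a plain U-Net scores high, and the ablation
ordering is reported rather than asserted.

## Benchmark and test problem sizes

The package's own benchmark protocol (chosen once, stated here as the
package's choice): 64×64 phantoms; model base width 16, depth 4; Adam as
above. The trainability check trains `dsu_net` on 48 phantoms (16
validation) for 6 epochs and requires mean Dice ≥ 0.85 on 24 fresh
phantoms for each of 3 seeds. The ablation comparison trains `dsu_net`
and `unet` pairwise on 5 seeds (24 training phantoms, 3 epochs) and
reports the median held-out Dice of both. `scripts/acceptance.R` runs a
single larger instance (64/16/32 phantoms, 6 epochs, both variants) and
writes the held-out Dice/Jaccard to JSON. A typical seed gives `dsu_net`
Dice ≈ 0.95 vs `unet` ≈ 0.92 — consistent in direction with the
architecture's motivation, with the domain-gap caveat above.

## Known limitations

* CPU only; the layers are hand-written RcppArmadillo kernels with
  analytic backprop, not bindings to a deep-learning framework. Training
  at clinical resolution (hundreds of 581×477 images, 80 epochs) is out
  of reach at desk scale; the package targets correctness and the scaled
  benchmark.
* Modulated (v2) deformable convolution, deformable RoI pooling,
  learning-rate schedules and early stopping beyond best-checkpoint
  retention are out of scope.
* The generator draws one organ per image; multi-structure scenes and
  image-free (unpaired) training are not supported.
* `augmentation_config` translation/crop magnitudes are declared
  defaults, not fitted to any dataset.
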