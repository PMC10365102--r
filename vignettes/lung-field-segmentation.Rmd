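---
title: "Lung-field segmentation with a residual CNN-transformer network"
author: "lungfields package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung-field segmentation with a residual CNN-transformer network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungfields)
```

# The problem

Automated delineation of the lung fields in frontal chest radiographs is a
prerequisite for downstream quantitative work (cardiothoracic ratios,
opacity scoring, registration). Pediatric radiographs are harder than adult
ones: thymic shadow, variable inspiration, and — in any multi-machine
archive — wildly inconsistent pixel-value ranges, because each acquisition
station applies its own gain and offset. Two error modes dominate naive
segmentations: non-lung regions whose gray level resembles the lungs are
picked up as false components, and small lung sections (often under rib
shadows) are missed, leaving holes.

This package implements a complete pipeline for that problem:
intensity harmonization, a hybrid CNN-transformer segmentation network
(TransResUNet), a standard training protocol, morphological mask clean-up,
and evaluation — together with a seeded synthetic phantom generator that
stands in for clinical data, which cannot be redistributed.

# Grayscale truncation

For an $x \times y$ image with intensities $V_{i,j}$, the central quarter
window $A_c = \{P_{i,j} \mid i \in [x/4, 3x/4), j \in [y/4, 3y/4)\}$ is
assumed to contain lung-relevant tissue and no collimation borders or
burnt-out background. With $V_{\min}, V_{\max}$ the extremes of $A_c$,
every pixel of the full image is clipped:

$$V_{i,j} \leftarrow \begin{cases}
V_{\min} & V_{i,j} \le V_{\min}\\
V_{i,j} & V_{\min} < V_{i,j} < V_{\max}\\
V_{\max} & V_{i,j} \ge V_{\max}
\end{cases}$$

then mapped affinely onto $[0,1]$ and resized (bilinear) to the model side
$S$. The payoff is exact invariance under positive affine intensity maps
$aI+b$ ($a>0$): radiographs of the same patient digitized by different
machines preprocess to the same array. `preprocessImage()` implements the
composition; the invariance is tested on random images.

Numerical decisions here, all of which the windowing idea leaves open:

* **Odd dimensions.** The quarter window uses floor-based half-open index
  ranges, so it is defined (and non-empty) for any image at least
  $4 \times 4$.
* **Degenerate window** ($V_{\min}=V_{\max}$): the output is all zeros
  rather than an error, so batch pipelines survive blank frames.
* **Resizing.** Bilinear for images, nearest-neighbor for masks (preserving
  binarity), both under the pixel-center convention, implemented in the
  package so the convention is under test control. Non-square images are
  resized anisotropically — no letterboxing — matching the reshape-to-
  $S\times S$ convention of the training protocol.
* **Inverted photometrics** (sources where bone is dark) are flipped
  $v \mapsto \max(v) - v$ before windowing via the `photometric` argument.
  The package reads PNG and TIFF; convert DICOM exports to 16-bit PNG/TIFF
  upstream and pass the photometric flag explicitly.

# The network

`TransResUNet()` builds the segmentation model described by
`ModelConfig()`:

* **Residual encoder.** Three stages of residual block + $2\times$ max
  pooling produce a feature pyramid $F_1, F_2, F_3$ at $S/2, S/4, S/8$ with
  channel widths `channels`. Each residual block is
  $\mathrm{transform}(x) + \mathrm{shortcut}(x)$ with the transform two
  3×3 convolution → batch-norm → ReLU stages, and the shortcut a 1×1
  projection when channel counts change, identity otherwise.
* **Patch/position embedding.** $F_3$ is cut into $p \times p$ patches
  ($p$ = `patchStride`, default 1, i.e. one token per $F_3$ cell),
  flattened row-major, projected linearly to $K$ = `embedDim` dimensions,
  and given a learned additive position embedding.
* **Transformer bottleneck.** $L$ pre-normalization layers, each
  $x \leftarrow x + \mathrm{MSA}(\mathrm{LN}(x))$ then
  $x \leftarrow x + \mathrm{MLP}(\mathrm{LN}(x))$, with $h$ attention
  heads and GELU MLP of width `mlpDim`. The stack's output $F_t$ is
  reshaped back onto the $S/(8p)$ grid. No extra normalization follows the
  stack: the layers normalize their own inputs, the decoder batch-norm
  rescales $F_t$ anyway, and omitting it keeps the useful exact property
  that a zero-weight (or $L=0$) bottleneck is the identity on tokens —
  which the tests exploit.
* **Residual decoder.** $[F_t; F_3]$ → residual block → $2\times$
  upsample → $[\cdot; F_2]$ → block → upsample → $[\cdot; F_1]$ → block →
  upsample to $S$ → pixelwise linear head with two logits; softmax gives
  the lung probability. The text description of the architecture reaches
  $S/2$ after two upsamplings; a third doubling precedes the head because
  a per-pixel prediction at full resolution requires it.

The full-scale configuration ($S=512$, channels 64/128/256, $L=12$,
$K=768$, $h=12$) has on the order of $9\times10^7$ parameters
(`countParams(ModelConfig())`); the desk-scale instance used throughout the
tests ($S=64$, channels 8/16/32, $L=2$, $K=64$, $h=4$) has about
$1.8\times10^5$ and trains in minutes on one CPU.

Unstated-by-construction choices, fixed here as defaults and exposed in
`ModelConfig`: attention heads $h=12$ at full scale with
$\mathrm{mlp}=4K$ (the ViT-B convention), batch-norm + ReLU in the CNN
blocks, layer-norm in the transformer, learned 1-D position tables,
truncated-normal (sd 0.02) initialization for projections, He-normal for
convolutions, and a zero initial scale on each residual branch's closing
batch-norm so every block starts as its shortcut. Training is from
scratch; no pretrained backbone weights ship with the package.

The forward *and* backward passes are written directly on BLAS matrix
operations (im2col convolutions, gather/scatter pooling, explicit
attention derivatives); gradients are verified against central finite
differences in the test suite.

# Training protocol

`TrainConfig()` encodes the protocol: RMSprop (lr 0.001; smoothing
constant 0.99 and $\epsilon=10^{-8}$, the usual framework defaults,
recorded in run manifests), batch size 2, 20 epochs, 70:10:20
train/validation/test split. The split rule is
$n_\mathrm{train} = \lfloor 0.7n \rfloor$,
$n_\mathrm{val} = \lfloor 0.1n + 0.5 \rfloor$, remainder test — the unique
simple rounding that yields the 810/116/232 partition at $n = 1158$. The
loss is per-pixel two-class cross-entropy by default (soft-Dice and a
combined loss are selectable); the returned model is the best-validation-
Dice epoch unless `selection = "last"`. No augmentation, no schedules.
Everything is seeded: the same `TrainConfig` reproduces the training
history bitwise.

# Post-processing

`postprocessMask()` repairs the two dominant error modes: binarize at 0.5,
keep at most two connected components (each at least 10% of the largest —
the two-lung prior, with tolerance for a merged field), fill fully
enclosed holes, and smooth with a morphological opening (disc radius
`openingRadius`). The clean-up stage named "opening" in the field cannot
by itself restore missing lung interior — opening only removes pixels — so
hole filling precedes it; both stages are independently switchable
(`fillHoles`, `openingRadius = 0`). Components are labeled 8-connected by
default (holes with the dual 4-connectivity).

The opening radius is a length in pixels and therefore scales with
resolution: the package's rule is radius 3 at side 512, i.e.
`round(3 * side / 512)` floored at 1, giving radius 1 for the desk-scale
side-64 pipeline.

# Evaluation

With lung as the positive class and per-pixel counts TP/TN/FP/FN:
$AC = (TP+TN)/\mathrm{total}$, $SE = TP/(TP+FN)$, $SP = TN/(TN+FP)$, and
$DI(e,f) = 2|e \cap f| / (|e|+|f|)$. Degenerate denominators yield `NA`,
excluded from aggregates; two empty masks have $DI = 1$ by convention.
None of these conventions are exercised by realistic data — they are
documented so the functions are total.

# The phantom generator

Clinical radiographs from a single children's hospital cannot be shipped,
so `generatePhantom()` synthesizes the statistical structure the pipeline
must survive:

* two dark, rotated lung ellipses inside a brighter thorax ellipse (the
  mask is exactly their union, independent of all intensity choices);
* a brighter mediastinal band between them (heart/thymus/spine);
* thin bright rib stripes crossing the lung fields — so the network must
  label bright pixels *inside* lungs as lung, and raw predictions tend to
  leave rib-shaped holes that the post-processing closes;
* occasional distractor blobs outside the lungs whose intensity sits in
  the lung band — the false-component trap for the component filter;
* additive Gaussian noise (sd 0.03 on the nominal [0,1] scale), then a
  per-image affine "machine" transform with gain in [0.5, 4000] and offset
  in [0, 2000], emulating the inconsistent ranges that motivate grayscale
  truncation.

Nominal intensity levels (background 0.10, lung 0.20, thorax 0.55,
mediastinum 0.75, rib 0.85, distractor 0.22) keep the contrast ordering
lung < thorax < rib of real radiographs while leaving the lung/distractor
gray levels close, as in the motivating failure mode. Phantoms are
rendered at side 128 for the desk-scale pipeline — coarse enough to train
quickly, fine enough that ribs, holes and specks survive resizing to the
model side 64. Generation is fully deterministic in (seed, index).

What the phantoms do **not** model: true rib curvature and posterior/
anterior rib crossings, costophrenic angle shape, scapulae, devices and
annotations, exposure gradients, and anatomical covariance between
neighboring structures. Passing the phantom suite therefore demonstrates
that the pipeline's mechanics are correct and that the architecture can
learn windowed-contrast segmentation end to end — not clinical-grade
performance, which requires real annotated radiographs at side 512 and
longer training.

# Scale of the shipped experiments

The package's tests and the acceptance script run a deliberately small
instance of the full recipe: 60 phantoms (42/6/12 after the 70:10:20
split), model side 64 with channels 8/16/32, $L=2$, $K=64$, $h=4$, trained
exactly per protocol (RMSprop, lr 0.001, batch 2, 20 epochs). These sizes
are the package's chosen desk-scale experiment: large enough for the
held-out Dice to reach ≈0.92 with post-processing, small enough to run
anywhere in a few minutes. The full-scale configuration differs only in
`ModelConfig`/`PhantomConfig` arguments.

# Known limitations

* No DICOM reader: images must arrive as PNG/TIFF, with photometric
  inversion requested explicitly.
* Training is single-threaded CPU (beyond BLAS) and intended for small
  instances; the full 512-side, 12-layer configuration is expressible but
  not practical to train here.
* The component keep-rule assumes at most two lung fields; it would need
  adjustment for projections with confluent or absent lungs.
* Opening can in principle split a component after the keep-rule has been
  applied; for anatomically plausible masks this does not occur.
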