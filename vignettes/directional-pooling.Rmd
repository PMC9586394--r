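---
title: "Directional vector pooling blocks: model, assumptions, and design notes"
author: "vpbpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional vector pooling blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpbpool)
```

## The operators

Square pooling compresses a feature map with a fixed $k \times k$ window, and
many distinct inputs collapse onto the same pooled output: within each window
only the maximum survives, so any rearrangement of the sub-maximal cells (or
of the position of the maximum) is invisible downstream. The vector pooling
block (VPB) replaces the square window with two directional paths. For an
input $x$ with $C$ channels:

$$y_v = \mathrm{ReLU}(\mathrm{Conv}_{1\times1}(\mathrm{MaxPool}_{1\times N}(x))), \qquad
  y_h = \mathrm{ReLU}(\mathrm{Conv}_{1\times1}(\mathrm{MaxPool}_{N\times 1}(x))),$$
$$y = \mathrm{ReLU}(y_v \oplus y_h),$$

where $\oplus$ is elementwise summation and each $1\times1$ convolution
preserves the channel count. The long axis of each kernel collects extended
structure in one orientation while the unit axis keeps local detail in the
other; the two orientations see different projections of the window
contents, which is what restores discriminability between max-pool
collisions (`make_maxpool_collisions()` constructs such collision sets and
the identity-convolution VPB separates every one of them).

The AVG-MAX VPB extends this to four paths — max and average pooling, each
in both orientations — whose ReLU outputs are summed, passed through batch
normalization, and rectified once more. Average pooling contributes the
window mean, which max pooling discards, at the cost of two more $1\times1$
convolutions. The defining equations place the final ReLU directly on the
four-path sum, while the accompanying description inserts a batch
normalization layer between the sum and the ReLU; this package follows the
description (BN before the final ReLU), and the VPB carries no BN, matching
its own description. `avgmax_vpb_forward()` therefore takes a `mode`
argument (`train`/`infer`) and returns updated running statistics.

## Shape reconciliation

A $1\times N$ pooling kernel strided only along its long axis would produce
$H \times \lceil W/N \rceil$, which cannot be summed with the
$\lceil H/N \rceil \times W$ of the other path. Both paths therefore use the
same stride $(s, s)$ in *both* dimensions, where $s$ is the stride of the
square pooling layer the block replaces, with "same-ceil" padding
($\lceil \cdot / s\rceil$ output dimensions). This is the only
interpretation that simultaneously satisfies the elementwise-sum
combination and preserves the downsampling behaviour a U-Net encoder relies
on, making the block a drop-in replacement. Padding uses $-\infty$
sentinels for max pooling and excludes padded cells from averages, so
padding never biases either statistic; for even dimensions with $k = s$ the
padding vanishes entirely.

## Gradients and numerical choices

Both blocks have analytic backward passes (`vpb_backward()`,
`avgmax_vpb_backward()`) built from reverse-mode composition: ReLU gate
masks, sum fan-out, $1\times1$-convolution transpose rules, average-pool
uniform spreading over non-padded cells, and train-mode batch-normalization
gradients. Max-pool gradients route to the *first* maximal cell in
row-major window order, a deterministic tie-break matching common
framework behaviour. The test suite checks every gradient against central
finite differences ($h = 10^{-6}$, float64) on tie-free inputs (inputs are
jittered off ties, since the max-pool subgradient is discontinuous at
them); agreement is required to a relative error below $10^{-5}$.

Other numerical defaults: batch-norm $\varepsilon = 10^{-5}$, momentum 0.1,
with the biased ($1/m$) batch variance used both for normalization and for
the running-average update; $1\times1$ weights are initialized zero-mean
Gaussian with variance $2/C$ (the standard ReLU-network scaling) and zero
biases, deterministically per seed. $N$ defaults to the kernel size of the
replaced pool (2 for U-Net's $2\times2$ pools, 3 for the $3\times3$ pools
of the classification backbones) and remains configurable, since nothing
forces the directional length to equal the square kernel.

## Architecture surgery

Architectures are declarative layer lists (`arch_spec()`) validated by a
shape dry run. `replace_pooling()` rewrites every intermediate pool layer
of kernel $k \times k$ and stride $s$ into a block with $N = k$ and stride
$s$; trailing global average pools (the $7\times7$ head pools of
ResNet18/GoogleNet-style classifiers) are kept by default and replaced only
on request, since only the segmentation network is described as having
*every* pooling layer exchanged. Surgery returns a fresh spec, reports the
replacement count, and re-runs the shape check so a block that breaks a
skip connection fails loudly with the layer name.

The mini U-Net (`build_unet()`) follows the classic encoder–decoder with
two $3\times3$ convolutions per level, 2×2 stride-2 max pools, nearest-
neighbour upsampling and skip concatenation; depth 4 reproduces the
original pool count, while the desk-scale default used in tests is depth 2
with 8 base channels on $64\times64$ inputs. The classifier builders
reproduce the *pooling inventories* of the full-size backbones (three
$3\times3$ max pools for the AlexNet-like layout; one plus a trailing
average pool for ResNet18-like; four plus a trailing average pool for
GoogleNet-like) over deliberately miniaturized convolutional trunks —
CPU-trainable stand-ins, not reproductions of the pretrained networks.

## Training

`train_network()` is a plain mini-batch ADAM loop ($\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\varepsilon = 10^{-8}$) with a piecewise learning-rate
schedule: the rate is multiplied by `lr_factor` every `lr_period` epochs
(segmentation defaults: initial $10^{-3}$, factor 0.30 every 10 epochs,
batch 8; classification: initial $2\times10^{-3}$). The loss is per-pixel
(or per-sample) cross-entropy on the final softmax — the natural choice for
softmax outputs, which the source material leaves unstated. Everything is
deterministic given the seed: initialization, shuffling, and generator
draws all derive from it, and two runs with one seed produce bitwise-equal
losses. A non-finite loss aborts with a diagnostic rather than training
onward.

## The synthetic thermogram generator

No external image database is required: `generate_sample()` produces
thermogram-like images emulating frontal breast thermograms — a smooth
vertical thermal gradient plus five low-frequency Gaussian intensity
blobs, two overlapping warm ellipses in the lower half whose union is the
breast mask (+0.2 intensity), and for the abnormal class one compact
bright hotspot (amplitude +0.25, $\sigma \in [2.6, 5]$ px at the reference
$64\times64$ size) placed inside the mask. Placement is rejection-sampled
so that every abnormal image contains a disc of at least 20 pixels whose
mean intensity exceeds the mask mean by at least 0.15 — the contrast
contract the classification task rests on. Intensity and geometry
distributions are invented (no source describes them); every parameter is
recorded in the sample's `metadata` so fixtures are self-documenting.

What the generator does *not* emulate: physically realistic heat
diffusion, patient-to-patient anatomy variation, camera noise and
vignetting, or multi-view (lateral) acquisitions. Passing the pipeline
tests therefore validates the machinery — operators, gradients, surgery,
training, metrics — on an easy, controlled task; it says nothing about
clinical segmentation or classification performance on real thermograms,
whose headline numbers require the real database and full-size pretrained
backbones.

`generate_dataset()` writes PNGs plus a CSV manifest and splits 70:15:15
per class; the validation and test partitions each receive
$\lfloor n \cdot r / 100 \rfloor$ samples and remainders go to training
(for 500 per class: 350/75/75).

## Metrics

Segmentation evaluation (`seg_scores()`) reports global accuracy, per-class
and mean accuracy, per-class and mean IoU, and the boundary-F1 (BF) score.
Accuracy and IoU aggregate one confusion matrix over the whole evaluation
set and then average over classes; BF is computed per image per class,
averaged over images per class, and the mean BF averages the per-class
values. (With both classes present in every image — always true for the
generator — the image-then-class and class-then-image orders coincide; the
choice is logged here because the convention is genuinely ambiguous.)
Boundaries are the mask minus its 4-connectivity erosion, with image-border
mask pixels counting as boundary; the match tolerance defaults to 0.75% of
the image diagonal (rounded, at least 1 px), the established convention for
this metric, exposed as an argument. Undefined per-class metrics (a class
absent from the evaluation set) are excluded from means and reported,
never silently scored 0 or 1 — except the conventional BF cases: both
boundaries empty scores 1, exactly one empty scores 0.
Classification evaluation reports accuracy, sensitivity and specificity
from the sample-level confusion matrix.

## Problem sizes used by the shipped checks

The test suite and the acceptance script train the depth-2, 8-channel mini
U-Net on 64 generated $64\times64$ images (32 per class) for 15 epochs per
pooling variant, evaluating mean IoU on 16 held-out images, and the
AVG-MAX AlexNet-like classifier on 96 images for 15 epochs with batch 8,
evaluating accuracy on 24 held-out images. These sizes were chosen so the
whole pipeline remains comfortable on a single CPU while the tasks stay
easy enough that every variant should exceed 0.90 on its respective
metric; operator-level checks use 100 random inputs up to $4\times32\times
32$ (forward oracles, tolerance $10^{-12}$) and $2\times6\times6$ inputs
(full finite-difference gradient audits).

## Known limitations

- The inner-product path combination mentioned as an alternative to
  elementwise summation is not implemented; its operand shapes are never
  defined.
- Whole-row/whole-column "strip" pooling (producing $H\times1$ and
  $1\times W$ vectors) is a plausible alternative reading of the design;
  the downsampling interpretation implemented here is the only one that
  preserves pooling's dimensionality reduction inside an encoder–decoder,
  which the drop-in-replacement usage requires.
- Training is CPU-only, single-threaded base R; it is meant for desk-scale
  experiments and tests, not for full-size $224\times224$ backbone
  training, although the architecture and schedule defaults scale there in
  principle.
- The classifier trunks are miniatures; only their pooling inventories
  match the named backbones.
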