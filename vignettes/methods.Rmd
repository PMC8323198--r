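---
title: "Model, losses and phantom design in msffn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, losses and phantom design in msffn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msffn)
```

## The segmentation problem

Gliomas appear in multimodal MRI as nested, irregular sub-regions:
a necrotic center (label 1), an edema halo (2), non-enhancing tumor (3)
and an enhancing rim (4), against an overwhelming majority of
background and healthy tissue (label 0). Scoring follows three
overlapping regions rather than the raw labels: *complete* tumor
(labels 1+2+3+4), tumor *core* (1+3+4) and *enhancing* tumor (4),
each evaluated by Dice similarity (DSC), positive predictive value
(PPV) and sensitivity.

Two difficulties dominate. First, sub-regions span very different
spatial scales, so a segmenter needs both high-resolution detail and
deep semantic context. Second, tumor voxels are a small fraction of
the volume; a plain cross-entropy objective is dominated by the
background class and converges to low-recall solutions.

## Architecture

The model is a parallel two-part fully convolutional network operating
on 2-D axial slices with the four sequences stacked as channels
(order T1, T1c, T2, FLAIR, fixed in the model metadata).

**Feature extraction network (FEN).** Five stages of *conv units* — a
3×3 convolution (stride 1, same padding), batch normalization, ReLU —
with channel widths 16/32/64/128/256. The first stage has four units,
later stages two each (12 convolution layers in total); stages 1–4 end
with 2×2 max-pooling and dropout. Eight intermediate maps are exported
as *taps*: all four stage-1 outputs at full resolution, plus the final
map of each later stage at 1/2, 1/4, 1/8 and 1/16 resolution.

**Multi-scale feature fusing network (MSFFN).** Every tap is brought
to input resolution by bilinear interpolation (factors 2/4/8/16) and
all eight are concatenated — 4·16 + 32 + 64 + 128 + 256 = 544 channels.
A fusing block of three conv units at width 64, dropout, a 1×1
convolution to 5 channels and a softmax produce the per-pixel class
probabilities. Unlike an encoder–decoder, all scales are fused *in
parallel*, so gradients reach deep layers through short paths and
full-resolution detail is never reconstructed from coarse maps alone.

With this configuration the network stores 1,576,005 parameters —
convolution kernels and biases plus four batch-norm quantities per
channel (scale, shift and both moving statistics). At 4 bytes each
that is 6.3 decimal megabytes, reproducing the published size of the
architecture; `count_parameters()` and the test suite verify the count
against an explicit layer-by-layer arithmetic oracle. The exact channel
plan is not printed in the source publication; the widths above are a
reconstruction constrained by that 6.3 MB figure while preserving the
conventional doubling pattern, and the 1×1 (rather than 3×3) classifier
was chosen for the same reason. The published figures 256×…×16 map
sizes conflict with the 176-pixel input; we use the 176-derived pyramid
(176/88/44/22/11), consistent with the stated 2×/4×/8×/16× upsampling
factors.

The U-net baseline (`unet_net()`) uses encoder widths 32–512 with two
conv units per stage, BN everywhere for parity, bilinear-upsample +
conv decoding and skip concatenations. Its exact published size
(30.3 MB) depends on unstated choices (transposed convolutions?, BN?),
so the package asserts only the ordering — the baseline is roughly five
times larger than the proposed model (ours counts 31.4 MB).

## Loss functions

Let $p_{i,k}$ be the softmax probability and $g_{i,k}\in\{0,1\}$ the
one-hot annotation of pixel $i$, class $k$, with channel index equal to
the raw label value. All sums pool over every pixel supplied — for a
batch, over all its slices at once, matching the single-$N$ form of the
defining formulas (the per-image-then-average alternative is noted but
not used).

* **Cross-entropy** $-\frac1N\sum_i\sum_k g_{i,k}\log p_{i,k}$, with
  probabilities clipped to $[10^{-7}, 1-10^{-7}]$ before the log.
* **Per-class Dice loss**
  $DL_k = 1 - \frac{2\sum_i p_{i,k} g_{i,k} + \epsilon}
  {\sum_i p_{i,k} + \sum_i g_{i,k} + \epsilon}$.
* **Region Dice losses** apply $DL$ to *soft region memberships*, the
  channel sums over a region's member labels (e.g.
  $p_{i,\mathrm{com}} = p_{i,1}+p_{i,2}+p_{i,3}+p_{i,4}$).
* **Combined Dice** = background + complete + core + enhancing Dice
  losses; **sliced Dice** = the five per-class Dice losses.
* **Recall losses** $RL = 1 - \frac{\sum_i p_i g_i + \epsilon}
  {\sum_i g_i + \epsilon}$ per class or region: they penalize missed
  target pixels only, shifting emphasis to the minority classes.
* **Hybrid losses**:
  $HL_1 = \alpha L_{ce} + \beta RL_{com} + \gamma RL_{core} + \delta RL_{enh}$
  with default weights (20, 0.5, 1, 0.5), and
  $HL_2 = \alpha DL_{combined} + \beta RL_{com} + \gamma RL_{core} +
  \delta RL_{enh}$ with defaults (1, 0.1, 1.3, 0.5).

Numerical choices: the smoothing constant $\epsilon = 10^{-5}$ enters
both numerator and denominator of every ratio loss, so a region absent
from both prediction and truth scores 0 (perfect) instead of dividing
by zero. The source text prints a factor 2 in the numerator of the
core-region recall loss, inconsistent with the other recall formulas
and with recall's definition (it would allow negative loss); the
package implements the loss without it and treats the 2 as a typo.
Analytic gradients of every loss are implemented alongside the values
and verified against central finite differences at $10^{-4}$ tolerance,
and every vectorized loss is checked against naive per-pixel
double-loop oracles at $10^{-6}$.

## Training

`msffn_train()` fits with Adam under a triangular cyclical learning
rate between $10^{-6}$ and $10^{-3}$ (the recipe's stated bounds);
`cycle_length` defaults to four epochs' worth of iterations, our choice
where only the bounds are given. The default batch size is 40 slices.
Augmentation uses horizontal/vertical flips and 90°-multiple rotations
only — these are label-exact (no interpolation), and the printed recipe
names flips and rotations without angles. Preprocessing is a centered
crop to the network input size (the 240→176 crop removes a 32-pixel
air border on each side; placement is our choice where the text asks
only to remove the border while keeping the brain) followed by
per-modality, per-case z-scoring over all voxels of the cropped volume
(the simplest, deterministic reading; brain-mask-only statistics are a
possible alternative).

Slice handling: training keeps only slices with brain content
(prediction always processes every slice). `slices_per_case` optionally
subsamples each case's slices per epoch — the standard device for
training a 2-D network from volumes on a compute budget — and
`tumor_slice_bias` draws half of that subsample from tumor-bearing
slices, a sampling-level counterpart of the loss-level imbalance
handling. Model selection keeps the weights with the lowest validation
loss; validation DSC is logged but not used for selection. Ensembling
(`build_ensemble()`) averages softmax maps across members before the
argmax — averaging uses the full probability information; majority
voting is available behind a flag. Per-member training sets are
obtained by re-seeding the 80/20 case-level split.

Batch-norm uses population statistics with momentum 0.9 on the moving
buffers; evaluation mode is deterministic. Conv biases ahead of BN are
retained (they are absorbed by the normalization — their gradient is
exactly zero — but they are part of the parameter-count convention the
6.3 MB figure relies on).

## Synthetic phantoms

`generate_case()` builds a multimodal phantom: an ellipsoidal brain in
a dark background and, with probability `tumor_probability`, one tumor
of nested sub-regions sharing a single perturbed ellipsoidal distance
field — necrotic center, non-enhancing band, enhancing rim, edema
shell. Because all interfaces are level sets of one field, the region
nesting enhancing ⊆ core ⊆ complete holds by construction. Intensities
follow a fixed tissue-by-modality table mimicking clinical contrast
(T1c-bright rim, FLAIR/T2-bright edema, T1-dark necrosis) plus Gaussian
noise (SD 10 against tissue separations of 20–60 units), so the task is
learnable but not trivial. Default test-scale volumes are 64×64×32 with
tumors occupying 1–3% of the volume — the background fraction stays
above 0.85, reproducing the class-imbalance regime.

What the phantoms do *not* emulate: real anatomy (no atlas), Rician
noise, bias fields, multi-focal or infiltrative growth, inter-scanner
intensity variation. Passing the desk-scale checks therefore
demonstrates that the architecture, losses, training loop and
evaluation are implemented correctly and can learn a nested,
imbalanced, multimodal segmentation task end to end — not that the
package reaches any particular accuracy on clinical data, which
requires the real benchmark and its online scorer.

## Desk-scale study conditions

The test suite trains the default model at 64×64 on 40 phantoms (32
train / 8 held-out by a case-level 80/20 split) with HL2 for 12 epochs,
batch 8, three slices per case per epoch, and requires mean held-out
complete-region DSC ≥ 0.80; with the frozen seeds the run reaches
≈ 0.86. A smaller companion experiment (15 phantoms at 32×32, 4 epochs,
three seeds) compares HL1 against plain cross-entropy and reports the
direction of the complete-region sensitivity difference; consistent
with the motivation for the recall terms, HL1 raises sensitivity at the
expense of precision. Problem sizes were chosen so a full check runs on
a single CPU in well under half an hour; they are stated here so the
conditions are explicit and reproducible.

## Known limitations

* 2-D slice-wise segmentation only; no 3-D convolutions and no CRF
  post-processing (out of scope by design).
* The published channel configuration is reconstructed, not copied;
  all counts are constrained by the printed model size.
* The empty-mask conventions of the reference online scorer are
  undocumented; this package scores both-empty as 1 and one-empty as 0
  so a correct all-negative prediction is not penalized.
* MetaImage support covers the uncompressed, single-file (`LOCAL`)
  form the pipeline writes; compressed or detached-header MetaImage
  files are rejected.
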