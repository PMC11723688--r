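---
title: "Methods: U-Net variants for histology segmentation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: U-Net variants for histology segmentation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pancreatic ductal adenocarcinoma (PDAC) biopsies are scanned as multi-gigapixel
whole-slide images (WSIs). Pathologist annotation marks tumor regions with a
contour line; the machine-learning task is per-pixel semantic segmentation of
tumor vs. background tissue inside pathologist-selected regions of interest
(ROIs). Because whole slides are far too large for a network input, the
pipeline is: annotate contours, crop ROIs, rasterize contours into binary
masks, mine fixed-size patches, train an encoder–decoder network with Dice
loss, and at inference patchify a large region, segment each tile, and
recombine (unpatchify) the tile predictions.

`histoseg` implements this pipeline end to end for a family of seven U-Net
architecture variants that are commonly compared on histology segmentation:
vanilla U-Net, Attention U-Net, Residual U-Net, Dense U-Net, Inception
U-Net, Squeeze-and-Excitation (SE) U-Net, and U-Net++.

## The unified backbone

All seven variants are instantiated from one configuration
(`unet_config()`) so that differences between them are attributable to their
block design rather than to capacity knobs:

* input 256×256×3 patches;
* depth 4: four 2×2 max-pooling stages down, four 2×2 stride-2
  transposed-convolution stages up;
* 16 filters at the first stage, doubled after each pooling and halved at
  each upsampling (so the bottleneck runs at 256 channels);
* three 3×3 convolutions per stage, every convolution (except the output
  head) followed by batch normalization and a ReLU;
* a 1×1 output convolution to 2 channels and a per-pixel softmax, so the
  output is a probability distribution over {background, tumor} at every
  pixel; binarization is arg-max (equivalently, foreground probability
  ≥ 0.5).

The network engine is implemented in R directly on BLAS matrix products
(a K×K convolution is K² flat matrix multiplications over a zero-padded
input) with hand-derived backward passes for every operator; the test suite
checks the analytic gradients of the whole graph against central
differences for each variant.

## Variant blocks and how their free knobs were pinned

The variant comparison that motivates this package reports, for each
architecture, a trainable-parameter total in millions. Published
descriptions of such comparisons rarely pin the block internals (SE
reduction ratio, inception branch widths, dense growth rate, nested-node
convolution count), but the parameter totals do pin them: for each variant
we chose the simplest standard form of the block and then fixed its single
free knob so the built network's count, rounded to the printed precision,
reproduces the published total. The resulting designs:

| variant | block design | free knob (pinned value) | count (×10⁶) |
|---|---|---|---|
| vanilla | three plain conv–BN–ReLU per stage | — | 2.93 |
| attention | additive attention gate on each skip, gated by the upsampled decoder signal; biased 1×1 convolutions, no BN in the gate | intermediate width = 1 × skip channels | 2.97 |
| residual | identity shortcut spanning convolutions 2–3 of each block (channels already match after convolution 1, so no projection) | — | 2.9 |
| dense | DenseNet-style block: three densely connected 3×3 convolutions plus a 1×1 transition to the stage width | growth rate = 15/16 × stage width | 5.4 |
| inception | four parallel branches (1×1; reduce→3×3; reduce→5×5; 3×3 same max-pool→1×1), each contributing a quarter of the stage width | reduction width = 5/4 × stage width | 4.6 |
| se | squeeze-and-excitation recalibration after every stage block | reduction ratio r = 2 | 3.04 |
| unetpp | nested dense skip pathways, two convolutions per node (backbone column included), transposed-conv upsampling halving channels, deep supervision off | the node that first refines the bottleneck keeps three convolutions | 2.4 |

Two of these deserve comment.

*Residual.* A residual block with a projection shortcut across the whole
three-convolution block would add ≈88k parameters and push the rounded
count to 3.0. Placing the identity shortcut after the first convolution
(where the channel count already equals the stage width) needs no
projection and leaves the count at the published 2.9.

*U-Net++.* Applying the backbone's three convolutions to every nested node
yields ≈3.05×10⁶ parameters, well above the published 2.4; plain
two-convolutions-per-node yields ≈2.27×10⁶, which rounds to 2.3. The
minimal structural choice landing on 2.4 keeps two convolutions everywhere
except the single node that first upsamples the bottleneck (the
parameter-heaviest refinement step), which retains three. This is recorded
here because it is the one place where the printed budget, not a standard
block recipe, decided the design.

## Loss, metrics, and conventions

Training minimizes the soft Dice loss. For foreground probabilities $p$ and
binary truth $t$,

$$\mathrm{Dice}_{soft} = \frac{2\sum p\,t + \varepsilon}{\sum p + \sum t + \varepsilon},
\qquad \mathcal{L} = 1 - \mathrm{Dice}_{soft},$$

with smoothing $\varepsilon = 1$ stabilizing empty-mask gradients. The loss
is computed per sample and averaged over the batch; its analytic gradient
is propagated through the softmax. On binary predictions the soft Dice
reduces to the count form $2TP/(2TP+FP+FN)$.

Evaluation reports *accuracy* as the per-patch unweighted mean Dice
coefficient expressed in percent, and the mean intersection-over-union
(IoU). Conventions, applied consistently everywhere:

* two empty masks agree perfectly: Dice = IoU = 1;
* Dice and IoU are linked by $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
  for any pair of binary masks (a property test enforces this identity);
* binarization is arg-max over the two classes;
* validation Dice during training is computed on binarized predictions,
  matching evaluation (the soft Dice is additionally logged for
  transparency). Whether the original comparisons validated on soft or
  binarized Dice is not determinable from their description; binarized was
  chosen because model selection should match the reported evaluation
  metric.

## Training protocol

`train_config()` defaults encode the reference protocol: 100 epochs, batch
size 16, Adam with default parameters (learning rate 10⁻³, β = (0.9,
0.999), ε = 10⁻⁷), on-the-fly augmentation restricted to random horizontal
and vertical flips (probability 0.5 per axis, independently; flips are the
only transform that cannot distort histological texture), and model
selection at the epoch with the best validation Dice, ties resolved to the
earliest epoch. Checkpoints carry the parameters *and* the batch-norm
running statistics, so a reloaded checkpoint reproduces its logged
validation Dice exactly.

Numerical choices: weights use He fan-in-scaled normal initialization under
a recorded seed; batch-norm uses ε = 10⁻³ and a running-statistics decay of
0.9 (the faster torch-style default rather than 0.99, because under short
desk-scale protocols validation metrics would otherwise be computed against
badly stale statistics); training is deterministic given the seed and a
fixed BLAS.

## Tiling and annotation conventions

* Coordinates are 0-based (row, col); windows and bounding boxes are
  half-open.
* Training patches are mined on a half-overlap grid (stride = tile/2) and
  kept when they contain tumor surface — by default ≥ 1 positive mask
  pixel, configurable via `min_positive`.
* Inference uses non-overlapping tiles (stride = tile); a 1024×1024 region
  yields exactly sixteen 256×256 tiles. Non-divisible regions are
  reflect-padded bottom/right and the padding is cropped after
  reconstruction, making `unpatchify(patchify(x))` the identity, bit for
  bit. Overlapping inference grids average tile probabilities and threshold
  at 0.5.
* Polygons rasterize by the even-odd rule at pixel centers
  ((col + 0.5, row + 0.5)); masks encode tumor as deep blue (0, 0, 255) on
  black; difference maps color TP light blue (128, 200, 255), FN deep blue,
  FP gray (128, 128, 128), TN black. The published figures name these
  colors without RGB values; the values are this package's choice.

## The synthetic fixture generator

The real WSI corpora behind this class of study are private, so every
module is exercised against `generate_roi()`/`build_corpus()` fixtures:
smooth Gaussian color fields (eosin-pink stroma vs. purple-shifted tumor),
Poisson-scattered dark elliptical nuclei (4× denser in tumor), and tumor
blobs bounded by low-frequency radial perturbations of ellipses — so each
blob has an exact per-pixel mask *and* a 72-vertex polygon annotation that
rasterizes to Dice ≥ 0.98 against it. A `difficulty` knob in [0, 1] moves
the tumor color distribution toward the background and raises noise; at
difficulty 0 a per-pixel color threshold recovers the mask at Dice > 0.99
(the separability oracle), and the oracle's score decreases monotonically
in difficulty.

What the generator does *not* emulate: stain variability between scanners,
out-of-focus regions, tissue folds, the morphological continuum between
well- and poorly-differentiated tumor, or annotation error. Tests passing
on these fixtures therefore demonstrate that the pipeline's machinery is
correct and that the architectures can learn a separable segmentation task
— not that any accuracy level transfers to real histology.

Split bookkeeping mirrors the WSI-level practice: whole sources are
assigned to train/validation/test, so patches from one pseudo-slide never
span splits; the default allocation scales the 26/5 train+validation/test
source split of a 31-slide corpus.

## Desk-scale profile and problem sizes

The full protocol (256×256 patches, depth 4, 100 epochs) is available but
deliberately not what the test suite runs. The package's desk-scale profile
— used by the learnability checks — is 32×32 patches, depth 2, 8 base
filters, two convolutions per block, batch 8, at most 10 epochs with early
stop once validation Dice reaches 0.98, on fully separable (difficulty 0)
fixtures of six 96×96 pseudo-slides (≈70 training patches). Learnability
corpora additionally raise the mining keep rule to 5% of the tile area:
at 32×32 resolution a patch holding a 2–4 pixel boundary sliver measures
boundary discretization, not class separability, and would dominate the
per-patch mean Dice. Under this profile each of the seven variants reaches
validation Dice ≥ 0.95, as the acceptance suite verifies on every run.

## Known limitations

* The engine is CPU-bound R; the full 256×256/100-epoch protocol is
  functional but slow — the package's scientific claims at full scale are
  limited to architecture construction and parameter accounting, which the
  acceptance script recomputes exactly.
* Only binary (tumor/background) segmentation; no multi-class head.
* No proprietary WSI container parsing (Motic, Aperio SVS): inputs are
  PNG/TIFF crops.
* Variant block internals beyond the parameter budgets are underdetermined
  by their published descriptions; the pinned knobs above are one
  consistent resolution, not a reconstruction of the original code.
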