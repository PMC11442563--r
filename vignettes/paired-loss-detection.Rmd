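---
title: "Training lesion detectors on synthetic positive/negative pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training lesion detectors on synthetic positive/negative pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The idea

Segmentation-based lesion detectors are usually trained with the soft Dice
loss on labeled diseased images. Dice has a blind spot: on a lesion-free
image (empty label region $R = \emptyset$) it degenerates to
$-\epsilon / (\sum_x f(x) + \epsilon)$, a nearly constant value dominated by
the stabilizer $\epsilon$, so negative images contribute almost nothing to
training and false positives (FPs) are only weakly penalized.

When lesions are *synthesized* into healthy backgrounds, something unusual
becomes available: for every diseased image $I_+$ there is a pixel-identical
healthy twin $I_-$. `cadpair` exploits such pairs with two extra loss terms
on the detector output $f(\cdot) \in [0, \infty)$:

* **Necmos** (negative-case maximum output suppression):
  $l_{Necmos}(f_-) = \max_{x \in \Omega} f_-(x)$.
  Candidates are the connected components of $\{x : f(x) > 0\}$, so a
  negative image produces zero FPs exactly when this maximum is zero; the
  term is the most direct FP penalty available.
* **Nac** (normal-abnormal contrastive):
  $l_{Nac} = -\min\{1, \max_{x \in R} f_+(x) - \max_{x \in R} f_-(x)\}$,
  rewarding a higher response inside the true lesion region on the diseased
  image than at the same location of its twin, clipped at 1 so the
  difference is not rewarded without bound.

The combined objective is
$w_{Dice} D + w_{Necmos}\, l_{Necmos} + w_{Nac}\, l_{Nac}$, where the Dice
term is computed after the squashing transfer $f \mapsto f/(1+f)$ that maps
the raw output range onto $[0, 1)$. The pairing is needed only for
training: inference takes one image.

### The Dice term and its logarithm

The source formulation places the Dice loss inside a logarithm. Since the
soft Dice loss $l_{Dice}$ lies in $[-1, 0)$, a literal $\log l_{Dice}$ is
undefined; this package implements the Dice term as
$D = -\log(-l_{Dice})$ — the negative log of the soft Dice coefficient.
This is the standard "log-Dice" form: it is finite everywhere, strictly
decreasing in the Dice coefficient, minimized exactly where $l_{Dice}$ is,
and it steepens the gradient when overlap is poor. This reading is a design
decision of the package, not the only possible one.

Two further placement decisions: Necmos and Nac act on the *raw*
$[0, \infty)$ outputs, because they are defined on that range and only the
Dice calculation is preceded by the transfer; and per-batch losses are
averaged (not summed) so that the learning rate is batch-size invariant.

## The pair simulator

The simulator stands in for a generative model of normal radiographs and
produces fully labeled pairs:

1. **Nodule solid.** A union of overlapping spheres: each added sphere is
   attached to a random predecessor at a center distance below
   $r_{parent} + 0.85\, r_{new}$, which keeps the center-to-union distance
   below $r_{new}$ and hence the solid connected. Sphere count, radii, and
   a per-shape attenuation coefficient are drawn from configured ranges.
2. **Projection.** Orthographic (parallel-ray) projection along the depth
   axis with analytic ray–sphere chords; per-ray chord intervals are merged
   before summing, so overlapping spheres are not double counted. The
   projection geometry of the imaging system is not specified by the source
   method, and parallel rays make every value exact.
3. **Background.** A procedural phantom: two soft-edged elliptical lung
   fields, a periodic rib-like band masked to the lungs, radial
   vignetting, and additive Gaussian noise. It emulates the *structure* of
   a chest radiograph (bright fields, periodic texture, smooth shading),
   not its appearance.
4. **Embedding.** Beer–Lambert attenuation $e^{-a(x)}$ applied to the
   background (on the inverted scale by default, so nodules read as added
   opacity), then linear interpolation between background and embedded
   image with a blend ratio $\alpha \sim U(0.3, 1)$. The random ratio
   reproduces the variable faintness that latent-space interpolation gives
   real synthesized nodules, in pixel space. The label is the attenuation
   map above 1% of its maximum — the threshold trims the anti-aliased rim
   that would otherwise inflate IoU denominators.

Because the twin is the *same* background, the pair differs only inside the
projected footprint; the package checks bit-identity outside the footprint
dilated by one pixel.

What the phantom does *not* model: anatomy (mediastinum, clavicles, vessel
trees), scanner characteristics, pathology other than blob-like nodules,
and scale (desk-scale images are 32–128 px, not 1024 px). Tests passing on
phantom pairs show the machinery is correct and that the loss behaves as
designed; they do not certify clinical performance.

## Detector and training

The detector is a U-shaped encoder–decoder with max-pool downsampling,
nearest-neighbor upsampling, shortcut concatenation, optionally residual
double-conv blocks, and a final ReLU so every output pixel is nonnegative
— the contract that ties candidates ($f > 0$) to the Necmos analysis. The
reference-scale setup (nine levels at 1024 px with a dense bottleneck
block) is expressible via `model_config()`, but the default is a small
CPU-scale variant (3 levels, 8 base channels, 32 px), because the
contribution under study is the loss, which is architecture-agnostic.
There being no framework dependency, convolution forward/backward passes
are implemented in compiled code and the optimizer is Adam with a fixed
learning rate (default `1e-3`; no schedule).

Both images of a pair pass through the same network; gradients from both
outputs accumulate before each optimizer step. After every epoch the model
is scored on a validation split by **R-CPM** — the mean FROC sensitivity at
1/8, 1/4, 1/2, and 1 FPs per case, with candidates matched to lesions at
IoU ≥ 0.1 — and the checkpoint with the best validation R-CPM (earliest on
ties) is selected. A separate Dice-only fine-tuning mode
(`fine_tune_single()`) accepts single images with or without labels —
lesion-free images train through the degenerate Dice branch — emulating
leave-one-case-out adaptation to a real labeled dataset, where no negative
twins exist.

### Numerical choices

* **Output clip.** The forward output ReLU is exact (zeros are real zeros;
  candidate extraction depends on this), and so is its backward
  subgradient during normal training. One state needs special handling:
  a few suppression-heavy batches can push *every* output pre-activation
  negative, after which the hard subgradient is identically zero and
  training is irreversibly dead — the all-zero-output failure that
  suppression-heavy weightings are known to produce. Exactly in that
  absorbing state, where any subgradient choice is otherwise
  inconsequential, the clipped side passes a small leak (0.01) so the
  Dice term can revive lesion pixels. The leak is deliberately *not*
  applied outside the dead state: Adam normalizes per-parameter gradient
  scale, so an unconditional leak would inflate the tiny clipped-side
  gradients into full-size parameter drift and measurably degrade
  training. `net_forward(output_leak = 0)` disables the escape hatch
  (used by the gradient-check tests).
* **Necmos at its optimum.** When a negative map is identically zero the
  Necmos term sits at its minimum; the zero subgradient is used rather
  than pushing the (arbitrary) first argmax pixel further down.
* **Max ties.** The max-type loss terms route their gradient to the first
  argmax pixel; exact ties have measure zero for continuous outputs.
* **Thresholding convention.** A candidate survives a threshold $\theta$
  iff its likelihood $L_j \ge \theta$; FROC/ROC operating points are step
  functions over the sorted unique likelihoods with no interpolation; the
  FP rate denominator counts *all* evaluated cases, positive and negative.
  Fractional-FP sensitivities read off a step curve can therefore differ
  slightly from conventions that interpolate.
* **Connectivity.** Candidate regions use 8-connectivity (diagonal
  bridges join); the labeler is compiled, and tests cross-check it against
  an independent flood fill under both 4- and 8-connectivity.
* **Degenerate inputs.** `nac_loss()` refuses an empty lesion region
  rather than inventing a value — the term is undefined there, and
  negative-only training paths (fine-tuning) use the Dice objective
  instead. `iou()` refuses two empty sets. `case_roc()` scores a
  candidate-free image 0.

## The desk-scale benchmark

The package's own study conditions, used by the test suite and
`scripts/acceptance.R`: 128 training / 32 validation pairs at 32 × 32 px,
nodules of 2–4 spheres with radii 1.8–3.5 px, attenuation 0.02–0.07 per
unit length, background noise SD 0.02, blend ratio $U(0.3, 1)$; a 3-level,
8-channel residual network trained 20 epochs with Adam (learning rate
`1e-3`, batch 8). These sizes were chosen so a training run takes on the
order of a minute on one CPU core; the reference experiment behind the
method is four orders of magnitude larger (131,072 pairs at 1024 px on
multi-GPU hardware), so headline clinical metrics are out of reach by
design and all expectations at this scale are *comparative*: with
everything else fixed, the combined loss should produce fewer candidates
on negative validation images than the Dice-only ablation, and no worse
validation R-CPM, across seeds. An earlier draft of these conditions used
higher-contrast nodules (attenuation up to 0.15, noise 0.01); validation
R-CPM then saturated at 1.0 within two epochs, which makes best-epoch
selection and arm comparisons meaningless, so the contrast was lowered
once to keep the metric informative and the conditions were frozen.

The simulator defaults (`synth_config()`) target a 128-px image with
correspondingly larger nodules; the benchmark overrides them through
`default_run_config()`.

## Known limitations

* The phantom background lacks real anatomy; absolute metric values on it
  say nothing about radiographs.
* Loss gradients at max ties and at the Nac clip are subgradients; the
  finite-difference tests deliberately avoid those kinks.
* Training small networks with max-based sparse gradients is noisy between
  epochs; best-epoch selection (the method's own procedure) absorbs most
  of that variance, but per-seed outcomes still vary.
* The FROC step-function convention can differ from interpolating
  implementations by small amounts at fractional FP rates.
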