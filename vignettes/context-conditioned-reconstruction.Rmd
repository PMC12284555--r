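---
title: "Context-conditioned artifact removal for sparse-sampled photoacoustic tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-conditioned artifact removal for sparse-sampled photoacoustic tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paomninet)
```

## The problem

Photoacoustic tomography reconstructs optical absorption maps from
ultrasound signals recorded by an array of transducer elements. Cost and
acquisition-speed pressures push systems toward *sparse sampling* — far
fewer elements than artifact-free reconstruction requires — and
backprojection of sparse data produces radial *streak artifacts*.
Convolutional networks remove these artifacts well, but a conventional
U-net must be retrained for every new transducer configuration.

The model implemented here (the PA OmniNet architecture) avoids
retraining by conditioning each forward pass on a small **context set**
of labeled input–output example pairs (typically 4–32). One trained
model then adapts to a new system simply by being handed a context set
that approximately represents the new task.

## The architecture

The network consists of a shared 3×3 embedding, **seven
Pairwise-Conv-Avg blocks** arranged as a U (three encoder blocks with
factor-2 down-resizing, one bottleneck, three decoder blocks with
factor-2 up-resizing), and an output convolution. Each block receives
three inputs — the target features and the per-pair context-in and
context-out features — and:

1. passes the target through its own residual unit (two 3×3
   convolutions with a LeakyReLU between, plus the identity);
2. passes every context-in and context-out feature through a residual
   unit whose weights are *shared* between the in and out streams;
3. concatenates `[target', in'_k, out'_k]` per pair on the channel axis
   and reduces back to the working width with a 1×1 convolution;
4. updates the target as the **mean over pairs** of these candidates;
5. resizes all outputs for the next block.

Because step 4 is a plain average, the network is exactly invariant to
context-pair order and to duplicating the context set — this is the
mechanism behind varying the context size freely between training and
inference, and both invariances are asserted to 1e-6 in the test suite.

### Choices the architecture description leaves open

The block count (seven) and the pairing/averaging scheme are fixed by
the design; the following were genuinely open and are resolved here as
config options with these defaults:

* **Layout** — 3 encoder / 1 bottleneck / 3 decoder, the symmetric U
  with the stated block count.
* **Resizing** — parameter-free factor-2 resizes: 2×2 average pooling
  down, bilinear (half-pixel-centre) up. A learned resize would add
  parameters the description never mentions.
* **Channel schedule** — `base_channels` at the top, doubling per
  down-resize, capped at 8× base (standard U-net practice).
* **Skip connections** — encoder-level *target* features are
  concatenated to the decoder target stream and reduced by a 1×1
  convolution; context streams are resized alongside but receive no
  skips (they only need to deliver coarse guidance).
* **Embedding** — one shared 3×3 convolution for the target and both
  context roles (`shared_embedding = FALSE` gives the context streams
  their own), extending the shared-weight principle of the context
  residual units.
* **Activation** — LeakyReLU(0.01) in residual units; ELU is specified
  for the baseline U-net and available here as a switch. No
  normalization layers.
* **Final block** — the context streams are dropped after the last
  block (their transition convolutions would otherwise be dead weights
  that never receive gradient).
* Odd spatial sizes are rejected at validation (inputs must be
  divisible by 8) rather than silently padded.

The baseline U-net is a plain encoder–decoder with two ELU convolutions
per level, average-pool down, bilinear up with skip concatenation, and
an optional scaled-RMSE loss — the published baseline's dilated/dense
hybrid internals are deliberately not reproduced; the comparisons this
package supports are property-based, not score-parity claims.

## Losses and statistics

Training losses: MSE, SSIM dissimilarity (`1 - SSIM`), and the **Alpha
loss** `(1 - α)·MSE + α·(1 - SSIM)` with α = 0.84. Read literally the
mixed loss adds `+α·SSIM`, which a minimizer would drive toward
*dissimilarity*; the dissimilarity convention used by the mixed-loss
literature the α value comes from is the default, and the literal form
is available behind `literal = TRUE` for audit. SSIM uses the reference
parameters (11-tap Gaussian window, σ = 1.5, K1 = 0.01, K2 = 0.03,
L = 1) since none are stated in context; PSNR uses `max_val = 1`
because every image is normalized to [0, 1] upstream.

The **edge sensitivity** statistic compares, across two transducer
counts i and j, the change in reconstruction SSIM to the change in
input-edge SSIM:

```
S = [SSIM(N_j, Gt_j) − SSIM(N_i, Gt_i)] /
    [SSIM(edge(X_j), Gt_j) − SSIM(edge(X_i), Gt_i)]
```

`edge(·)` is a Sobel gradient magnitude (replicated borders, min–max
normalized) — the operator itself is unspecified in the source
formulation, and the denominator wording is ambiguous between
comparing `edge(X)` against the ground-truth *image* (the literal
reading, default) and against the ground truth's *edge map*
(`denominator = "edge_vs_edge"`); both are implemented, neither is
asserted as authorial intent. A zero denominator raises an explicit
error rather than returning an infinity.

All losses are differentiable through the package's reverse-mode tape
(SSIM included — it is built from convolutions and elementwise ops, so
its gradient is exact and is checked against central differences).

## The simulator

No external data is required: an idealized 2-D forward model generates
paired sparse/dense images that reproduce the streak-artifact
phenomenology at desk scale.

* **Field of view** [-1, 1]², pixel centres, origin at the grid centre,
  y up. Sound speed normalized: one time bin per pixel width; the bin
  count `ceil(1.5 × grid diagonal)` covers every propagation path.
* **Geometries** — ring (full circle), semicircle (180° arc),
  multi-segment (a chord holding half the elements flanked by two
  concave wings of a quarter each: 256 = 128 + 64 + 64), linear.
* **Forward model** — bin t of element e integrates the phantom over
  the pixels whose distance to e rounds to t bin widths (an arc
  integral); **reconstruction** is nearest-bin delay-and-sum, min–max
  normalized. With few elements each pixel is covered by only a few
  arcs, which *is* the streak pattern: a 16-element ring imaging a
  centred point yields an angular profile with dominant frequency 16.
* **Sparse sampling** — uniform stride decimation anchored at the first
  element (which elements are kept is a convention; uniform is the
  standard one). Multi-segment arrays are decimated per segment so the
  2:1:1 composition survives at every sparsity level.
* **Datasets** — seeded random scenes (2–5 disks, 0–2 vessel
  segments) assigned round-robin to synthetic "patient" groups; whole
  groups are partitioned 70/20/10 (configurable) into
  train/validation/test so no group spans two splits. Everything is a
  pure function of the seed. Per-image min–max normalization to [0, 1]
  is a stand-in for whatever windowing real scanner pipelines apply —
  the upstream preprocessing is not documented for the real datasets.

What the simulator does *not* emulate: acoustic heterogeneity,
frequency-dependent transducer response, 3-D propagation, realistic
noise spectra (only optional additive Gaussian noise), or real tissue
texture. Passing tests therefore demonstrate that the method behaves as
claimed on streak-artifacted inputs, not that it reaches any particular
score on scanner data.

## Training and inference protocol

* Adam, learning rate 1e-4, at most 500 epochs with early stopping on
  validation loss (patience 20 epochs — a patience value is needed but
  none is stated; the best-validation epoch's weights are kept).
* Training context: a **sliding window of 4** — each training item's
  context is the next four input–output pairs in dataset order,
  wrapping modulo the dataset size (wrap keeps the window size constant
  at the dataset tail; what happens there is otherwise unspecified).
  The target pair is never its own context.
* Validation uses the training protocol (sliding window); which
  protocol validation used is unspecified, and the training one keeps
  model selection consistent with what is being optimized.
* Inference context: **static**, the first 16 pairs of the training
  data in stored order (the dataset writer records a canonical order to
  make "first" well defined), identical for every test input. Outputs
  are clipped to [0, 1].
* Batch size 8 by default (unstated; config-exposed). Seeds fully
  determine shuffling, weights, and therefore the whole trajectory —
  two runs with the same seeds produce identical loss curves.

## The context-identifiability experiment

The headline mechanism — that the context set, not just the input,
steers the reconstruction — is tested at desk scale by
`context_identifiability_experiment()`: one network is trained jointly
on two synthetic degradation tasks (ring-16 and multisegment-32), then
held-out test images are reconstructed under (a) the matching task's
context, (b) a context from the same task but a held-out group, and
(c) the other task's context. Matched must beat mismatched (one-sided
paired t-test on pooled per-image SSIM differences, p < 0.05 over
three seeds), and the same-task/other-group context must degrade SSIM
less than the mismatched-task context.

Study conditions, chosen once for desk scale: 32×32 images, 4 base
channels, 45 items in 9 groups per task (25 train / 10 val / 10 test
after the 0.6/0.2/0.2 grouped split; 60 pooled comparisons over three
seeds), training context 2 and test context 8 (scaled from 4/16), MSE
loss, Adam at 2e-3 for up to 40 epochs (patience 10, batch 2). The
learning rate and epoch budget were set so the toy model actually
converges (final MSE ≈ 1e-3, reconstruction SSIM well above the raw
input's); the package-level defaults remain the full-scale protocol
values. The output convolution is initialized at a tenth of the He
scale so early optimization is not spent shrinking the activation scale
accumulated through seven residual blocks.

## Numerical choices and degenerate inputs

* Convolutions are direct correlations (no kernel flip), compiled via
  im2col + BLAS; weight layout is documented in `src/conv_ops.cpp`.
* The tape propagates gradients only into subgraphs containing a
  parameter, so constant inputs cost nothing on the backward pass.
* `sqrt` in the scaled-RMSE loss is stabilized with eps = 1e-12.
* Min–max normalization of an all-constant image returns all zeros.
* A non-finite training loss aborts with a diagnostic rather than
  continuing.
* The paired t-test refuses zero-variance differences; the sensitivity
  ratio refuses a zero denominator.
* PNG round-trips quantize intensities to 8 bits; the dataset writer is
  byte-deterministic given the seed.

## Problem sizes used by the tests and the acceptance script

Oracle-equivalence checks run on ≤ 32×32 instances against brute-force
loop implementations written independently in the test helpers. The
simulator quality curve uses 20 seeded scenes per element count at
64×64 with a 256-element dense ring. The mechanism experiment uses the
desk-scale conditions above. These sizes are the package's chosen study
conditions; the published full-scale experiments (256×256 images, tens
of thousands of pairs, 60 trained models) are out of scope here, and
the published per-dataset improvement table is shipped as a fixture so
its aggregation arithmetic (panel averages, positive fractions, paired
t-tests) is reproduced from data rather than re-measured.

## Known limitations

* The simulator's idealized physics means absolute SSIM/RMSE/PSNR
  levels are not comparable to scanner-data results; only relative and
  structural claims transfer.
* The hybrid U-net baseline's exact published architecture is not
  reproduced (its defining details live outside the source text).
* The paired t statistics printed alongside the published improvement
  table were evidently computed on unprinted underlying scores; the
  package reproduces the t-test machinery and the table's aggregation,
  not those specific t values.
* Training is CPU-bound R/C++; it is sized for 32–64 px experiments,
  not for 256×256 production training.
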