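# paomninet

Context-conditioned artifact removal for sparse-sampled photoacoustic
tomography, in R.

Photoacoustic tomography (PAT) maps optical absorption in tissue by
recording laser-induced ultrasound with an array of transducer elements.
Using fewer elements makes systems cheaper and faster but leaves radial
*streak artifacts* in backprojection reconstructions. Deep networks remove
these artifacts well, yet a conventional U-net must be retrained for every
new transducer configuration. This package implements a
**context-conditioned reconstruction network** (the PA OmniNet
architecture): alongside the image to be cleaned, the network receives a
small **context set** of labeled input–output example pairs (typically
4–32) and adapts to the task *in a single forward pass*, with no
retraining.

The architecture is an embedding layer, seven **Pairwise-Conv-Avg blocks**
in a U-shaped encoder/decoder, and an output convolution. In each block the
target and every context pair pass through residual units (context-in and
context-out share weights), each pair is concatenated with the target and
reduced by a 1×1 convolution, and the target is updated as the *mean over
pairs* — making the network exactly invariant to context order and
duplication, hence to context-set size. Training uses Adam with a sliding
window of 4 context pairs; inference uses a static context of the first 16
training pairs. Losses: MSE, SSIM dissimilarity (1 − SSIM), and the Alpha
loss (1 − α)·MSE + α·(1 − SSIM) with α = 0.84.

The package is self-contained:

* **Simulator** — ring / semicircle / multi-segment / linear transducer
  geometries, an idealized arc-integral forward model, delay-and-sum
  backprojection (which reproduces the streak phenomenology), and grouped
  ("patient"-wise) train/val/test dataset bundles, all pure functions of a
  seed.
* **Models** — the context-conditioned network plus a plain U-net baseline
  (ELU activations, optional scaled-RMSE loss), both running on a small
  built-in reverse-mode differentiation engine with compiled convolution
  kernels (no external deep-learning framework).
* **Statistics** — SSIM / RMSE / PSNR, a Sobel-based edge-sensitivity
  ratio, per-dataset improvement tables, positive-fraction summaries, and
  paired t-tests.

## Worked example

Simulate a sparse-ring dataset, train the network at desk scale, and score
the held-out reconstructions (a few minutes on one CPU):

```r
library(paomninet)

task <- list(kind = "ring", n_sparse = 16L, n_dense = 256L)
ds <- build_dataset(n_items = 45, n_groups = 9, task = task,
                    split_fractions = c(0.6, 0.2, 0.2),
                    seed = 42, grid_size = 32)
ds
#> <pa_dataset> 45 pairs (ring-16), 9 groups, splits train/val/test = 25/10/10

fit <- fit_model(ds, model = "omninet",
                 config = omninet_config(base_channels = 4, seed = 1),
                 control = train_control(loss = "mse", learning_rate = 2e-3,
                                         max_epochs = 30, patience = 8,
                                         batch_size = 2, context_size = 2,
                                         context_size_test = 8, seed = 1))
fit
#> <pa_fit> omninet, 108253 parameters, trained 30 epochs (best 29, val loss 0.00209)

test_pairs <- ds$pairs[ds$split$test]
recon <- predict(fit, test_pairs)   # static first-8 training pairs as context
metric_report(lapply(test_pairs, `[[`, "input"),
              lapply(test_pairs, `[[`, "target"),
              dataset = "ring-16", model = "input")
#> <pa_metric_report> ring-16 [input] n=10  SSIM 0.7761  RMSE 0.0774  PSNR 22.34 dB
rep_model <- metric_report(recon, lapply(test_pairs, `[[`, "target"),
                           dataset = "ring-16", model = "omninet")
rep_model
#> <pa_metric_report> ring-16 [omninet] n=10  SSIM 0.8838  RMSE 0.0378  PSNR 28.58 dB
```

The 16-element inputs score SSIM 0.776 against the 256-element ground
truth; the network's reconstructions reach SSIM 0.884, halve the RMSE and
gain 6.2 dB PSNR — the streaks are removed while the absorbers are kept.
`context_identifiability_experiment()` runs the companion mechanism study:
the same jointly trained model scores higher with the matching task's
context than with a mismatched one, and a same-task context from a
different patient group costs far less than a wrong-task context.

A thin command-line front end (`inst/cli/paomninet.R`) exposes
`simulate`, `describe`, `train`, `infer`, `evaluate` and `report`
subcommands over the same functions.

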