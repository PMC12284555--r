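# ---------------------------------------------------------------------------
# Study harnesses built from the simulator + models: the sparsity/quality
# curve, streak-periodicity analysis, and the context-identifiability
# experiment (does conditioning on the matching task's context help?).
# ---------------------------------------------------------------------------

#' Mean reconstruction quality versus element count
#'
#' Simulates `n_scenes` seeded phantoms and reports, per sparsity level,
#' the mean SSIM between the delay-and-sum reconstruction at that element
#' count and the densely sampled ground truth. Quality should grow with
#' the element count as streak artifacts fill in.
#'
#' @param n_scenes Number of seeded scenes (>= 20 for stable means).
#' @param levels Sparse element counts to evaluate.
#' @param n_dense Dense (ground-truth) element count.
#' @param kind Geometry kind.
#' @param grid_size Image side length in pixels.
#' @param seed Integer seed.
#' @return Data frame with `n_elements` and `mean_ssim`.
#' @export
sparsity_quality_curve <- function(n_scenes = 20L,
                                   levels = c(16L, 32L, 64L, 128L),
                                   n_dense = 256L, kind = "ring",
                                   grid_size = 64L, seed = 1L) {
  dense <- make_geometry(kind, n_dense)
  sparse <- lapply(levels, function(k) subsample_elements(dense, k))
  scenes <- with_seed(seed, lapply(seq_len(n_scenes), function(i)
    random_scene(grid_size)))
  acc <- matrix(0, n_scenes, length(levels))
  for (i in seq_len(n_scenes)) {
    sino <- forward_project(scenes[[i]], dense,
                            n_time_bins = default_time_bins(grid_size))
    gt <- das_reconstruct(sino, dense, grid_size)
    for (j in seq_along(levels)) {
      sp <- sparse[[j]]
      sps <- structure(list(data = sino$data[sp$kept_idx, , drop = FALSE],
                            n_elements = sp$n_elements,
                            n_time_bins = sino$n_time_bins,
                            dr = sino$dr, sound_speed = 1),
                       class = "pa_sinogram")
      acc[i, j] <- ssim(das_reconstruct(sps, sp, grid_size), gt)
    }
  }
  data.frame(n_elements = levels, mean_ssim = colMeans(acc))
}

#' Angular intensity profile at a fixed radius
#'
#' Bilinearly samples an image on a circle around the grid centre;
#' used to count streaks in sparse-ring reconstructions.
#'
#' @param image Numeric matrix.
#' @param radius Sampling radius in normalized field-of-view units.
#' @param n_angles Number of samples on the circle.
#' @export
angular_profile <- function(image, radius = 0.5, n_angles = 720L) {
  x <- as_mat(image)
  H <- nrow(x); W <- ncol(x)
  th <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  px <- radius * cos(th)
  py <- radius * sin(th)
  # invert the pixel-centre mapping (y axis up)
  cj <- (px + 1) * W / 2 + 0.5
  ci <- (1 - py) * H / 2 + 0.5
  j0 <- pmin(pmax(floor(cj), 1L), W - 1L)
  i0 <- pmin(pmax(floor(ci), 1L), H - 1L)
  fj <- cj - j0
  fi <- ci - i0
  x[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    x[cbind(i0 + 1L, j0)] * fi * (1 - fj) +
    x[cbind(i0, j0 + 1L)] * (1 - fi) * fj +
    x[cbind(i0 + 1L, j0 + 1L)] * fi * fj
}

#' Dominant angular frequency of a profile
#'
#' Index (cycles per revolution) of the largest Fourier magnitude of the
#' mean-removed profile; an n-element ring imaging a centred point gives a
#' profile whose energy sits on multiples of n.
#'
#' @param profile Numeric vector from [angular_profile()].
#' @export
dominant_angular_frequency <- function(profile) {
  n <- length(profile)
  sp <- Mod(stats::fft(profile - mean(profile)))[2:(n %/% 2L)]
  which.max(sp)
}

#' Context-identifiability experiment
#'
#' Trains one context-conditioned network jointly on two synthetic
#' degradation tasks and measures, on held-out test images, whether
#' conditioning with the matching task's context yields higher SSIM than
#' (a) a context from the same task but a different (held-out) group and
#' (b) a context from the other task. The experiment is repeated over
#' several seeds and pooled per-image matched-minus-mismatched SSIM
#' differences are tested with a one-sided paired t-test.
#'
#' Defaults are desk-scale study conditions: 32x32 images, 4 base
#' channels, ring-16 and multisegment-32 degradations, 45 items in 9
#' groups per task (25 train / 10 val / 10 test), training context 2 and
#' test context 8.
#'
#' @param seeds Integer vector of experiment seeds (>= 3 for the pooled
#'   test).
#' @param tasks List of two task descriptors (`kind`, `n_sparse`,
#'   `n_dense`).
#' @param n_items,n_groups Per-task dataset size and group count.
#' @param grid_size Image side length (divisible by 8).
#' @param base_channels Network width.
#' @param context_size_train,context_size_test Context sizes.
#' @param max_epochs,patience,batch_size,learning_rate Training scale.
#' @param verbose Print training progress.
#' @return A `pa_context_experiment`: pooled per-image SSIMs under the
#'   three contexts, per-seed means, and the one-sided paired t-test of
#'   matched vs mismatched.
#' @export
context_identifiability_experiment <- function(
    seeds = 1:3,
    tasks = list(list(kind = "ring", n_sparse = 16L, n_dense = 256L),
                 list(kind = "multisegment", n_sparse = 32L,
                      n_dense = 256L)),
    n_items = 45L, n_groups = 9L, grid_size = 32L, base_channels = 4L,
    context_size_train = 2L, context_size_test = 8L, max_epochs = 40L,
    patience = 10L, batch_size = 2L, learning_rate = 2e-3,
    verbose = FALSE) {
  stopifnot(length(tasks) == 2L)
  pooled <- list()
  per_seed <- list()
  for (seed in seeds) {
    bundles <- lapply(seq_along(tasks), function(t)
      build_dataset(n_items, n_groups, tasks[[t]],
                    split_fractions = c(0.6, 0.2, 0.2),
                    seed = seed * 101L + 37L * t, grid_size = grid_size))
    train <- c(dataset_pairs(bundles[[1L]], "train"),
               dataset_pairs(bundles[[2L]], "train"))
    val <- c(dataset_pairs(bundles[[1L]], "val"),
             dataset_pairs(bundles[[2L]], "val"))
    fit <- fit_model(list(train = train, val = val), model = "omninet",
                     config = omninet_config(base_channels = base_channels,
                                             seed = seed),
                     control = train_control(
                       loss = "mse", learning_rate = learning_rate,
                       max_epochs = max_epochs, patience = patience,
                       batch_size = batch_size,
                       context_size = context_size_train,
                       context_size_test = context_size_test,
                       seed = seed, verbose = verbose))
    rows <- list()
    for (t in 1:2) {
      test_pairs <- dataset_pairs(bundles[[t]], "test")
      ctx_matched <- static_context(dataset_pairs(bundles[[t]], "train"),
                                    context_size_test)
      ctx_other_group <- static_context(dataset_pairs(bundles[[t]], "val"),
                                        context_size_test)
      ctx_mismatched <- static_context(
        dataset_pairs(bundles[[if (t == 1L) 2L else 1L]], "train"),
        context_size_test)
      s <- function(ctx) {
        preds <- predict(fit, test_pairs, context = ctx)
        vapply(seq_along(preds), function(i)
          ssim(preds[[i]], test_pairs[[i]]$target), numeric(1))
      }
      rows[[t]] <- data.frame(seed = seed, task = task_label(tasks[[t]]),
                              matched = s(ctx_matched),
                              other_group = s(ctx_other_group),
                              mismatched = s(ctx_mismatched))
    }
    df <- do.call(rbind, rows)
    pooled[[length(pooled) + 1L]] <- df
    per_seed[[as.character(seed)]] <-
      colMeans(df[c("matched", "other_group", "mismatched")])
  }
  pooled <- do.call(rbind, pooled)
  tt <- stats::t.test(pooled$matched, pooled$mismatched, paired = TRUE,
                      alternative = "greater")
  structure(list(
    pooled = pooled,
    per_seed = do.call(rbind, per_seed),
    means = colMeans(pooled[c("matched", "other_group", "mismatched")]),
    t = unname(tt$statistic), p = tt$p.value, n = nrow(pooled)),
    class = "pa_context_experiment")
}

#' @export
print.pa_context_experiment <- function(x, ...) {
  cat(sprintf(
    "<pa_context_experiment> n = %d paired images over %d seeds\n",
    x$n, nrow(x$per_seed)))
  cat(sprintf("  mean SSIM: matched %.4f | same task, other group %.4f | mismatched task %.4f\n",
              x$means["matched"], x$means["other_group"],
              x$means["mismatched"]))
  cat(sprintf("  matched > mismatched: one-sided paired t = %.3f, p = %.2g\n",
              x$t, x$p))
  invisible(x)
}
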