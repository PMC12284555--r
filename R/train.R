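# ---------------------------------------------------------------------------
# Training loop (Adam, sliding-window context assembly, early stopping on
# validation loss) and the static-context inference protocol. One harness
# serves both models; the only difference is whether context inputs are
# assembled and fed to the forward pass.
# ---------------------------------------------------------------------------

#' Training control parameters
#'
#' Defaults follow the reference protocol: Adam with learning rate 1e-4,
#' at most 500 epochs with early stopping on validation loss, a sliding
#' training-context window of 4 pairs and a static test context of the
#' first 16 training pairs. Scale them down for desk-size experiments.
#'
#' @param loss `"mse"`, `"alpha"`, `"ssim"` or `"srmse"`.
#' @param alpha Mixing weight of the alpha loss (default 0.84).
#' @param learning_rate Adam step size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs (stop after this many
#'   consecutive epochs without a new validation-loss minimum).
#' @param batch_size Mini-batch size (gradients averaged per batch).
#' @param context_size Sliding-window context size during training.
#' @param context_size_test Static context size at inference.
#' @param srmse_scale Intensity scale of the scaled-RMSE loss.
#' @param ssim_params SSIM parameters used by SSIM-based losses.
#' @param seed Seed controlling shuffling (weights carry their own seed).
#' @param verbose Print per-epoch losses.
#' @export
train_control <- function(loss = c("mse", "alpha", "ssim", "srmse"),
                          alpha = 0.84, learning_rate = 1e-4,
                          max_epochs = 500L, patience = 20L,
                          batch_size = 8L, context_size = 4L,
                          context_size_test = 16L, srmse_scale = 255,
                          ssim_params = paomninet::ssim_params(),
                          seed = 1L, verbose = FALSE) {
  loss <- match.arg(loss)
  stopifnot(learning_rate > 0, max_epochs >= 1L, patience >= 1L,
            batch_size >= 1L, context_size >= 1L, context_size_test >= 1L,
            alpha >= 0, alpha <= 1)
  structure(list(loss = loss, alpha = alpha,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 context_size = as.integer(context_size),
                 context_size_test = as.integer(context_size_test),
                 srmse_scale = srmse_scale, ssim_params = ssim_params,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

#' Sliding-window context for a training item
#'
#' The context of the pair at `index` (1-based) is the next `window`
#' pairs in dataset order, wrapping modulo the dataset size, so the window
#' size is constant and the target pair is never its own context.
#'
#' @param pairs Ordered list of image pairs.
#' @param index 1-based index of the target pair.
#' @param window Context size (dataset must hold more than `window`
#'   pairs).
#' @return List of `window` image pairs.
#' @export
sliding_context <- function(pairs, index, window = 4L) {
  n <- length(pairs)
  window <- as.integer(window)
  stopifnot(window >= 1L, index >= 1L, index <= n)
  if (n <= window)
    stop("dataset must contain more than 'window' pairs", call. = FALSE)
  pairs[((index - 1L + seq_len(window)) %% n) + 1L]
}

#' Static inference context: first k training pairs
#'
#' @param pairs Ordered list of training pairs.
#' @param k Context size.
#' @export
static_context <- function(pairs, k = 16L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (length(pairs) < k)
    stop("training data holds fewer than k pairs", call. = FALSE)
  pairs[seq_len(k)]
}

#' Early-stopping trace over a validation-loss sequence
#'
#' Pure helper implementing the stopping rule: the best epoch is the first
#' minimum of the sequence; training stops after `patience` consecutive
#' epochs without improvement (or at the end of the sequence).
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return List with `best_epoch` and `stop_epoch`.
#' @export
early_stop_trace <- function(val_losses, patience) {
  best <- Inf
  best_epoch <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
    } else if (e - best_epoch >= patience) {
      return(list(best_epoch = best_epoch, stop_epoch = e))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(val_losses))
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# context provider: per-task ordered training lists so sliding windows stay
# within the target's own task
make_context_provider <- function(train_pairs, window) {
  tasks <- vapply(train_pairs, function(p)
    if (is.null(p$meta$task)) "task" else p$meta$task, character(1))
  by_task <- split(seq_along(train_pairs), tasks)
  within_idx <- integer(length(train_pairs))
  for (ids in by_task) within_idx[ids] <- seq_along(ids)
  function(i) {
    ids <- by_task[[tasks[i]]]
    # clamp so degenerate tiny splits still get a valid (smaller) window
    w <- min(window, length(ids) - 1L)
    sliding_context(train_pairs[ids], within_idx[i], w)
  }
}

sample_loss_tape <- function(model, params, config, pair, context, control,
                             track) {
  tp <- new_tape()
  pid <- push_params(tp, params, track = track)
  d <- dim(pair$input)
  xin <- tp_const(tp, array(pair$input, c(d, 1L)))
  tgt <- tp_const(tp, array(pair$target, c(d, 1L)))
  out <- if (model == "omninet") {
    cin <- lapply(context, function(p)
      tp_const(tp, array(p$input, c(d, 1L))))
    cout <- lapply(context, function(p)
      tp_const(tp, array(p$target, c(d, 1L))))
    omninet_tape_forward(tp, pid, xin, cin, cout, config)
  } else {
    unet_tape_forward(tp, pid, xin, config)
  }
  loss <- tp_training_loss(tp, out, tgt, control)
  list(tp = tp, pid = pid, loss = loss)
}

accumulate_grads <- function(acc, gr, pid) {
  for (nm in names(pid)) {
    g <- gr[[pid[[nm]]]]
    if (is.null(g)) next
    acc[[nm]] <- if (is.null(acc[[nm]])) g else acc[[nm]] + g
  }
  acc
}

#' Fit a reconstruction model
#'
#' Trains the context-conditioned network or the baseline U-net on a
#' paired dataset with Adam, assembling each training item's context by
#' the sliding-window rule (within the item's own task for multi-task
#' data), evaluating the validation loss under the same protocol each
#' epoch, and keeping the weights of the epoch with the lowest validation
#' loss (early stopping). Fully reproducible from the config and control
#' seeds.
#'
#' @param data A `pa_dataset` from [build_dataset()], or a list with
#'   `$train` and `$val` lists of image pairs.
#' @param model `"omninet"` (context-conditioned) or `"unet"` (baseline).
#' @param config An [omninet_config()] or [unet_config()]; sensible small
#'   defaults are derived from the data when omitted.
#' @param control A [train_control()].
#' @return An object of class `pa_fit` with elements `params` (best
#'   weights), `history` (per-epoch train/val losses), `best_epoch`,
#'   `config`, `control`, `model` and `train_pairs` (kept for context
#'   assembly at prediction time).
#' @export
fit_model <- function(data, model = c("omninet", "unet"), config = NULL,
                      control = train_control()) {
  model <- match.arg(model)
  stopifnot(inherits(control, "train_control"))
  if (inherits(data, "pa_dataset")) {
    train_pairs <- dataset_pairs(data, "train")
    val_pairs <- dataset_pairs(data, "val")
  } else {
    train_pairs <- data$train
    val_pairs <- data$val
  }
  if (length(train_pairs) == 0L || length(val_pairs) == 0L)
    stop("training and validation splits must be nonempty", call. = FALSE)
  if (is.null(config))
    config <- if (model == "omninet") omninet_config(base_channels = 8L)
  else unet_config(depth = 3L, base_channels = 8L)
  params <- if (model == "omninet") omninet_init(config) else
    unet_init(config)
  ctx_of <- make_context_provider(train_pairs, control$context_size)
  val_ctx_of <- local({
    # validation uses the training protocol: sliding window over the
    # validation split itself (within task)
    make_context_provider(val_pairs, control$context_size)
  })
  opt <- adam_new(params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_epoch <- 0L
  best_params <- params
  n <- length(train_pairs)
  with_seed(control$seed, {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      tr_loss <- 0
      for (batch in batches) {
        gacc <- list()
        for (i in batch) {
          st <- sample_loss_tape(model, params, config, train_pairs[[i]],
                                 if (model == "omninet") ctx_of(i),
                                 control, track = TRUE)
          lv <- tp_val(st$tp, st$loss)
          if (!is.finite(lv))
            stop(sprintf(
              "non-finite training loss (%g) at epoch %d item %d; try a smaller learning rate",
              lv, epoch, i), call. = FALSE)
          tr_loss <- tr_loss + lv
          gr <- tp_backward(st$tp, st$loss)
          gacc <- accumulate_grads(gacc, gr, st$pid)
        }
        gacc <- lapply(gacc, function(g) g / length(batch))
        upd <- adam_step(params, gacc, opt, control$learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      tr_loss <- tr_loss / n
      vl <- 0
      for (j in seq_along(val_pairs)) {
        st <- sample_loss_tape(model, params, config, val_pairs[[j]],
                               if (model == "omninet") val_ctx_of(j),
                               control, track = FALSE)
        vl <- vl + tp_val(st$tp, st$loss)
      }
      vl <- vl / length(val_pairs)
      history[epoch, ] <- list(epoch, tr_loss, vl)
      if (control$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, tr_loss,
                        vl))
      if (vl < best_val) {
        best_val <- vl
        best_epoch <- epoch
        best_params <- params
      } else if (epoch - best_epoch >= control$patience) break
    }
  })
  structure(list(model = model, params = best_params, config = config,
                 control = control, history = history,
                 best_epoch = best_epoch, best_val = best_val,
                 train_pairs = train_pairs),
            class = "pa_fit")
}

forward_any <- function(fit, input, context) {
  if (fit$model == "omninet")
    omninet_forward(fit$params, input, context, fit$config)
  else unet_forward(fit$params, input, fit$config)
}

#' Predict reconstructions from a fitted model
#'
#' Runs the fitted network on new sparse inputs. For the
#' context-conditioned model the context defaults to the static first-k
#' training pairs (`control$context_size_test`); outputs are clipped to
#' \[0, 1\].
#'
#' @param object A `pa_fit`.
#' @param newdata List of input matrices or of image pairs.
#' @param context Optional context set (list of pairs); defaults to
#'   [static_context()] over the fit's training pairs.
#' @param clip Clip outputs to \[0, 1\] (default TRUE).
#' @param ... Unused.
#' @return List of reconstructed matrices.
#' @export
predict.pa_fit <- function(object, newdata, context = NULL, clip = TRUE,
                           ...) {
  inputs <- lapply(newdata, function(p)
    if (is.list(p) && !is.null(p$input)) p$input else p)
  if (object$model == "omninet" && is.null(context))
    context <- static_context(object$train_pairs,
                              min(object$control$context_size_test,
                                  length(object$train_pairs)))
  lapply(inputs, function(x) {
    y <- forward_any(object, x, context)
    if (clip) pmin(pmax(y, 0), 1) else y
  })
}

#' Reconstruct a batch of images with a fixed context set
#'
#' Thin wrapper over [predict.pa_fit()] exposing the inference protocol
#' explicitly: every input is accompanied by the same static context set.
#'
#' @param fit A `pa_fit`.
#' @param inputs List of input matrices or image pairs.
#' @param context Context set (list of pairs); required for the
#'   context-conditioned model unless the default static context applies.
#' @export
infer <- function(fit, inputs, context = NULL) {
  predict(fit, inputs, context = context)
}

#' @export
print.pa_fit <- function(x, ...) {
  cat(sprintf("<pa_fit> %s, %d parameters, trained %d epochs (best %d, val loss %.5f)\n",
              x$model, sum(lengths(x$params)), nrow(x$history),
              x$best_epoch, x$best_val))
  invisible(x)
}

#' @export
summary.pa_fit <- function(object, ...) {
  cat(sprintf("Model: %s (%s loss)\n", object$model, object$control$loss))
  cat(sprintf("Parameters: %d\n", sum(lengths(object$params))))
  cat(sprintf("Epochs run: %d, best epoch %d (val loss %.5f)\n",
              nrow(object$history), object$best_epoch, object$best_val))
  cat(sprintf("Final train loss: %.5f\n",
              utils::tail(object$history$train_loss, 1L)))
  invisible(object)
}

#' @export
coef.pa_fit <- function(object, ...) object$params

#' @export
plot.pa_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted model checkpoint
#'
#' The checkpoint bundles the config snapshot and named parameter arrays;
#' the loader validates that parameter shapes agree with the config.
#'
#' @param fit A `pa_fit`.
#' @param path File path.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "pa_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "pa_fit"))
  ref <- if (fit$model == "omninet") omninet_init(fit$config) else
    unet_init(fit$config)
  if (!identical(lapply(ref, dim2), lapply(fit$params, dim2)))
    stop("checkpoint parameter shapes disagree with its config",
         call. = FALSE)
  fit
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)

#' Evaluate a fit across context sizes
#'
#' Reconstructs the test pairs with the first `k` pairs of `context_pool`
#' for each requested size and reports aggregate metrics per size.
#'
#' @param fit A `pa_fit` for the context-conditioned model.
#' @param test_pairs List of image pairs to evaluate.
#' @param context_pool Ordered list of pairs the contexts are drawn from.
#' @param sizes Integer vector of context sizes.
#' @return Data frame with one row per size (ssim/rmse/psnr means).
#' @export
context_size_sweep <- function(fit, test_pairs, context_pool,
                               sizes = c(1L, 2L, 4L, 8L, 16L, 32L)) {
  stopifnot(max(sizes) <= length(context_pool))
  rows <- lapply(sizes, function(k) {
    rep <- evaluate_pairs(fit, test_pairs,
                          context = static_context(context_pool, k))
    cbind(data.frame(context_size = k), as.data.frame(as.list(
      rep$aggregate)))
  })
  do.call(rbind, rows)
}

#' Evaluate a fit under alternative context sets
#'
#' @param fit A `pa_fit`.
#' @param test_pairs List of image pairs.
#' @param contexts Nonempty named list of context sets.
#' @return Data frame, one row of aggregate metrics per context.
#' @export
context_swap <- function(fit, test_pairs, contexts) {
  if (!is.list(contexts) || length(contexts) == 0L)
    stop("'contexts' must be a nonempty list of context sets",
         call. = FALSE)
  nm <- names(contexts)
  if (is.null(nm)) nm <- paste0("context", seq_along(contexts))
  rows <- lapply(seq_along(contexts), function(i) {
    rep <- evaluate_pairs(fit, test_pairs, context = contexts[[i]])
    cbind(data.frame(context = nm[i]),
          as.data.frame(as.list(rep$aggregate)))
  })
  do.call(rbind, rows)
}

# reconstruct pairs and score against their targets
evaluate_pairs <- function(fit, pairs, context = NULL) {
  preds <- predict(fit, pairs, context = context)
  metric_report(preds, lapply(pairs, `[[`, "target"),
                model = fit$model)
}
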