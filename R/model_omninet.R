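# ---------------------------------------------------------------------------
# Context-conditioned reconstruction network (PA OmniNet architecture).
#
# One shared 3x3 embedding, seven Pairwise-Conv-Avg blocks in a U-shaped
# layout (3 encoder / 1 bottleneck / 3 decoder, factor-2 resizes), and an
# output convolution. Each block processes the target stream and every
# context input/output pair through residual units (context-in and
# context-out share weights), concatenates [target', in'_k, out'_k] per
# pair, reduces with a 1x1 convolution, and updates the target by
# averaging over pairs -- making the whole network exactly invariant to
# context-order permutation and context duplication. Channels double per
# down-resize (capped at 8x base); target-stream skip connections join
# encoder features to decoder features through 1x1 reductions.
# ---------------------------------------------------------------------------

#' Configuration of the context-conditioned network
#'
#' @param base_channels Channels after the embedding (level 0).
#' @param channel_multiplier Per-level channel multipliers for the four
#'   resolution levels (default doubling, capped at 8x).
#' @param kernel_size Spatial kernel of the embedding/residual/output
#'   convolutions.
#' @param activation Activation inside residual units: `"lrelu"`
#'   (LeakyReLU, default) or `"elu"`.
#' @param lrelu_slope Negative-side slope of the LeakyReLU.
#' @param shared_embedding Share the embedding convolution between the
#'   target and both context streams (default) or give the context streams
#'   their own.
#' @param seed Seed for weight initialization.
#' @export
omninet_config <- function(base_channels = 32L,
                           channel_multiplier = c(1L, 2L, 4L, 8L),
                           kernel_size = 3L,
                           activation = c("lrelu", "elu"),
                           lrelu_slope = 0.01,
                           shared_embedding = TRUE,
                           seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(base_channels >= 1L, length(channel_multiplier) == 4L,
            all(channel_multiplier >= 1L), kernel_size %% 2L == 1L)
  ch <- as.integer(base_channels * pmin(channel_multiplier,
                                        8L * channel_multiplier[1L]))
  structure(list(base_channels = as.integer(base_channels),
                 channels = ch, n_blocks = 7L,
                 kernel_size = as.integer(kernel_size),
                 activation = activation, lrelu_slope = lrelu_slope,
                 shared_embedding = isTRUE(shared_embedding),
                 seed = as.integer(seed)),
            class = "omninet_config")
}

# per-block (cin, cout, resize) schedule for the fixed 3-1-3 layout
omninet_schedule <- function(config) {
  ch <- config$channels
  list(cin = c(ch[1L], ch[2L], ch[3L], ch[4L], ch[4L], ch[3L], ch[2L]),
       cout = c(ch[2L], ch[3L], ch[4L], ch[4L], ch[3L], ch[2L], ch[1L]),
       resize = c("down", "down", "down", "none", "up", "up", "up"))
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

conv_par <- function(k, cin, cout) {
  list(w = he_init(k * k * cin, cout, k * k * cin), b = numeric(cout))
}

#' Initialize network parameters
#'
#' He-initialized weights, fully determined by `config$seed`.
#'
#' @param config An [omninet_config()].
#' @return Named list of weight matrices and bias vectors.
#' @export
omninet_init <- function(config) {
  stopifnot(inherits(config, "omninet_config"))
  k <- config$kernel_size
  sch <- omninet_schedule(config)
  with_seed(config$seed, {
    par <- list()
    add <- function(name, p) {
      par[[paste0(name, ".w")]] <<- p$w
      par[[paste0(name, ".b")]] <<- p$b
    }
    add("embed", conv_par(k, 1L, config$channels[1L]))
    if (!config$shared_embedding)
      add("embed_ctx", conv_par(k, 1L, config$channels[1L]))
    for (l in 1:7) {
      ci <- sch$cin[l]; co <- sch$cout[l]
      add(sprintf("b%d.rt1", l), conv_par(k, ci, ci))
      add(sprintf("b%d.rt2", l), conv_par(k, ci, ci))
      add(sprintf("b%d.rc1", l), conv_par(k, ci, ci))
      add(sprintf("b%d.rc2", l), conv_par(k, ci, ci))
      add(sprintf("b%d.pw", l), conv_par(1L, 3L * ci, co))
      if (l < 7L)  # the last block's context streams feed nothing further
        add(sprintf("b%d.ct", l), conv_par(1L, ci, co))
    }
    for (j in 1:3)
      add(sprintf("skip%d", j),
          conv_par(1L, 2L * config$channels[j], config$channels[j]))
    # damp the initial output scale so early optimization is not spent
    # shrinking activations accumulated through the residual stack
    outp <- conv_par(k, config$channels[1L], 1L)
    outp$w <- outp$w * 0.1
    add("out", outp)
    par
  })
}

#' Closed-form parameter count
#'
#' Number of trainable scalars as a function of the configuration alone
#' (kernel size k, per-block channel schedule ci -> co): embedding
#' k^2*1*C+C, per block two target and two shared-context residual convs
#' (each k^2*ci^2 + ci), a 3ci -> co pairwise 1x1 and a ci -> co context
#' transition 1x1, three 2C_j -> C_j skip reducers, and the output conv.
#'
#' @param config An [omninet_config()].
#' @export
omninet_param_count <- function(config) {
  k <- config$kernel_size
  sch <- omninet_schedule(config)
  C <- config$channels[1L]
  n <- k * k * C + C                        # embedding
  if (!config$shared_embedding) n <- 2L * n
  for (l in 1:7) {
    ci <- sch$cin[l]; co <- sch$cout[l]
    n <- n + 4L * (k * k * ci * ci + ci)    # two residual units, 2 convs each
    n <- n + (3L * ci * co + co)            # pairwise 1x1
    if (l < 7L)
      n <- n + (ci * co + co)               # context transition 1x1
  }
  for (j in 1:3) {
    cj <- config$channels[j]
    n <- n + 2L * cj * cj + cj              # skip reducer
  }
  n + k * k * C + 1L                        # output conv
}

tp_activation <- function(tp, x, config) {
  if (config$activation == "elu") tp_elu(tp, x)
  else tp_lrelu(tp, x, config$lrelu_slope)
}

# residual unit: x + conv2(act(conv1(x)))
tp_residual_unit <- function(tp, x, pid, name, config) {
  k <- config$kernel_size
  h <- tp_conv2d(tp, x, pid[[paste0(name, "1.w")]],
                 pid[[paste0(name, "1.b")]], k)
  h <- tp_activation(tp, h, config)
  h <- tp_conv2d(tp, h, pid[[paste0(name, "2.w")]],
                 pid[[paste0(name, "2.b")]], k)
  tp_add(tp, x, h)
}

# one Pairwise-Conv-Avg block; state = list(target, ctx_in, ctx_out) of ids
tp_pairwise_block <- function(tp, state, l, pid, config, resize,
                              update_context = TRUE) {
  tgt <- tp_residual_unit(tp, state$target, pid, sprintf("b%d.rt", l),
                          config)
  cin <- lapply(state$ctx_in, tp_residual_unit, tp = tp, pid = pid,
                name = sprintf("b%d.rc", l), config = config)
  cout <- lapply(state$ctx_out, tp_residual_unit, tp = tp, pid = pid,
                 name = sprintf("b%d.rc", l), config = config)
  pw_w <- pid[[sprintf("b%d.pw.w", l)]]
  pw_b <- pid[[sprintf("b%d.pw.b", l)]]
  cand <- mapply(function(a, b) {
    tp_conv2d(tp, tp_concat_c(tp, c(tgt, a, b)), pw_w, pw_b, 1L, 1L, 0L)
  }, cin, cout, SIMPLIFY = TRUE)
  new_tgt <- tp_mean_list(tp, cand)
  if (!update_context)
    return(list(target = tp_resize(tp, new_tgt, resize)))
  ct_w <- pid[[sprintf("b%d.ct.w", l)]]
  ct_b <- pid[[sprintf("b%d.ct.b", l)]]
  trans <- function(x) tp_conv2d(tp, x, ct_w, ct_b, 1L, 1L, 0L)
  list(target = tp_resize(tp, new_tgt, resize),
       ctx_in = lapply(lapply(cin, trans), tp_resize, tp = tp,
                       mode = resize),
       ctx_out = lapply(lapply(cout, trans), tp_resize, tp = tp,
                        mode = resize))
}

check_context <- function(context, d) {
  if (!is.list(context) || length(context) == 0L)
    stop("context set must contain at least one input-output pair",
         call. = FALSE)
  for (p in context) {
    if (is.null(p$input) || is.null(p$target))
      stop("each context pair needs $input and $target", call. = FALSE)
    if (!all(dim(as_mat(p$input)) == d) || !all(dim(as_mat(p$target)) == d))
      stop("context images must be co-shaped with the target input",
           call. = FALSE)
  }
  invisible(TRUE)
}

# full forward pass as tape nodes; pid: named list of parameter node ids
omninet_tape_forward <- function(tp, pid, input_id, ctx_in_ids, ctx_out_ids,
                                 config) {
  k <- config$kernel_size
  emb_w <- pid[["embed.w"]]; emb_b <- pid[["embed.b"]]
  ce_w <- if (config$shared_embedding) emb_w else pid[["embed_ctx.w"]]
  ce_b <- if (config$shared_embedding) emb_b else pid[["embed_ctx.b"]]
  state <- list(
    target = tp_conv2d(tp, input_id, emb_w, emb_b, k),
    ctx_in = lapply(ctx_in_ids, function(i) tp_conv2d(tp, i, ce_w, ce_b, k)),
    ctx_out = lapply(ctx_out_ids, function(i) tp_conv2d(tp, i, ce_w, ce_b, k)))
  sch <- omninet_schedule(config)
  skips <- list()
  for (l in 1:3) {
    skips[[l]] <- state$target
    state <- tp_pairwise_block(tp, state, l, pid, config, sch$resize[l])
  }
  state <- tp_pairwise_block(tp, state, 4L, pid, config, "none")
  for (l in 5:7) {
    state <- tp_pairwise_block(tp, state, l, pid, config, sch$resize[l],
                               update_context = l < 7L)
    j <- 8L - l
    state$target <- tp_conv2d(tp, tp_concat_c(tp, c(state$target,
                                                    skips[[j]])),
                              pid[[sprintf("skip%d.w", j)]],
                              pid[[sprintf("skip%d.b", j)]], 1L, 1L, 0L)
  }
  tp_conv2d(tp, state$target, pid[["out.w"]], pid[["out.b"]], k)
}

push_params <- function(tp, params, track = TRUE) {
  lapply(params, function(p)
    if (track) tp_param(tp, p) else tp_const(tp, p))
}

validate_forward_input <- function(input) {
  x <- as_mat(input, "input")
  if (nrow(x) %% 8L != 0L || ncol(x) %% 8L != 0L)
    stop("input height and width must be divisible by 8 (three resizes)",
         call. = FALSE)
  x
}

#' Forward pass of the context-conditioned network
#'
#' Embeds the target image and every context pair, runs the seven
#' Pairwise-Conv-Avg blocks with target-stream skip connections, and maps
#' back to a single channel. Deterministic given weights; exactly
#' invariant to context-pair order and duplication.
#'
#' @param params Parameter list from [omninet_init()] (or a fitted model's
#'   `$params`).
#' @param input H x W numeric matrix, H and W divisible by 8.
#' @param context List of input-output pairs (each with `$input`,
#'   `$target`) co-shaped with `input`.
#' @param config The [omninet_config()] the parameters were built with.
#' @return H x W numeric matrix.
#' @export
omninet_forward <- function(params, input, context, config) {
  x <- validate_forward_input(input)
  check_context(context, dim(x))
  tp <- new_tape()
  pid <- push_params(tp, params, track = FALSE)
  xin <- tp_const(tp, array(x, c(dim(x), 1L)))
  cin <- lapply(context, function(p)
    tp_const(tp, array(as_mat(p$input), c(dim(x), 1L))))
  cout <- lapply(context, function(p)
    tp_const(tp, array(as_mat(p$target), c(dim(x), 1L))))
  out <- omninet_tape_forward(tp, pid, xin, cin, cout, config)
  tp_val(tp, out)[, , 1L]
}

#' Describe the network for a given configuration
#'
#' Prints the per-block channel schedule, feature-map sizes and the total
#' parameter count.
#'
#' @param config An [omninet_config()].
#' @param H,W Input size used to report feature-map resolutions.
#' @export
omninet_describe <- function(config, H = 256L, W = H) {
  sch <- omninet_schedule(config)
  cat(sprintf("Context-conditioned network: embedding (1 -> %d), 7 blocks, output conv\n",
              config$channels[1L]))
  h <- H; w <- W
  for (l in 1:7) {
    cat(sprintf("  block %d: %3d -> %3d channels at %dx%d, resize %s\n",
                l, sch$cin[l], sch$cout[l], h, w, sch$resize[l]))
    if (sch$resize[l] == "down") { h <- h %/% 2L; w <- w %/% 2L }
    if (sch$resize[l] == "up") { h <- h * 2L; w <- w * 2L }
  }
  cat(sprintf("  parameters: %d\n", omninet_param_count(config)))
  invisible(omninet_param_count(config))
}
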