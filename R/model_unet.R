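# ---------------------------------------------------------------------------
# Plain encoder-decoder U-net benchmark: two 3x3 convs per level with ELU
# activations, factor-2 average-pool downsizing, bilinear upsizing with
# skip concatenation, 1x1 output conv. Trained under the same losses and
# harness as the context-conditioned network; it simply ignores context.
# ---------------------------------------------------------------------------

#' Configuration of the baseline U-net
#'
#' @param depth Number of encoder levels (>= 2); input sides must be
#'   divisible by 2^depth.
#' @param base_channels Channels at the top level; doubled per level,
#'   capped at 8x.
#' @param activation `"elu"` (default) or `"lrelu"`.
#' @param lrelu_slope Negative-side slope when `activation = "lrelu"`.
#' @param srmse_scale Intensity scale of the optional scaled-RMSE loss.
#' @param seed Seed for weight initialization.
#' @export
unet_config <- function(depth = 4L, base_channels = 32L,
                        activation = c("elu", "lrelu"), lrelu_slope = 0.01,
                        srmse_scale = 255, seed = 1L) {
  activation <- match.arg(activation)
  depth <- as.integer(depth)
  stopifnot(depth >= 2L, base_channels >= 1L, srmse_scale > 0)
  ch <- as.integer(pmin(base_channels * 2^(0:depth), 8L * base_channels))
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 channels = ch, kernel_size = 3L, activation = activation,
                 lrelu_slope = lrelu_slope, srmse_scale = srmse_scale,
                 seed = as.integer(seed)),
            class = "unet_config")
}

#' Initialize U-net parameters
#'
#' @param config A [unet_config()].
#' @export
unet_init <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  k <- config$kernel_size
  ch <- config$channels
  d <- config$depth
  with_seed(config$seed, {
    par <- list()
    add <- function(name, p) {
      par[[paste0(name, ".w")]] <<- p$w
      par[[paste0(name, ".b")]] <<- p$b
    }
    for (i in seq_len(d)) {
      cin <- if (i == 1L) 1L else ch[i - 1L]
      add(sprintf("enc%d.c1", i), conv_par(k, cin, ch[i]))
      add(sprintf("enc%d.c2", i), conv_par(k, ch[i], ch[i]))
    }
    add("bott.c1", conv_par(k, ch[d], ch[d + 1L]))
    add("bott.c2", conv_par(k, ch[d + 1L], ch[d + 1L]))
    for (i in seq_len(d)) {
      cskip <- ch[i]
      cup <- if (i == d) ch[d + 1L] else ch[i + 1L]
      add(sprintf("dec%d.c1", i), conv_par(k, cskip + cup, ch[i]))
      add(sprintf("dec%d.c2", i), conv_par(k, ch[i], ch[i]))
    }
    add("out", conv_par(1L, ch[1L], 1L))
    par
  })
}

#' Closed-form U-net parameter count
#'
#' @param config A [unet_config()].
#' @export
unet_param_count <- function(config) {
  k <- config$kernel_size
  ch <- config$channels
  d <- config$depth
  cc <- function(kk, ci, co) kk * kk * ci * co + co
  n <- 0L
  for (i in seq_len(d)) {
    cin <- if (i == 1L) 1L else ch[i - 1L]
    n <- n + cc(k, cin, ch[i]) + cc(k, ch[i], ch[i])
  }
  n <- n + cc(k, ch[d], ch[d + 1L]) + cc(k, ch[d + 1L], ch[d + 1L])
  for (i in seq_len(d)) {
    cup <- if (i == d) ch[d + 1L] else ch[i + 1L]
    n <- n + cc(k, ch[i] + cup, ch[i]) + cc(k, ch[i], ch[i])
  }
  n + cc(1L, ch[1L], 1L)
}

unet_act <- function(tp, x, config) {
  if (config$activation == "elu") tp_elu(tp, x)
  else tp_lrelu(tp, x, config$lrelu_slope)
}

unet_double_conv <- function(tp, x, pid, name, config) {
  k <- config$kernel_size
  h <- unet_act(tp, tp_conv2d(tp, x, pid[[paste0(name, ".c1.w")]],
                              pid[[paste0(name, ".c1.b")]], k), config)
  unet_act(tp, tp_conv2d(tp, h, pid[[paste0(name, ".c2.w")]],
                         pid[[paste0(name, ".c2.b")]], k), config)
}

unet_tape_forward <- function(tp, pid, input_id, config) {
  d <- config$depth
  skips <- list()
  h <- input_id
  for (i in seq_len(d)) {
    h <- unet_double_conv(tp, h, pid, sprintf("enc%d", i), config)
    skips[[i]] <- h
    h <- tp_resize(tp, h, "down")
  }
  h <- unet_double_conv(tp, h, pid, "bott", config)
  for (i in rev(seq_len(d))) {
    h <- tp_resize(tp, h, "up")
    h <- tp_concat_c(tp, c(skips[[i]], h))
    h <- unet_double_conv(tp, h, pid, sprintf("dec%d", i), config)
  }
  tp_conv2d(tp, h, pid[["out.w"]], pid[["out.b"]], 1L, 1L, 0L)
}

#' Forward pass of the baseline U-net
#'
#' @param params Parameter list from [unet_init()].
#' @param input H x W numeric matrix with sides divisible by 2^depth.
#' @param config The [unet_config()] used to build `params`.
#' @return H x W numeric matrix.
#' @export
unet_forward <- function(params, input, config) {
  x <- as_mat(input, "input")
  if (nrow(x) %% 2L^config$depth != 0L || ncol(x) %% 2L^config$depth != 0L)
    stop(sprintf("input sides must be divisible by 2^depth = %d",
                 2L^config$depth), call. = FALSE)
  tp <- new_tape()
  pid <- push_params(tp, params, track = FALSE)
  xin <- tp_const(tp, array(x, c(dim(x), 1L)))
  out <- unet_tape_forward(tp, pid, xin, config)
  tp_val(tp, out)[, , 1L]
}
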