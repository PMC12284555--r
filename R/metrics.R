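# ---------------------------------------------------------------------------
# Image-quality statistics: MSE, RMSE, PSNR, SSIM, Sobel edge map, and the
# edge-sensitivity ratio used to compare model robustness across transducer
# counts. All functions take plain numeric matrices with intensities in
# [0, L] (L = 1 after the simulator's normalization).
# ---------------------------------------------------------------------------

as_mat <- function(x, arg = "image") {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 1L)
    x <- x[, , 1L]
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  x
}

check_pair <- function(x, y) {
  x <- as_mat(x, "x"); y <- as_mat(y, "y")
  if (!all(dim(x) == dim(y)))
    stop("images must have identical dimensions", call. = FALSE)
  list(x = x, y = y)
}

#' Mean squared error between two images
#'
#' @param x,y Numeric matrices of identical dimensions.
#' @return A scalar, the mean of squared pixel differences.
#' @export
mse <- function(x, y) {
  p <- check_pair(x, y)
  mean((p$x - p$y)^2)
}

#' Root mean squared error between two images
#'
#' @inheritParams mse
#' @return `sqrt(mse(x, y))`.
#' @export
rmse <- function(x, y) sqrt(mse(x, y))

#' Peak signal-to-noise ratio in decibels
#'
#' `20 * log10(max_val / rmse)`. Identical images return `Inf`.
#'
#' @inheritParams mse
#' @param max_val Peak intensity of the data range (1 for normalized images).
#' @export
psnr <- function(x, y, max_val = 1) {
  if (!is.numeric(max_val) || max_val <= 0)
    stop("'max_val' must be positive", call. = FALSE)
  r <- rmse(x, y)
  if (r == 0) return(Inf)
  20 * log10(max_val / r)
}

#' SSIM parameter set
#'
#' The reference defaults: an 11-tap Gaussian window with sigma 1.5,
#' stabilizers K1 = 0.01 and K2 = 0.03, dynamic range L = 1.
#'
#' @param window_size Odd window width in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @param K1,K2 Stabilizing constants.
#' @param L Dynamic range of the intensities.
#' @export
ssim_params <- function(window_size = 11L, sigma = 1.5, K1 = 0.01,
                        K2 = 0.03, L = 1) {
  stopifnot(window_size %% 2L == 1L, window_size >= 3L, sigma > 0, L > 0)
  structure(list(window_size = as.integer(window_size), sigma = sigma,
                 K1 = K1, K2 = K2, L = L), class = "ssim_params")
}

gaussian_kernel_1d <- function(size, sigma) {
  half <- (size - 1L) %/% 2L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

# banded matrix applying a 1-D kernel in "valid" mode: (n-k+1) x n
valid_filter_mat <- function(n, kern) {
  k <- length(kern)
  m <- matrix(0, n - k + 1L, n)
  for (i in seq_len(n - k + 1L))
    m[i, i:(i + k - 1L)] <- kern
  m
}

#' Structural similarity index
#'
#' Mean local SSIM over all valid positions of a Gaussian window
#' (luminance/contrast/structure comparison). Symmetric in its arguments;
#' `ssim(x, x)` is exactly 1.
#'
#' @inheritParams mse
#' @param params An [ssim_params()] object.
#' @return Scalar in \[-1, 1\].
#' @export
ssim <- function(x, y, params = ssim_params()) {
  p <- check_pair(x, y)
  x <- p$x; y <- p$y
  k <- params$window_size
  if (nrow(x) < k || ncol(x) < k)
    stop("image smaller than the SSIM window", call. = FALSE)
  g <- gaussian_kernel_1d(k, params$sigma)
  Fh <- valid_filter_mat(nrow(x), g)
  Fw <- valid_filter_mat(ncol(x), g)
  f <- function(z) Fh %*% z %*% t(Fw)
  mean(ssim_map_from_moments(f(x), f(y), f(x * x), f(y * y), f(x * y),
                             params))
}

ssim_map_from_moments <- function(mu_x, mu_y, exx, eyy, exy, params) {
  C1 <- (params$K1 * params$L)^2
  C2 <- (params$K2 * params$L)^2
  sx <- exx - mu_x^2
  sy <- eyy - mu_y^2
  sxy <- exy - mu_x * mu_y
  ((2 * mu_x * mu_y + C1) * (2 * sxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (sx + sy + C2))
}

sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
sobel_y <- t(sobel_x)

# 3x3 correlation with replicated borders (constant images stay flat)
conv3_same <- function(x, k) {
  xp <- x[c(1L, seq_len(nrow(x)), nrow(x)), c(1L, seq_len(ncol(x)),
                                              ncol(x))]
  cpp_conv2d(array(xp, c(nrow(xp), ncol(xp), 1L)),
             matrix(as.vector(t(k)), ncol = 1L),  # rows ordered (dy, dx)
             0, 3L, 3L, 0L)[, , 1L]
}

#' Sobel edge-magnitude map
#'
#' Gradient magnitude from 3x3 Sobel kernels, min-max normalized to
#' \[0, 1\]; a constant image maps to all zeros.
#'
#' @param image Numeric matrix.
#' @export
edge_map <- function(image) {
  x <- as_mat(image)
  gx <- conv3_same(x, sobel_x)
  gy <- conv3_same(x, sobel_y)
  normalize01(sqrt(gx^2 + gy^2))
}

normalize01 <- function(x) {
  r <- range(x)
  if (r[2L] > r[1L]) (x - r[1L]) / (r[2L] - r[1L]) else x * 0
}

#' Reconstruction triplet for the sensitivity statistic
#'
#' Bundles a sparse input `X`, a model reconstruction `N` and the ground
#' truth `Gt` for one transducer count.
#'
#' @param X,N,Gt Co-shaped numeric matrices.
#' @param n_elements Positive integer transducer-count tag.
#' @export
recon_triplet <- function(X, N, Gt, n_elements) {
  X <- as_mat(X, "X"); N <- as_mat(N, "N"); Gt <- as_mat(Gt, "Gt")
  if (!all(dim(X) == dim(N)) || !all(dim(X) == dim(Gt)))
    stop("triplet images must be co-shaped", call. = FALSE)
  stopifnot(n_elements >= 1)
  structure(list(X = X, N = N, Gt = Gt, n_elements = as.integer(n_elements)),
            class = "recon_triplet")
}

#' Edge sensitivity across two transducer counts
#'
#' Ratio of the change in reconstruction quality to the change in
#' input-edge quality between two transducer counts i and j:
#' `[SSIM(N_j, Gt_j) - SSIM(N_i, Gt_i)] /
#'  [SSIM(edge(X_j), Gt_j) - SSIM(edge(X_i), Gt_i)]`.
#' Values nearer zero mean the model is less perturbed by degraded inputs.
#' The denominator compares the input edge map against the ground-truth
#' image by default; `denominator = "edge_vs_edge"` compares it against the
#' ground truth's edge map instead.
#'
#' @param t_i,t_j [recon_triplet()] objects with distinct element tags.
#' @param params An [ssim_params()] object.
#' @param denominator Denominator convention (see above).
#' @export
edge_sensitivity <- function(t_i, t_j, params = ssim_params(),
                             denominator = c("edge_vs_image",
                                             "edge_vs_edge")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(t_i, "recon_triplet"), inherits(t_j, "recon_triplet"))
  if (t_i$n_elements == t_j$n_elements)
    stop("triplets must carry distinct transducer counts", call. = FALSE)
  num <- ssim(t_j$N, t_j$Gt, params) - ssim(t_i$N, t_i$Gt, params)
  ref <- function(t) if (denominator == "edge_vs_image") t$Gt else
    edge_map(t$Gt)
  den <- ssim(edge_map(t_j$X), ref(t_j), params) -
    ssim(edge_map(t_i$X), ref(t_i), params)
  if (den == 0)
    stop("sensitivity undefined: zero edge-quality difference", call. = FALSE)
  num / den
}
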