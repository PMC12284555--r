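# ---------------------------------------------------------------------------
# Training losses. Each loss exists twice: as a plain function of two
# matrices (for evaluation and tests) and as a tape builder (suffix `tp_`)
# used inside the training loop so gradients flow to the network weights.
# ---------------------------------------------------------------------------

#' SSIM dissimilarity loss
#'
#' `1 - ssim(x, y)`; zero iff the images are identical, minimized at
#' identity.
#'
#' @inheritParams ssim
#' @export
ssim_loss <- function(x, y, params = ssim_params()) 1 - ssim(x, y, params)

#' Alpha loss: convex mix of MSE and SSIM dissimilarity
#'
#' `(1 - alpha) * MSE + alpha * (1 - SSIM)` with alpha = 0.84 by default.
#' The mixed loss rewards both pixel fidelity and structural similarity;
#' at `alpha = 0` it reduces to MSE. `literal = TRUE` switches the SSIM
#' term to `+ alpha * SSIM` (which rewards dissimilarity under
#' minimization) for auditing the sign convention.
#'
#' @inheritParams ssim
#' @param alpha Mixing weight in \[0, 1\].
#' @param literal Use the raw `+ alpha * SSIM` form instead of the
#'   dissimilarity term.
#' @export
alpha_loss <- function(x, y, alpha = 0.84, params = ssim_params(),
                       literal = FALSE) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  s <- ssim(x, y, params)
  (1 - alpha) * mse(x, y) + alpha * (if (literal) s else 1 - s)
}

#' Scaled RMSE loss
#'
#' RMSE computed under a constant intensity scale:
#' `scale * rmse(pred, target)`. The scale keeps gradients away from the
#' vanishing regime when intensities are very small.
#'
#' @param pred,target Co-shaped numeric matrices.
#' @param scale Positive intensity scale (default 255).
#' @export
srmse_loss <- function(pred, target, scale = 255) {
  if (!is.numeric(scale) || scale <= 0)
    stop("'scale' must be positive", call. = FALSE)
  scale * rmse(pred, target)
}

# -- tape builders -----------------------------------------------------------

tp_mse_loss <- function(tp, pred, target) {
  tp_mean_all(tp, tp_square(tp, tp_sub(tp, pred, target)))
}

tp_srmse_loss <- function(tp, pred, target, scale = 255) {
  tp_scale(tp, tp_sqrt(tp, tp_mse_loss(tp, pred, target)), scale)
}

# Gaussian-window SSIM built from tape ops so the gradient w.r.t. `pred`
# is exact (the window is a constant valid-mode convolution).
tp_ssim <- function(tp, pred, target, params = ssim_params()) {
  k <- params$window_size
  g1 <- gaussian_kernel_1d(k, params$sigma)
  w <- tp_const(tp, matrix(as.vector(outer(g1, g1)), ncol = 1L))
  b0 <- tp_const(tp, 0)
  C1 <- (params$K1 * params$L)^2
  C2 <- (params$K2 * params$L)^2
  f <- function(id) tp_conv2d(tp, id, w, b0, k, k, 0L)
  mu_x <- f(pred); mu_y <- f(target)
  exx <- f(tp_square(tp, pred))
  eyy <- f(tp_square(tp, target))
  exy <- f(tp_mul(tp, pred, target))
  mux2 <- tp_square(tp, mu_x)
  muy2 <- tp_square(tp, mu_y)
  muxy <- tp_mul(tp, mu_x, mu_y)
  sx <- tp_sub(tp, exx, mux2)
  sy <- tp_sub(tp, eyy, muy2)
  sxy <- tp_sub(tp, exy, muxy)
  num <- tp_mul(tp, tp_addc(tp, tp_scale(tp, muxy, 2), C1),
                tp_addc(tp, tp_scale(tp, sxy, 2), C2))
  den <- tp_mul(tp, tp_addc(tp, tp_add(tp, mux2, muy2), C1),
                tp_addc(tp, tp_add(tp, sx, sy), C2))
  tp_mean_all(tp, tp_div(tp, num, den))
}

tp_ssim_loss <- function(tp, pred, target, params = ssim_params()) {
  tp_addc(tp, tp_scale(tp, tp_ssim(tp, pred, target, params), -1), 1)
}

tp_alpha_loss <- function(tp, pred, target, alpha = 0.84,
                          params = ssim_params()) {
  tp_add(tp,
         tp_scale(tp, tp_mse_loss(tp, pred, target), 1 - alpha),
         tp_scale(tp, tp_ssim_loss(tp, pred, target, params), alpha))
}

# dispatcher used by the training loop
tp_training_loss <- function(tp, pred, target, control) {
  switch(control$loss,
         mse = tp_mse_loss(tp, pred, target),
         ssim = tp_ssim_loss(tp, pred, target, control$ssim_params),
         alpha = tp_alpha_loss(tp, pred, target, control$alpha,
                               control$ssim_params),
         srmse = tp_srmse_loss(tp, pred, target, control$srmse_scale),
         stop("unknown loss: ", control$loss))
}
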