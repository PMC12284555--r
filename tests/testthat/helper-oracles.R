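# Independent brute-force oracles. These deliberately share no code with
# the package internals: direct loops, no im2col, no banded matrices.

naive_conv2d <- function(x, w, b, kh, kw, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- ncol(w)
  Ho <- H + 2 * pad - kh + 1
  Wo <- W + 2 * pad - kw + 1
  y <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    s <- b[co]
    for (ki in 0:(kh - 1)) for (kj in 0:(kw - 1)) for (c in seq_len(Cin)) {
      si <- i + ki - pad; sj <- j + kj - pad
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        s <- s + x[si, sj, c] * w[(ki * kw + kj) * Cin + c, co]
    }
    y[i, j, co] <- s
  }
  y
}

# per-window SSIM reference: explicit loop over valid window positions
naive_ssim <- function(x, y, params = ssim_params()) {
  k <- params$window_size
  half <- (k - 1) %/% 2
  g1 <- exp(-((-half:half)^2) / (2 * params$sigma^2))
  g1 <- g1 / sum(g1)
  w2 <- outer(g1, g1)
  C1 <- (params$K1 * params$L)^2
  C2 <- (params$K2 * params$L)^2
  H <- nrow(x); W <- ncol(x)
  vals <- c()
  for (i in seq_len(H - k + 1)) for (j in seq_len(W - k + 1)) {
    px <- x[i:(i + k - 1), j:(j + k - 1)]
    py <- y[i:(i + k - 1), j:(j + k - 1)]
    mx <- sum(w2 * px); my <- sum(w2 * py)
    sx <- sum(w2 * px * px) - mx^2
    sy <- sum(w2 * py * py) - my^2
    sxy <- sum(w2 * px * py) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                ((mx^2 + my^2 + C1) * (sx + sy + C2)))
  }
  mean(vals)
}

# brute-force arc-membership forward projection: per-pixel loop
naive_forward_project <- function(img, geometry, n_bins) {
  H <- nrow(img); W <- ncol(img)
  dr <- 2 / max(H, W)
  out <- matrix(0, geometry$n_elements, n_bins)
  for (e in seq_len(geometry$n_elements)) {
    ex <- geometry$positions[e, 1]; ey <- geometry$positions[e, 2]
    for (i in seq_len(H)) for (j in seq_len(W)) {
      px <- (j - 0.5) / W * 2 - 1
      py <- 1 - (i - 0.5) / H * 2
      bin <- round(sqrt((px - ex)^2 + (py - ey)^2) / dr)
      bin <- min(max(bin, 1), n_bins)
      out[e, bin] <- out[e, bin] + img[i, j]
    }
  }
  out
}

naive_das <- function(data, geometry, grid_size, dr) {
  H <- W <- grid_size
  out <- matrix(0, H, W)
  nb <- ncol(data)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    px <- (j - 0.5) / W * 2 - 1
    py <- 1 - (i - 0.5) / H * 2
    s <- 0
    for (e in seq_len(geometry$n_elements)) {
      bin <- round(sqrt((px - geometry$positions[e, 1])^2 +
                          (py - geometry$positions[e, 2])^2) / dr)
      s <- s + data[e, min(max(bin, 1), nb)]
    }
    out[i, j] <- s / geometry$n_elements
  }
  r <- range(out)
  if (r[2] > r[1]) (out - r[1]) / (r[2] - r[1]) else out * 0
}

# independent factor-2 resizes (own formulas, matrices rebuilt per call)
naive_down2 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
  for (c in seq_len(d[3]))
    for (i in seq_len(d[1] / 2)) for (j in seq_len(d[2] / 2))
      out[i, j, c] <- mean(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
  out
}

naive_up2 <- function(x) {
  d <- dim(x)
  H <- d[1]
  wrow <- function(i) {
    src <- (i - 0.5) / 2 - 0.5
    lo <- min(max(floor(src), 0), H - 1)
    hi <- min(lo + 1, H - 1)
    f <- src - floor(src)
    w <- numeric(H); w[lo + 1] <- w[lo + 1] + 1 - f; w[hi + 1] <- w[hi + 1] + f
    w
  }
  U <- t(vapply(seq_len(2 * H), wrow, numeric(H)))
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c in seq_len(d[3])) out[, , c] <- U %*% x[, , c] %*% t(U)
  out
}

naive_lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)

# residual unit / Pairwise-Conv-Avg block re-implemented with the naive ops
naive_residual <- function(x, w1, b1, w2, b2, k, slope = 0.01) {
  x + naive_conv2d(naive_lrelu(naive_conv2d(x, w1, b1, k, k, (k - 1) / 2),
                               slope), w2, b2, k, k, (k - 1) / 2)
}

naive_block <- function(target, ctx_in, ctx_out, par, l, k, resize,
                        slope = 0.01, update_context = TRUE) {
  p <- function(s) par[[sprintf("b%d.%s", l, s)]]
  tgt <- naive_residual(target, p("rt1.w"), p("rt1.b"), p("rt2.w"),
                        p("rt2.b"), k, slope)
  rc <- function(x) naive_residual(x, p("rc1.w"), p("rc1.b"), p("rc2.w"),
                                   p("rc2.b"), k, slope)
  cin <- lapply(ctx_in, rc)
  cout <- lapply(ctx_out, rc)
  cands <- mapply(function(a, b) {
    cc <- array(c(tgt, a, b), c(dim(tgt)[1], dim(tgt)[2], 3 * dim(tgt)[3]))
    naive_conv2d(cc, p("pw.w"), p("pw.b"), 1, 1, 0)
  }, cin, cout, SIMPLIFY = FALSE)
  new_tgt <- Reduce(`+`, cands) / length(cands)
  rs <- switch(resize, down = naive_down2, up = naive_up2, none = identity)
  if (!update_context) return(list(target = rs(new_tgt)))
  tr <- function(x) naive_conv2d(x, p("ct.w"), p("ct.b"), 1, 1, 0)
  list(target = rs(new_tgt), ctx_in = lapply(lapply(cin, tr), rs),
       ctx_out = lapply(lapply(cout, tr), rs))
}

# full forward pass assembled step by step from the naive operations
naive_omninet_forward <- function(par, x, context, config) {
  k <- config$kernel_size
  slope <- config$lrelu_slope
  im <- function(m) array(m, c(nrow(m), ncol(m), 1))
  emb <- function(m) naive_conv2d(im(m), par$embed.w, par$embed.b, k, k,
                                  (k - 1) / 2)
  state <- list(target = emb(x),
                ctx_in = lapply(context, function(p) emb(p$input)),
                ctx_out = lapply(context, function(p) emb(p$target)))
  resize <- c("down", "down", "down", "none", "up", "up", "up")
  skips <- list()
  for (l in 1:3) {
    skips[[l]] <- state$target
    state <- naive_block(state$target, state$ctx_in, state$ctx_out, par, l,
                         k, resize[l], slope)
  }
  state <- naive_block(state$target, state$ctx_in, state$ctx_out, par, 4,
                       k, "none", slope)
  for (l in 5:7) {
    state <- naive_block(state$target, state$ctx_in, state$ctx_out, par, l,
                         k, resize[l], slope, update_context = l < 7)
    j <- 8 - l
    cc <- array(c(state$target, skips[[j]]),
                c(dim(state$target)[1], dim(state$target)[2],
                  2 * dim(state$target)[3]))
    state$target <- naive_conv2d(cc, par[[sprintf("skip%d.w", j)]],
                                 par[[sprintf("skip%d.b", j)]], 1, 1, 0)
  }
  naive_conv2d(state$target, par$out.w, par$out.b, k, k, (k - 1) / 2)[, , 1]
}

rand_img <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n), n)
}

make_pairs <- function(k, n, seed) {
  set.seed(seed)
  lapply(seq_len(k), function(i)
    list(input = matrix(runif(n * n), n), target = matrix(runif(n * n), n),
         meta = list(task = "t")))
}
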