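test_that("mse, rmse and psnr obey their closed forms", {
  x <- rand_img(8, 1)
  expect_equal(mse(x, x), 0)
  expect_equal(rmse(x, x), 0)
  y <- x + 0.1
  expect_equal(mse(x, y), 0.01)
  expect_equal(rmse(x, y), 0.1)
  z0 <- matrix(0, 8, 8)
  expect_equal(psnr(z0, z0 + 0.1), 20)
  expect_equal(psnr(z0, z0 + 0.01), 40)
  expect_identical(psnr(x, x), Inf)
  expect_error(psnr(x, y, max_val = 0), "positive")
  expect_error(mse(x, matrix(0, 4, 4)), "identical dimensions")
})

test_that("mse matches a double-loop summation oracle", {
  x <- rand_img(8, 2); y <- rand_img(8, 3)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(mse(x, y), acc / 64, tolerance = 1e-12)
  expect_equal(rmse(x, y), sqrt(acc / 64), tolerance = 1e-12)
})

test_that("ssim is 1 at identity, symmetric, and matches the sliding-window oracle", {
  x <- rand_img(32, 4); y <- rand_img(32, 5)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-14)
  expect_equal(ssim(x, y), naive_ssim(x, y), tolerance = 1e-8)
  # structured pair too, not just noise
  s <- outer(1:32, 1:32, function(i, j) sin(i / 4) * cos(j / 5)) / 2 + 0.5
  expect_equal(ssim(s, 0.8 * s + 0.05), naive_ssim(s, 0.8 * s + 0.05),
               tolerance = 1e-8)
  expect_error(ssim(rand_img(8, 1), rand_img(8, 2)), "window")
})

test_that("ssim_loss vanishes at identity and its tape gradient matches finite differences", {
  x <- rand_img(16, 6); y <- rand_img(16, 7)
  expect_equal(ssim_loss(x, x), 0)
  expect_equal(ssim_loss(x, y), 1 - ssim(x, y))
  tp <- paomninet:::new_tape()
  px <- paomninet:::tp_param(tp, array(x, c(16, 16, 1)))
  py <- paomninet:::tp_const(tp, array(y, c(16, 16, 1)))
  l <- paomninet:::tp_ssim_loss(tp, px, py)
  expect_equal(paomninet:::tp_val(tp, l), ssim_loss(x, y), tolerance = 1e-12)
  gr <- paomninet:::tp_backward(tp, l)
  g <- as.vector(gr[[px]])
  eps <- 1e-5
  for (i in c(5L, 60L, 130L, 250L)) {
    xp <- as.vector(x); xm <- xp
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    fd <- (ssim_loss(matrix(xp, 16), y) - ssim_loss(matrix(xm, 16), y)) /
      (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("alpha loss is the stated convex mix of MSE and SSIM dissimilarity", {
  x <- rand_img(32, 8); y <- rand_img(32, 9)
  expect_equal(alpha_loss(x, y, alpha = 0), mse(x, y))
  expect_equal(alpha_loss(x, x, alpha = 0.3), 0)
  m <- mse(x, y); s <- naive_ssim(x, y)
  expect_equal(alpha_loss(x, y, alpha = 0.84), 0.16 * m + 0.84 * (1 - s),
               tolerance = 1e-8)
  expect_equal(alpha_loss(x, y, alpha = 0.84, literal = TRUE),
               0.16 * m + 0.84 * s, tolerance = 1e-8)
  expect_error(alpha_loss(x, y, alpha = 1.2), "alpha")
  # convex-combination bound at the extremes and midpoint
  for (a in c(0, 0.5, 1)) {
    v <- alpha_loss(x, y, alpha = a)
    expect_gte(v, min(m, 1 - s) - 1e-12)
    expect_lte(v, max(m, 1 - s) + 1e-12)
  }
})

test_that("scaled RMSE is linear in the scale", {
  x <- rand_img(8, 10)
  expect_equal(srmse_loss(x, x + 0.01, scale = 10), 0.1)
  expect_equal(srmse_loss(x, x + 0.3, scale = 1), rmse(x, x + 0.3))
  y <- rand_img(8, 11)
  expect_equal(srmse_loss(x, y, scale = 255), 255 * rmse(x, y))
  expect_error(srmse_loss(x, y, scale = -1), "positive")
})

test_that("edge map is a normalized Sobel magnitude", {
  expect_true(all(edge_map(matrix(0.5, 10, 10)) == 0))
  step <- matrix(0, 12, 12); step[, 7:12] <- 1
  em <- edge_map(step)
  expect_true(all(apply(em, 1, which.max) %in% 6:7))
  x <- rand_img(10, 12)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  corr <- function(img, k) {
    out <- matrix(0, 10, 10)
    for (i in 1:10) for (j in 1:10) for (di in -1:1) for (dj in -1:1) {
      si <- min(max(i + di, 1), 10)  # replicated borders
      sj <- min(max(j + dj, 1), 10)
      out[i, j] <- out[i, j] + img[si, sj] * k[di + 2, dj + 2]
    }
    out
  }
  mag <- sqrt(corr(x, sx)^2 + corr(x, t(sx))^2)
  mag <- (mag - min(mag)) / (max(mag) - min(mag))
  expect_equal(edge_map(x), mag, tolerance = 1e-12)
})

test_that("edge sensitivity composes the four SSIM terms correctly", {
  set.seed(20)
  mk <- function(s) {
    set.seed(s)
    Gt <- matrix(runif(256), 16)
    X <- pmin(pmax(Gt + matrix(rnorm(256, 0, 0.2), 16), 0), 1)
    N <- pmin(pmax(Gt + matrix(rnorm(256, 0, 0.05), 16), 0), 1)
    list(X = X, N = N, Gt = Gt)
  }
  a <- mk(21); b <- mk(22)
  ti <- recon_triplet(a$X, a$N, a$Gt, 16)
  tj <- recon_triplet(b$X, b$N, b$Gt, 32)
  num <- ssim(tj$N, tj$Gt) - ssim(ti$N, ti$Gt)
  den <- ssim(edge_map(tj$X), tj$Gt) - ssim(edge_map(ti$X), ti$Gt)
  expect_equal(edge_sensitivity(ti, tj), num / den, tolerance = 1e-12)
  # numerator == denominator by construction -> exactly 1
  ti2 <- recon_triplet(a$X, edge_map(a$X), a$Gt, 16)
  tj2 <- recon_triplet(b$X, edge_map(b$X), b$Gt, 32)
  expect_equal(edge_sensitivity(ti2, tj2), 1.0, tolerance = 1e-12)
  # zero numerator with nonzero denominator -> 0
  ti3 <- recon_triplet(a$X, a$N, a$Gt, 16)
  tj3 <- recon_triplet(b$X, a$N, a$Gt, 32)
  expect_equal(edge_sensitivity(ti3, tj3), 0.0, tolerance = 1e-12)
  # identical inputs on both sides -> zero denominator error
  ti4 <- recon_triplet(a$X, a$N, a$Gt, 16)
  tj4 <- recon_triplet(a$X, b$N, a$Gt, 32)
  expect_error(edge_sensitivity(ti4, tj4), "undefined")
  expect_error(edge_sensitivity(ti, ti), "distinct")
  # edge-vs-edge denominator variant
  den2 <- ssim(edge_map(tj$X), edge_map(tj$Gt)) -
    ssim(edge_map(ti$X), edge_map(ti$Gt))
  expect_equal(edge_sensitivity(ti, tj, denominator = "edge_vs_edge"),
               num / den2, tolerance = 1e-12)
})

test_that("metrics are invariant under a simultaneous flip and psnr falls with rmse", {
  x <- rand_img(32, 30); y <- rand_img(32, 31)
  fx <- x[, 32:1]; fy <- y[, 32:1]
  expect_equal(mse(fx, fy), mse(x, y))
  expect_equal(ssim(fx, fy), ssim(x, y), tolerance = 1e-12)
  expect_equal(psnr(fx, fy), psnr(x, y))
  z <- matrix(0, 16, 16)
  rs <- c(0.01, 0.05, 0.2, 0.5)
  ps <- vapply(rs, function(r) psnr(z, z + r), numeric(1))
  expect_true(all(diff(ps) < 0))
})
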