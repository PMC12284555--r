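test_that("the shared embedding treats target and context roles identically", {
  cfg <- omninet_config(base_channels = 2L, seed = 1L)
  par <- omninet_init(cfg)
  expect_false("embed_ctx.w" %in% names(par))
  cfg2 <- omninet_config(base_channels = 2L, shared_embedding = FALSE,
                         seed = 1L)
  par2 <- omninet_init(cfg2)
  expect_true("embed_ctx.w" %in% names(par2))
  expect_equal(omninet_param_count(cfg2) - omninet_param_count(cfg),
               9L * 2L + 2L)
  # zero image through a zero-bias embedding gives zero features, and the
  # same image embeds identically regardless of role (shared weights)
  z <- paomninet:::cpp_conv2d(array(0, c(8, 8, 1)), par$embed.w,
                              par$embed.b * 0, 3L, 3L, 1L)
  expect_true(all(z == 0))
  img <- rand_img(8, 2)
  e1 <- paomninet:::cpp_conv2d(array(img, c(8, 8, 1)), par$embed.w,
                               par$embed.b, 3L, 3L, 1L)
  e2 <- paomninet:::cpp_conv2d(array(img, c(8, 8, 1)), par$embed.w,
                               par$embed.b, 3L, 3L, 1L)
  expect_identical(e1, e2)
})

test_that("residual units are identity at zero weights and linear without activation", {
  cfg <- omninet_config(base_channels = 4L, seed = 2L)
  par <- omninet_init(cfg)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  zpar <- par
  for (nm in grep("^b1\\.r", names(par), value = TRUE))
    zpar[[nm]] <- zpar[[nm]] * 0
  t1 <- paomninet:::new_tape()
  pid <- paomninet:::push_params(t1, zpar, track = FALSE)
  xi <- paomninet:::tp_const(t1, x)
  y <- paomninet:::tp_residual_unit(t1, xi, pid, "b1.rt", cfg)
  expect_equal(paomninet:::tp_val(t1, y), x, tolerance = 1e-14)
  # slope-1 LeakyReLU makes the unit linear: f(a x) = a f(x) at zero bias
  cfl <- omninet_config(base_channels = 4L, lrelu_slope = 1, seed = 2L)
  lp <- omninet_init(cfl)
  lp[["b1.rt1.b"]] <- lp[["b1.rt1.b"]] * 0
  lp[["b1.rt2.b"]] <- lp[["b1.rt2.b"]] * 0
  run <- function(xx) {
    t2 <- paomninet:::new_tape()
    pid2 <- paomninet:::push_params(t2, lp, track = FALSE)
    paomninet:::tp_val(t2, paomninet:::tp_residual_unit(
      t2, paomninet:::tp_const(t2, xx), pid2, "b1.rt", cfl))
  }
  expect_equal(run(3 * x), 3 * run(x), tolerance = 1e-10)
  expect_equal(dim(run(x)), dim(x))
})

test_that("the pairwise block matches a naively coded per-pair loop", {
  cfg <- omninet_config(base_channels = 4L, seed = 3L)
  par <- omninet_init(cfg)
  set.seed(30)
  tgt <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  cin <- lapply(1:2, function(i) array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  cout <- lapply(1:2, function(i) array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  for (rs in c("none", "down", "up")) {
    t1 <- paomninet:::new_tape()
    pid <- paomninet:::push_params(t1, par, track = FALSE)
    st <- list(target = paomninet:::tp_const(t1, tgt),
               ctx_in = lapply(cin, paomninet:::tp_const, tp = t1),
               ctx_out = lapply(cout, paomninet:::tp_const, tp = t1))
    got <- paomninet:::tp_pairwise_block(t1, st, 1L, pid, cfg, rs)
    want <- naive_block(tgt, cin, cout, par, 1, cfg$kernel_size, rs)
    expect_equal(paomninet:::tp_val(t1, got$target), want$target,
                 tolerance = 1e-6)
    expect_equal(paomninet:::tp_val(t1, got$ctx_in[[2]]),
                 want$ctx_in[[2]], tolerance = 1e-6)
    expect_equal(paomninet:::tp_val(t1, got$ctx_out[[1]]),
                 want$ctx_out[[1]], tolerance = 1e-6)
  }
})

test_that("block and forward outputs are invariant to context order and duplication", {
  cfg <- omninet_config(base_channels = 2L, seed = 4L)
  par <- omninet_init(cfg)
  x <- rand_img(16, 31)
  ctx <- make_pairs(4, 16, 32)
  y <- omninet_forward(par, x, ctx, cfg)
  expect_equal(dim(y), c(16L, 16L))
  yp <- omninet_forward(par, x, ctx[c(3, 1, 4, 2)], cfg)
  expect_lt(max(abs(y - yp)), 1e-6)
  yd <- omninet_forward(par, x, c(ctx, ctx, ctx), cfg)
  expect_lt(max(abs(y - yd)), 1e-6)
  # one pair replicated four times equals the single pair
  y1 <- omninet_forward(par, x, ctx[1], cfg)
  y4 <- omninet_forward(par, x, ctx[c(1, 1, 1, 1)], cfg)
  expect_lt(max(abs(y1 - y4)), 1e-6)
})

test_that("the forward pass equals a step-by-step naive composition", {
  cfg <- omninet_config(base_channels = 2L, seed = 6L)
  par <- omninet_init(cfg)
  x <- rand_img(16, 33)
  ctx <- make_pairs(1, 16, 34)
  got <- omninet_forward(par, x, ctx, cfg)
  want <- naive_omninet_forward(par, x, ctx, cfg)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("output shape is preserved at realistic sizes and inputs are validated", {
  cfg <- omninet_config(base_channels = 2L, seed = 7L)
  par <- omninet_init(cfg)
  x <- rand_img(64, 35)
  ctx <- make_pairs(4, 64, 36)
  expect_equal(dim(omninet_forward(par, x, ctx, cfg)), c(64L, 64L))
  expect_error(omninet_forward(par, rand_img(20, 1), make_pairs(1, 20, 2),
                               cfg), "divisible by 8")
  expect_error(omninet_forward(par, x, list(), cfg), "at least one")
  bad <- ctx
  bad[[1]]$input <- rand_img(32, 3)
  expect_error(omninet_forward(par, x, bad, cfg), "co-shaped")
  expect_error(omninet_forward(par, array(runif(64 * 64 * 3),
                                          c(64, 64, 3)), ctx, cfg),
               "matrix")
})

test_that("parameter counts follow the closed form and every group receives gradient", {
  for (bc in c(2L, 3L)) {
    cfg <- omninet_config(base_channels = bc, seed = 8L)
    expect_equal(sum(lengths(omninet_init(cfg))), omninet_param_count(cfg))
  }
  # frozen hand total for the smallest config (kernel 3, channels 2/4/8/16)
  expect_equal(omninet_param_count(omninet_config(base_channels = 2L)),
               27263L)
  cfg <- omninet_config(base_channels = 2L, seed = 9L)
  par <- omninet_init(cfg)
  ctl <- train_control(loss = "mse", seed = 1L)
  pair <- make_pairs(1, 16, 40)[[1]]
  st <- paomninet:::sample_loss_tape("omninet", par, cfg, pair,
                                     make_pairs(2, 16, 41), ctl, TRUE)
  gr <- paomninet:::tp_backward(st$tp, st$loss)
  for (nm in names(par)) {
    g <- gr[[st$pid[[nm]]]]
    expect_false(is.null(g), info = nm)
    expect_gt(max(abs(g)), 0)
  }
})

test_that("forward passes are bitwise deterministic", {
  cfg <- omninet_config(base_channels = 2L, seed = 10L)
  par <- omninet_init(cfg)
  x <- rand_img(16, 50)
  ctx <- make_pairs(2, 16, 51)
  expect_identical(omninet_forward(par, x, ctx, cfg),
                   omninet_forward(par, x, ctx, cfg))
  expect_identical(omninet_init(cfg), par)
})
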