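test_that("geometries lay out elements as specified", {
  g4 <- make_geometry("ring", 4)
  expect_equal(g4$positions,
               rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
               tolerance = 1e-12)
  gm <- make_geometry("multisegment", 256)
  expect_equal(gm$n_elements, 256L)
  expect_equal(unname(table(gm$segment)[c("linear", "concave_left",
                                          "concave_right")]),
               c(128L, 64L, 64L), ignore_attr = TRUE)
  gs <- make_geometry("semicircle", 256)
  ang <- atan2(gs$positions[, 2], gs$positions[, 1])
  expect_true(all(ang >= -1e-9 & ang <= pi + 1e-9))
  expect_equal(max(ang) - min(ang), pi, tolerance = 1e-9)
  expect_equal(nrow(gs$positions), gs$n_elements)
  expect_error(make_geometry("hexagon", 8))
  expect_error(make_geometry("multisegment", 30), "n/2")
  expect_error(make_geometry("ring", 0), ">= 1")
})

test_that("uniform decimation keeps stride-spaced elements and segment ratios", {
  g <- make_geometry("ring", 512)
  s <- subsample_elements(g, 32)
  expect_equal(s$kept_idx, seq(1L, 512L, by = 16L))
  expect_identical(subsample_elements(g, 512), g)
  expect_error(subsample_elements(g, 600), "n_elements")
  expect_error(subsample_elements(g, 100), "divide")
  gm <- make_geometry("multisegment", 256)
  sm <- subsample_elements(gm, 32)
  expect_equal(unname(table(sm$segment)[c("linear", "concave_left",
                                          "concave_right")]),
               c(16L, 8L, 8L), ignore_attr = TRUE)
})

test_that("forward projection matches geometry of flight times and the brute-force oracle", {
  # ring-4: grid symmetric under 90-degree rotation -> identical traces
  sc <- phantom_scene(list(list(type = "disk", center = c(0, 0),
                                radius = 0.3, amplitude = 1)), 24)
  sino <- forward_project(sc, make_geometry("ring", 4))
  expect_lt(max(apply(sino$data, 2, function(z) diff(range(z)))), 1e-12)
  # off-centre point absorber peaks at the rounded time-of-flight bin
  img <- matrix(0, 32, 32); img[10, 25] <- 1
  g8 <- make_geometry("ring", 8)
  s8 <- forward_project(img, g8)
  px <- (25 - 0.5) / 32 * 2 - 1
  py <- 1 - (10 - 0.5) / 32 * 2
  for (e in 1:8) {
    d <- sqrt(sum((c(px, py) - g8$positions[e, ])^2))
    expect_equal(which.max(s8$data[e, ]), round(d / s8$dr))
  }
  # random 3-disk scene equals the per-pixel arc-membership oracle
  sc3 <- phantom_scene(list(
    list(type = "disk", center = c(0.2, -0.1), radius = 0.2, amplitude = 0.8),
    list(type = "disk", center = c(-0.4, 0.3), radius = 0.15, amplitude = 1),
    list(type = "disk", center = c(0.1, 0.45), radius = 0.1, amplitude = 0.5)),
    24)
  g6 <- make_geometry("ring", 6)
  got <- forward_project(sc3, g6)
  want <- naive_forward_project(rasterize_scene(sc3), g6, got$n_time_bins)
  expect_equal(got$data, want, tolerance = 1e-10)
  expect_error(forward_project(matrix(1, 1, 1), g6), "degenerate")
})

test_that("delay-and-sum reconstruction behaves and matches its oracle", {
  g <- make_geometry("ring", 16)
  zero <- structure(list(data = matrix(0, 16, 60), n_elements = 16L,
                         n_time_bins = 60L, dr = 2 / 24, sound_speed = 1),
                    class = "pa_sinogram")
  expect_true(all(das_reconstruct(zero, g, 24) == 0))
  # centred disk with a dense ring peaks at the grid centre
  sc <- phantom_scene(list(list(type = "disk", center = c(0, 0),
                                radius = 0.15, amplitude = 1)), 32)
  gd <- make_geometry("ring", 256)
  rec <- das_reconstruct(forward_project(sc, gd), gd, 32)
  peak <- which(rec == max(rec), arr.ind = TRUE)
  expect_true(all(peak >= 15 & peak <= 18))
  # oracle equivalence on a small instance
  g6 <- make_geometry("ring", 6)
  sino <- forward_project(sc, g6)
  expect_equal(das_reconstruct(sino, g6, 24),
               naive_das(sino$data, g6, 24, sino$dr), tolerance = 1e-10)
  expect_error(das_reconstruct(sino, g, 24), "element counts")
})

test_that("a 16-element ring imaging a centred point produces 16 streaks", {
  sc <- phantom_scene(list(list(type = "disk", center = c(0, 0),
                                radius = 0.03, amplitude = 1)), 64)
  g16 <- make_geometry("ring", 16)
  rec <- das_reconstruct(forward_project(sc, g16), g16, 64)
  prof <- angular_profile(rec, radius = 0.5)
  expect_equal(dominant_angular_frequency(prof), 16L)
})

test_that("dense ground truth is closer to the phantom than the sparse input", {
  skipped <- 0
  wins <- 0
  diffs <- numeric(0)
  dense <- make_geometry("ring", 256)
  for (s in 1:20) {
    sc <- random_scene(48, seed = 1000 + s)
    ph <- paomninet:::normalize01(rasterize_scene(sc))
    pair <- simulate_pair(sc, list(kind = "ring", n_sparse = 32L,
                                   n_dense = 256L), 48)
    diffs <- c(diffs, ssim(pair$target, ph) - ssim(pair$input, ph))
  }
  expect_gt(mean(diffs), 0)
})

test_that("ground-truth rendering is deterministic and handles empty scenes", {
  empty <- phantom_scene(list(), 32)
  g <- make_geometry("ring", 64)
  expect_true(all(render_ground_truth(empty, g, 32) == 0))
  a <- render_ground_truth(random_scene(32, seed = 7), g, 32)
  b <- render_ground_truth(random_scene(32, seed = 7), g, 32)
  expect_identical(a, b)
  ph <- render_ground_truth(random_scene(32, seed = 7), g, 32,
                            mode = "phantom")
  expect_true(all(ph >= 0 & ph <= 1))
})

test_that("dataset bundles honour grouped splits and reproducibility", {
  b <- build_dataset(100, 10, task = list(kind = "ring", n_sparse = 32L,
                                          n_dense = 128L),
                     split_fractions = c(0.7, 0.2, 0.1), seed = 3,
                     grid_size = 16)
  expect_equal(lengths(b$split), c(train = 70L, val = 20L, test = 10L))
  gsp <- lapply(b$split, function(ix) unique(b$groups[ix]))
  expect_length(intersect(gsp$train, gsp$val), 0)
  expect_length(intersect(gsp$train, gsp$test), 0)
  expect_length(intersect(gsp$val, gsp$test), 0)
  expect_error(build_dataset(10, 1, split_fractions = c(0.7, 0.2, 0.1)),
               "3 groups")
  expect_error(build_dataset(10, 5, split_fractions = c(0.7, 0.2, 0.2)),
               "sum to 1")
  expect_error(build_dataset(0, 3), "zero-item")
  b2 <- build_dataset(6, 3, task = list(kind = "ring", n_sparse = 16L,
                                        n_dense = 64L), seed = 3,
                      grid_size = 16)
  b3 <- build_dataset(6, 3, task = list(kind = "ring", n_sparse = 16L,
                                        n_dense = 64L), seed = 3,
                      grid_size = 16)
  expect_identical(b2$pairs, b3$pairs)
})

test_that("dataset writer round-trips and is byte-stable", {
  b <- build_dataset(6, 3, task = list(kind = "ring", n_sparse = 16L,
                                       n_dense = 64L), seed = 4,
                     grid_size = 16)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  write_dataset(b, d1)
  write_dataset(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  rt <- read_dataset(d1)
  expect_equal(lengths(rt$split), lengths(b$split))
  for (i in seq_along(b$pairs)) {
    expect_lt(max(abs(rt$pairs[[i]]$input - b$pairs[[i]]$input)), 1 / 254)
    expect_lt(max(abs(rt$pairs[[i]]$target - b$pairs[[i]]$target)), 1 / 254)
    expect_equal(rt$pairs[[i]]$meta$group_id, b$pairs[[i]]$meta$group_id)
  }
})
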