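# ---------------------------------------------------------------------------
# Synthetic sparse-sampling photoacoustic simulator.
#
# Field of view is the square [-1, 1]^2 in normalized units, pixel centres,
# origin at the grid centre, y axis up (row 1 = top of the image). Sound
# speed is normalized so one time bin spans one pixel width. The forward
# model is an idealized 2-D arc integral; reconstruction is nearest-bin
# delay-and-sum backprojection, which reproduces the streak-artifact
# phenomenology of sparse arrays.
# ---------------------------------------------------------------------------

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Transducer array geometry
#'
#' Lays out detector element positions for the supported array kinds:
#' `ring` (full circle, equal angular spacing), `semicircle` (180-degree
#' arc), `multisegment` (a central linear segment holding half the
#' elements, flanked by two concave arc wings holding a quarter each, e.g.
#' 256 = 128 + 64 + 64), and `linear`.
#'
#' @param kind One of `"ring"`, `"semicircle"`, `"multisegment"`,
#'   `"linear"`.
#' @param n_elements Number of detector elements (multisegment counts must
#'   be divisible by 4 to keep the 2:1:1 segment composition).
#' @param radius_or_extent Array radius / half-extent in normalized
#'   field-of-view units.
#' @return A `pa_geometry` object with an `n_elements` x 2 position matrix.
#' @export
make_geometry <- function(kind = c("ring", "semicircle", "multisegment",
                                   "linear"),
                          n_elements, radius_or_extent = 1) {
  kind <- match.arg(kind)
  n <- as.integer(n_elements)
  if (is.na(n) || n < 1L) stop("'n_elements' must be >= 1", call. = FALSE)
  r <- radius_or_extent
  stopifnot(r > 0)
  segment <- rep("all", n)
  if (kind == "ring") {
    th <- 2 * pi * (seq_len(n) - 1L) / n
    pos <- cbind(r * cos(th), r * sin(th))
  } else if (kind == "semicircle") {
    th <- if (n == 1L) pi / 2 else seq(0, pi, length.out = n)
    pos <- cbind(r * cos(th), r * sin(th))
  } else if (kind == "linear") {
    xs <- if (n == 1L) 0 else seq(-r, r, length.out = n)
    pos <- cbind(xs, rep(r, n))
  } else {
    if (n %% 4L != 0L)
      stop("multisegment 'n_elements' must split as n/2 + n/4 + n/4",
           call. = FALSE)
    nl <- n %/% 2L
    nc <- n %/% 4L
    # chord between the 60 and 120 degree points, wings continue the circle
    y0 <- r * sin(pi / 3)
    xs <- seq(-r * cos(pi / 3), r * cos(pi / 3), length.out = nl)
    lin <- cbind(xs, rep(y0, nl))
    th_r <- seq(pi / 3, 0, length.out = nc + 1L)[-1L]
    th_l <- seq(2 * pi / 3, pi, length.out = nc + 1L)[-1L]
    pos <- rbind(lin, cbind(r * cos(th_r), r * sin(th_r)),
                 cbind(r * cos(th_l), r * sin(th_l)))
    segment <- c(rep("linear", nl), rep("concave_right", nc),
                 rep("concave_left", nc))
  }
  structure(list(kind = kind, n_elements = n, positions = unname(pos),
                 radius_or_extent = r, segment = segment,
                 kept_idx = seq_len(n)),
            class = "pa_geometry")
}

#' @export
print.pa_geometry <- function(x, ...) {
  cat(sprintf("<pa_geometry> %s, %d elements, radius/extent %.3g\n",
              x$kind, x$n_elements, x$radius_or_extent))
  if (x$kind == "multisegment")
    cat("  segments:", paste(sprintf("%s=%d", names(table(x$segment)),
                                     table(x$segment)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Uniformly decimate a transducer array
#'
#' Keeps every (n_elements / n_keep)-th element starting at the first,
#' preserving order. Multisegment arrays are decimated per segment so the
#' 2:1:1 composition survives (e.g. 256 -> 32 keeps 16 + 8 + 8).
#'
#' @param geometry A [make_geometry()] object.
#' @param n_keep Number of elements to keep; must divide `n_elements`.
#' @export
subsample_elements <- function(geometry, n_keep) {
  stopifnot(inherits(geometry, "pa_geometry"))
  n <- geometry$n_elements
  k <- as.integer(n_keep)
  if (is.na(k) || k < 1L || k > n)
    stop("'n_keep' must be in [1, n_elements]", call. = FALSE)
  if (n %% k != 0L)
    stop("'n_keep' must divide n_elements under the uniform policy",
         call. = FALSE)
  if (k == n) return(geometry)
  if (geometry$kind == "multisegment") {
    if (k %% 4L != 0L)
      stop("multisegment 'n_keep' must be divisible by 4", call. = FALSE)
    stride <- n %/% k
    idx <- unlist(lapply(split(seq_len(n), factor(geometry$segment,
                                                  unique(geometry$segment))),
                         function(s) s[seq(1L, length(s), by = stride)]),
                  use.names = FALSE)
    idx <- sort(idx)
  } else {
    idx <- seq(1L, n, by = n %/% k)
  }
  out <- geometry
  out$n_elements <- length(idx)
  out$positions <- geometry$positions[idx, , drop = FALSE]
  out$segment <- geometry$segment[idx]
  out$kept_idx <- geometry$kept_idx[idx]
  out
}

#' Phantom scene of optical absorbers
#'
#' @param absorbers List of primitives: disks
#'   (`list(type = "disk", center, radius, amplitude)`) and vessel segments
#'   (`list(type = "vessel", p1, p2, width, amplitude)`), coordinates in
#'   normalized field-of-view units.
#' @param grid_size Image side length in pixels.
#' @param seed Optional integer recorded for provenance.
#' @export
phantom_scene <- function(absorbers, grid_size = 64L, seed = NULL) {
  stopifnot(is.list(absorbers), grid_size >= 2L)
  for (a in absorbers) {
    stopifnot(a$type %in% c("disk", "vessel"), a$amplitude > 0)
    if (a$type == "disk") stopifnot(all(abs(a$center) <= 1), a$radius > 0)
    else stopifnot(all(abs(c(a$p1, a$p2)) <= 1), a$width > 0)
  }
  structure(list(absorbers = absorbers, grid_size = as.integer(grid_size),
                 seed = seed), class = "pa_scene")
}

#' Random seeded phantom scene
#'
#' Draws 2-5 disks and 0-2 vessel segments inside the field of view;
#' identical `(seed, grid_size)` always reproduces the identical scene.
#'
#' @param grid_size Image side length in pixels.
#' @param seed Integer seed.
#' @export
random_scene <- function(grid_size = 64L, seed = NULL) {
  draw <- function() {
    nd <- sample(2:5, 1L)
    nv <- sample(0:2, 1L)
    abs_d <- lapply(seq_len(nd), function(i) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.55)
      list(type = "disk", center = rad * c(cos(ang), sin(ang)),
           radius = runif(1, 0.05, 0.18), amplitude = runif(1, 0.4, 1))
    })
    abs_v <- lapply(seq_len(nv), function(i) {
      p1 <- runif(2, -0.6, 0.6)
      dir <- runif(1, 0, 2 * pi)
      len <- runif(1, 0.3, 0.8)
      p2 <- pmin(pmax(p1 + len * c(cos(dir), sin(dir)), -0.9), 0.9)
      list(type = "vessel", p1 = p1, p2 = p2,
           width = runif(1, 0.03, 0.07), amplitude = runif(1, 0.3, 0.8))
    })
    phantom_scene(c(abs_d, abs_v), grid_size, seed)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

pixel_coords <- function(H, W = H) {
  xs <- ((seq_len(W) - 0.5) / W) * 2 - 1
  ys <- 1 - ((seq_len(H) - 0.5) / H) * 2
  list(x = matrix(xs, H, W, byrow = TRUE), y = matrix(ys, H, W))
}

#' Rasterize a phantom scene onto the pixel grid
#'
#' Overlays primitives with per-pixel maximum of their amplitudes.
#'
#' @param scene A [phantom_scene()].
#' @param grid_size Side length in pixels (defaults to the scene's).
#' @return H x W numeric matrix.
#' @export
rasterize_scene <- function(scene, grid_size = scene$grid_size) {
  stopifnot(inherits(scene, "pa_scene"))
  H <- W <- as.integer(grid_size)
  if (H < 2L) stop("degenerate grid", call. = FALSE)
  pc <- pixel_coords(H, W)
  img <- matrix(0, H, W)
  for (a in scene$absorbers) {
    if (a$type == "disk") {
      m <- (pc$x - a$center[1L])^2 + (pc$y - a$center[2L])^2 <= a$radius^2
    } else {
      v <- a$p2 - a$p1
      L2 <- sum(v^2)
      t <- if (L2 == 0) 0 else
        pmin(pmax(((pc$x - a$p1[1L]) * v[1L] +
                     (pc$y - a$p1[2L]) * v[2L]) / L2, 0), 1)
      dx <- pc$x - (a$p1[1L] + t * v[1L])
      dy <- pc$y - (a$p1[2L] + t * v[2L])
      m <- dx^2 + dy^2 <= (a$width / 2)^2
    }
    img[m] <- pmax(img[m], a$amplitude)
  }
  img
}

default_time_bins <- function(H, W = H) as.integer(ceiling(sqrt(H^2 + W^2) * 1.5))

#' Idealized photoacoustic forward projection
#'
#' For each element, time bin t accumulates the phantom intensity over the
#' pixels whose distance from the element rounds to t bin widths (an arc
#' integral at sound speed one pixel per bin).
#'
#' @param scene A [phantom_scene()] or a numeric image matrix.
#' @param geometry A [make_geometry()] object.
#' @param n_time_bins Number of time-of-flight bins; the default
#'   `ceil(1.5 * grid diagonal)` covers all propagation paths.
#' @return A `pa_sinogram`: elements x bins matrix plus bin width.
#' @export
forward_project <- function(scene, geometry, n_time_bins = NULL) {
  stopifnot(inherits(geometry, "pa_geometry"))
  img <- if (inherits(scene, "pa_scene")) rasterize_scene(scene) else
    as_mat(scene, "scene")
  H <- nrow(img); W <- ncol(img)
  if (H < 2L || W < 2L) stop("degenerate grid", call. = FALSE)
  if (is.null(n_time_bins)) n_time_bins <- default_time_bins(H, W)
  n_time_bins <- as.integer(n_time_bins)
  dr <- 2 / max(H, W)
  pc <- pixel_coords(H, W)
  px <- as.vector(pc$x); py <- as.vector(pc$y)
  vals <- as.vector(img)
  E <- geometry$n_elements
  data <- matrix(0, E, n_time_bins)
  for (e in seq_len(E)) {
    d <- sqrt((px - geometry$positions[e, 1L])^2 +
                (py - geometry$positions[e, 2L])^2)
    bin <- pmin(pmax(as.integer(round(d / dr)), 1L), n_time_bins)
    acc <- rowsum(vals, bin)
    data[e, as.integer(rownames(acc))] <- acc
  }
  structure(list(data = data, n_elements = E, n_time_bins = n_time_bins,
                 dr = dr, sound_speed = 1),
            class = "pa_sinogram")
}

#' Delay-and-sum backprojection
#'
#' Each pixel averages, over elements, the sinogram value at the pixel's
#' nearest time-of-flight bin. The output is min-max normalized to \[0, 1\]
#' when its dynamic range is nonzero. With few elements the average is
#' supported on a few arcs per pixel, which is exactly the streak-artifact
#' pattern of sparse arrays.
#'
#' @param sinogram A `pa_sinogram` from [forward_project()].
#' @param geometry The matching geometry (same element count).
#' @param grid_size Output side length in pixels.
#' @export
das_reconstruct <- function(sinogram, geometry, grid_size) {
  stopifnot(inherits(sinogram, "pa_sinogram"),
            inherits(geometry, "pa_geometry"))
  if (sinogram$n_elements != geometry$n_elements)
    stop("sinogram and geometry element counts differ", call. = FALSE)
  H <- W <- as.integer(grid_size)
  pc <- pixel_coords(H, W)
  px <- as.vector(pc$x); py <- as.vector(pc$y)
  nb <- sinogram$n_time_bins
  acc <- numeric(H * W)
  for (e in seq_len(geometry$n_elements)) {
    d <- sqrt((px - geometry$positions[e, 1L])^2 +
                (py - geometry$positions[e, 2L])^2)
    bin <- pmin(pmax(as.integer(round(d / sinogram$dr)), 1L), nb)
    acc <- acc + sinogram$data[e, bin]
  }
  normalize01(matrix(acc / geometry$n_elements, H, W))
}

#' Densely sampled ground-truth image
#'
#' Reconstructs the scene with the full (dense) array, the regression
#' target for artifact removal; `mode = "phantom"` returns the noiseless
#' rasterized phantom instead.
#'
#' @param scene A [phantom_scene()].
#' @param geometry_dense Full-sampling geometry (e.g. ring-256/512).
#' @param grid_size Output side length in pixels.
#' @param mode `"das"` (default) or `"phantom"`.
#' @export
render_ground_truth <- function(scene, geometry_dense, grid_size,
                                mode = c("das", "phantom")) {
  mode <- match.arg(mode)
  if (mode == "phantom")
    return(normalize01(rasterize_scene(scene, grid_size)))
  sino <- forward_project(scene, geometry_dense)
  das_reconstruct(sino, geometry_dense, grid_size)
}

task_label <- function(task) paste0(task$kind, "-", task$n_sparse)

#' Simulate one paired sparse/dense image
#'
#' @param scene A [phantom_scene()].
#' @param task List with `kind`, `n_sparse`, `n_dense`.
#' @param grid_size Side length in pixels.
#' @param noise_sd Optional additive Gaussian noise on the sparse input
#'   (before normalization).
#' @param gt_mode Ground-truth convention, see [render_ground_truth()].
#' @return An `image_pair`: `input`, `target`, `meta`.
#' @export
simulate_pair <- function(scene, task, grid_size = 64L, noise_sd = 0,
                          gt_mode = "das") {
  dense <- make_geometry(task$kind, task$n_dense)
  sparse <- subsample_elements(dense, task$n_sparse)
  sino <- forward_project(scene, dense,
                          n_time_bins = default_time_bins(grid_size))
  sp_sino <- structure(list(data = sino$data[sparse$kept_idx, ,
                                             drop = FALSE],
                            n_elements = sparse$n_elements,
                            n_time_bins = sino$n_time_bins, dr = sino$dr,
                            sound_speed = 1), class = "pa_sinogram")
  input <- das_reconstruct(sp_sino, sparse, grid_size)
  if (noise_sd > 0)
    input <- normalize01(input + matrix(rnorm(length(input), 0, noise_sd),
                                        nrow(input)))
  target <- if (gt_mode == "das") das_reconstruct(sino, dense, grid_size)
  else normalize01(rasterize_scene(scene, grid_size))
  structure(list(input = input, target = target,
                 meta = list(geometry = task$kind,
                             n_sparse = task$n_sparse,
                             n_dense = task$n_dense,
                             task = task_label(task),
                             seed = scene$seed)),
            class = "image_pair")
}

split_groups <- function(n_groups, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  if (n_groups < 3L)
    stop("need at least 3 groups to form nonempty train/val/test splits",
         call. = FALSE)
  n_tr <- round(fractions[1L] * n_groups)
  n_va <- round(fractions[2L] * n_groups)
  n_te <- n_groups - n_tr - n_va
  # keep every split nonempty
  while (n_te < 1L) { n_tr <- n_tr - 1L; n_te <- n_te + 1L }
  while (n_va < 1L) { n_tr <- n_tr - 1L; n_va <- n_va + 1L }
  while (n_tr < 1L) {
    if (n_va > 1L) { n_va <- n_va - 1L } else { n_te <- n_te - 1L }
    n_tr <- n_tr + 1L
  }
  g <- seq_len(n_groups)
  list(train = g[seq_len(n_tr)],
       val = g[n_tr + seq_len(n_va)],
       test = g[n_tr + n_va + seq_len(n_te)])
}

#' Build a grouped paired dataset
#'
#' Generates `n_items` seeded scenes, simulates sparse input / dense
#' ground-truth pairs for the requested task, assigns items round-robin to
#' synthetic "patient" groups, and partitions whole groups into
#' train/validation/test so no group spans two splits (the patient-wise
#' split convention). The bundle is a pure function of `(arguments, seed)`.
#'
#' @param n_items Number of image pairs.
#' @param n_groups Number of groups (>= 3).
#' @param task List with `kind`, `n_sparse`, `n_dense`.
#' @param split_fractions Train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @param grid_size Image side length in pixels.
#' @param noise_sd Optional additive Gaussian input noise.
#' @param gt_mode Ground-truth convention, see [render_ground_truth()].
#' @return A `pa_dataset`: list of pairs, per-split index vectors, config.
#' @export
build_dataset <- function(n_items, n_groups,
                          task = list(kind = "ring", n_sparse = 32L,
                                      n_dense = 256L),
                          split_fractions = c(0.7, 0.2, 0.1), seed = 1L,
                          grid_size = 64L, noise_sd = 0, gt_mode = "das") {
  n_items <- as.integer(n_items)
  n_groups <- as.integer(n_groups)
  if (n_items < 1L) stop("zero-item request", call. = FALSE)
  if (n_groups > n_items) stop("'n_groups' must be <= 'n_items'",
                               call. = FALSE)
  gsplit <- split_groups(n_groups, split_fractions)
  group_of <- ((seq_len(n_items) - 1L) %% n_groups) + 1L
  pairs <- with_seed(seed, lapply(seq_len(n_items), function(i) {
    sc <- random_scene(grid_size)
    sc$seed <- seed
    p <- simulate_pair(sc, task, grid_size, noise_sd, gt_mode)
    p$meta$group_id <- group_of[i]
    p$meta$item <- i
    p
  }))
  split <- lapply(gsplit, function(gs) which(group_of %in% gs))
  structure(list(pairs = pairs, split = split, groups = group_of,
                 task = task,
                 config = list(n_items = n_items, n_groups = n_groups,
                               split_fractions = split_fractions,
                               seed = seed, grid_size = grid_size,
                               noise_sd = noise_sd, gt_mode = gt_mode)),
            class = "pa_dataset")
}

#' @export
print.pa_dataset <- function(x, ...) {
  cat(sprintf(
    "<pa_dataset> %d pairs (%s), %d groups, splits train/val/test = %d/%d/%d\n",
    length(x$pairs), task_label(x$task), x$config$n_groups,
    length(x$split$train), length(x$split$val), length(x$split$test)))
  invisible(x)
}

dataset_pairs <- function(bundle, split) bundle$pairs[bundle$split[[split]]]

#' Write a dataset bundle to disk
#'
#' Directory layout: `train/ val/ test/` holding paired
#' `item_%04d_input.png` / `item_%04d_target.png` files plus a
#' `manifest.json` recording per-item metadata, the split assignment and
#' the generation config (including the coordinate convention).
#'
#' @param bundle A [build_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pa_dataset"))
  for (s in names(bundle$split))
    dir.create(file.path(dir, s), recursive = TRUE, showWarnings = FALSE)
  items <- list()
  for (s in names(bundle$split)) {
    for (i in bundle$split[[s]]) {
      p <- bundle$pairs[[i]]
      fin <- file.path(s, sprintf("item_%04d_input.png", i))
      ftg <- file.path(s, sprintf("item_%04d_target.png", i))
      png::writePNG(pmin(pmax(p$input, 0), 1), file.path(dir, fin))
      png::writePNG(pmin(pmax(p$target, 0), 1), file.path(dir, ftg))
      items[[length(items) + 1L]] <- c(list(item = i, split = s,
                                            input = fin, target = ftg),
                                       p$meta)
    }
  }
  manifest <- list(format = "paomninet-dataset-v1",
                   coordinates = "pixel centres, origin at grid centre, y up",
                   config = bundle$config, task = bundle$task,
                   groups = bundle$groups, items = items)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A `pa_dataset` (image intensities quantized by the PNG codec).
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  n <- length(man$items)
  pairs <- vector("list", n)
  split <- list(train = integer(0), val = integer(0), test = integer(0))
  for (it in man$items) {
    i <- it$item
    pairs[[i]] <- structure(
      list(input = png::readPNG(file.path(dir, it$input)),
           target = png::readPNG(file.path(dir, it$target)),
           meta = it[setdiff(names(it), c("split", "input", "target"))]),
      class = "image_pair")
    split[[it$split]] <- c(split[[it$split]], i)
  }
  structure(list(pairs = pairs, split = split,
                 groups = unlist(man$groups), task = man$task,
                 config = man$config),
            class = "pa_dataset")
}
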