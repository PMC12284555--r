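#' @useDynLib paomninet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode differentiation tape.
#
# Values are either scalars or 3-D arrays [H, W, C] (single images are
# [H, W, 1]). Each op pushes a node holding the value, its parent ids and a
# backward closure mapping the node's upstream gradient to per-parent
# gradients. Gradients are only propagated into subgraphs that contain a
# parameter leaf (track flag), so constant inputs cost nothing on the way
# back. This is deliberately small: just the ops the reconstruction networks
# and the differentiable losses need.
# ---------------------------------------------------------------------------

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$parents <- list()
  tp$bwds <- list()
  tp$track <- logical(0)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = integer(0), backward = NULL,
                    track = FALSE) {
  id <- tp$n + 1L
  tp$n <- id
  tp$vals[[id]] <- value
  tp$parents[[id]] <- parents
  tp$bwds[[id]] <- backward
  tp$track[id] <- track
  id
}

tp_val <- function(tp, id) {
  force(id)  # nested op calls mutate tp before vals is fetched
  tp$vals[[id]]
}

tp_tracked <- function(tp, ids) any(tp$track[ids])

tp_const <- function(tp, value) tp_push(tp, value)

tp_param <- function(tp, value) tp_push(tp, value, track = TRUE)

#' @noRd
tp_backward <- function(tp, loss_id) {
  gr <- vector("list", tp$n)
  gr[[loss_id]] <- 1
  for (id in seq(tp$n, 1L)) {
    g <- gr[[id]]
    if (is.null(g) || is.null(tp$bwds[[id]])) next
    pg <- tp$bwds[[id]](g)
    ps <- tp$parents[[id]]
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      p <- ps[k]
      gr[[p]] <- if (is.null(gr[[p]])) pg[[k]] else gr[[p]] + pg[[k]]
    }
    gr[[id]] <- NULL  # free
  }
  gr
}

as_im <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

# -- elementwise ------------------------------------------------------------

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g) list(g, g), tp_tracked(tp, c(a, b)))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g) list(g, -g), tp_tracked(tp, c(a, b)))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  tp_push(tp, va * vb, c(a, b),
          function(g) list(g * vb, g * va), tp_tracked(tp, c(a, b)))
}

tp_div <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  tp_push(tp, va / vb, c(a, b),
          function(g) list(g / vb, -g * va / (vb * vb)),
          tp_tracked(tp, c(a, b)))
}

# value + constant scalar
tp_addc <- function(tp, a, cst) {
  force(a)
  tp_push(tp, tp$vals[[a]] + cst, a, function(g) list(g), tp$track[a])
}

# constant scalar * value
tp_scale <- function(tp, a, cst) {
  force(a)
  tp_push(tp, cst * tp$vals[[a]], a, function(g) list(cst * g), tp$track[a])
}

tp_square <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  tp_push(tp, va * va, a, function(g) list(2 * g * va), tp$track[a])
}

tp_sqrt <- function(tp, a, eps = 1e-12) {
  force(a)
  v <- sqrt(tp$vals[[a]] + eps)
  tp_push(tp, v, a, function(g) list(g / (2 * v)), tp$track[a])
}

tp_mean_all <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  n <- length(va)
  tp_push(tp, sum(va) / n, a,
          function(g) list(array(g / n, dim(va))), tp$track[a])
}

# -- activations ------------------------------------------------------------

tp_lrelu <- function(tp, a, slope = 0.01) {
  force(a)
  va <- tp$vals[[a]]
  dpos <- slope + (1 - slope) * (va > 0)
  tp_push(tp, va * dpos, a, function(g) list(g * dpos), tp$track[a])
}

tp_elu <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  pos <- va > 0
  v <- va * pos + (exp(pmin(va, 0)) - 1) * !pos
  tp_push(tp, v, a, function(g) list(g * (pos + (v + 1) * !pos)),
          tp$track[a])
}

# -- convolution ------------------------------------------------------------

# x: [H,W,Cin]; w: matrix [kh*kw*Cin, Cout]; b: vector [Cout]
tp_conv2d <- function(tp, x, w, b, kh = 3L, kw = kh, pad = (kh - 1L) %/% 2L) {
  force(x); force(w); force(b)
  vx <- tp$vals[[x]]; vw <- tp$vals[[w]]; vb <- tp$vals[[b]]
  y <- cpp_conv2d(vx, vw, vb, kh, kw, pad)
  need_gx <- tp$track[x]
  need_gw <- tp$track[w] || tp$track[b]
  tp_push(tp, y, c(x, w, b), function(g) {
    if (!need_gx && !need_gw) return(list(NULL, NULL, NULL))
    r <- cpp_conv2d_bwd(vx, vw, as_im(g), kh, kw, pad, need_gx, need_gw)
    list(if (need_gx) r$gx else NULL,
         if (need_gw) r$gw else NULL,
         if (need_gw) as.numeric(r$gb) else NULL)
  }, need_gx || need_gw)
}

# -- channel concat / set mean ----------------------------------------------

tp_concat_c <- function(tp, ids) {
  force(ids)
  vs <- lapply(ids, function(i) tp$vals[[i]])
  d <- dim(vs[[1L]])
  ncs <- vapply(vs, function(v) dim(v)[3L], integer(1))
  out <- array(unlist(vs, use.names = FALSE), c(d[1L], d[2L], sum(ncs)))
  ends <- cumsum(ncs)
  starts <- c(1L, head(ends, -1L) + 1L)
  tp_push(tp, out, ids, function(g) {
    lapply(seq_along(ids), function(k)
      g[, , starts[k]:ends[k], drop = FALSE])
  }, tp_tracked(tp, ids))
}

tp_mean_list <- function(tp, ids) {
  force(ids)
  vs <- lapply(ids, function(i) tp$vals[[i]])
  m <- Reduce(`+`, vs) / length(ids)
  k <- length(ids)
  tp_push(tp, m, as.integer(ids), function(g) {
    gk <- g / k
    rep(list(gk), k)
  }, tp_tracked(tp, ids))
}

# -- resizing ----------------------------------------------------------------

.resize_cache <- new.env(parent = emptyenv())

# 2x average-pool downsampling matrix (H/2 x H)
down_mat <- function(H) {
  key <- paste0("d", H)
  m <- .resize_cache[[key]]
  if (is.null(m)) {
    stopifnot(H %% 2L == 0L)
    m <- matrix(0, H %/% 2L, H)
    idx <- seq_len(H %/% 2L)
    m[cbind(idx, 2L * idx - 1L)] <- 0.5
    m[cbind(idx, 2L * idx)] <- 0.5
    .resize_cache[[key]] <- m
  }
  m
}

# factor-2 bilinear upsampling matrix (2H x H), half-pixel-centre convention
up_mat <- function(H) {
  key <- paste0("u", H)
  m <- .resize_cache[[key]]
  if (is.null(m)) {
    m <- matrix(0, 2L * H, H)
    for (i in seq_len(2L * H)) {
      src <- (i - 1 + 0.5) / 2 - 0.5
      lo <- floor(src)
      f <- src - lo
      lo <- max(min(lo, H - 1), 0)
      hi <- min(lo + 1, H - 1)
      m[i, lo + 1] <- m[i, lo + 1] + (1 - f)
      m[i, hi + 1] <- m[i, hi + 1] + f
    }
    .resize_cache[[key]] <- m
  }
  m
}

apply_sep <- function(x, Mh, Mw) {
  d <- dim(x)
  out <- array(0, c(nrow(Mh), nrow(Mw), d[3L]))
  for (c in seq_len(d[3L]))
    out[, , c] <- Mh %*% x[, , c] %*% t(Mw)
  out
}

tp_resize <- function(tp, a, mode = c("none", "down", "up")) {
  force(a)
  mode <- match.arg(mode)
  if (mode == "none") return(a)
  va <- tp$vals[[a]]
  d <- dim(va)
  if (mode == "down") {
    Mh <- down_mat(d[1L]); Mw <- down_mat(d[2L])
  } else {
    Mh <- up_mat(d[1L]); Mw <- up_mat(d[2L])
  }
  tp_push(tp, apply_sep(va, Mh, Mw), a,
          function(g) list(apply_sep(as_im(g), t(Mh), t(Mw))),
          tp$track[a])
}
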