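# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# A computation builds an implicit tape of nodes (environments holding a
# value, a list of parent nodes and a backward function); `ad_backward()`
# topologically sorts the tape and accumulates gradients into every
# parameter node. The op set is exactly what the registration and
# segmentation networks in this package need: 2D convolution (im2col),
# gated/element-wise arithmetic, channel normalisation, pooling, bilinear
# up-sampling and warping, all-pairs correlation with windowed lookups,
# row-softmax attention and the usual reductions. Feature maps are
# (H, W, C) arrays; convolution weights are (kh, kw, Cin, Cout).
#
# The engine favours clarity over speed but is vectorised throughout; the
# intended scale is 32x32 phantine frames with tens of channels, where a
# training step costs a few hundredths of a second.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$n <- 0

new_node <- function(value, parents = list(), backfn = NULL, is_param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value; e$grad <- NULL
  e$parents <- parents; e$backfn <- backfn
  e$is_param <- is_param
  .ad_counter$n <- .ad_counter$n + 1
  e$id <- .ad_counter$n
  class(e) <- "ad_node"
  e
}

#' Create autodiff nodes
#'
#' `ad_param()` wraps an array as a trainable parameter (gradients are
#' accumulated into it by [ad_backward()]); `ad_const()` wraps a fixed
#' input; `ad_value()` extracts the numeric value of a node (and passes
#' plain arrays through).
#'
#' @param x numeric array or `ad_node`.
#' @return an `ad_node` (or array for `ad_value`).
#' @export
ad_param <- function(x) new_node(x, is_param = TRUE)

#' @rdname ad_param
#' @export
ad_const <- function(x) new_node(x)

#' @rdname ad_param
#' @export
ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

as_node <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

#' Run backpropagation from a scalar loss node
#'
#' Topologically sorts the tape reachable from `root` and accumulates
#' gradients into every node; parameter nodes keep their `$grad` field for
#' the optimizer.
#'
#' @param root scalar-valued `ad_node`.
#' @export
ad_backward <- function(root) {
  # iterative DFS topological order
  topo <- vector("list", 256); n_topo <- 0L
  stack <- list(list(node = root, i = 0L))
  seen <- new.env(parent = emptyenv())
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    node <- top$node
    kids <- node$parents
    if (top$i < length(kids)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- kids[[top$i + 1L]]
      ck <- as.character(child$id)
      if (is.null(seen[[ck]])) {
        seen[[ck]] <- TRUE
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
      }
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  if (length(root$value) != 1) stop("ad_backward expects a scalar root")
  root$grad <- 1
  for (k in seq(n_topo, 1L)) {
    node <- topo[[k]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    pgrads <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is.null(pgrads[[j]])) next
      p$grad <- if (is.null(p$grad)) pgrads[[j]] else p$grad + pgrads[[j]]
    }
  }
  invisible(root)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- arithmetic ------------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  new_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  a <- as_node(a)
  new_node(a$value * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(av %*% bv, list(a, b),
           function(g) list(g %*% t(bv), t(av) %*% g))
}

# ---- nonlinearities --------------------------------------------------------

ad_relu <- function(a) {
  a <- as_node(a); m <- a$value > 0
  new_node(a$value * m, list(a), function(g) list(g * m))
}

ad_tanh <- function(a) {
  a <- as_node(a); y <- tanh(a$value)
  new_node(y, list(a), function(g) list(g * (1 - y^2)))
}

ad_sigmoid <- function(a) {
  a <- as_node(a); y <- 1 / (1 + exp(-a$value))
  new_node(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_abs <- function(a, eps = 1e-8) {
  a <- as_node(a); y <- sqrt(a$value^2 + eps)
  new_node(y, list(a), function(g) list(g * a$value / y))
}

ad_square <- function(a) ad_mul(a, a)

# ---- reductions ------------------------------------------------------------

ad_mean <- function(a) {
  a <- as_node(a); n <- length(a$value)
  new_node(mean(a$value), list(a),
           function(g) list(array(as.numeric(g) / n, dim(a$value) %||% length(a$value))))
}

ad_sum <- function(a) {
  a <- as_node(a)
  new_node(sum(a$value), list(a),
           function(g) list(array(as.numeric(g), dim(a$value) %||% length(a$value))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- shape ops -------------------------------------------------------------

ad_concat_c <- function(...) {
  nodes <- lapply(list(...), as_node)
  vals <- lapply(nodes, function(n) n$value)
  dims <- lapply(vals, function(v) dim(v))
  H <- dims[[1]][1]; W <- dims[[1]][2]
  chans <- vapply(dims, function(d) if (length(d) == 3) d[3] else 1L, numeric(1))
  out <- array(0, c(H, W, sum(chans)))
  off <- 0
  for (i in seq_along(vals)) {
    out[, , off + seq_len(chans[i])] <- vals[[i]]
    off <- off + chans[i]
  }
  offsets <- cumsum(c(0, chans))
  new_node(out, nodes, function(g) {
    lapply(seq_along(nodes), function(i) {
      gi <- g[, , offsets[i] + seq_len(chans[i]), drop = FALSE]
      if (length(dims[[i]]) == 2) dim(gi) <- dims[[i]]
      gi
    })
  })
}

ad_slice_c <- function(a, idx) {
  a <- as_node(a)
  d <- dim(a$value)
  new_node(a$value[, , idx, drop = FALSE], list(a), function(g) {
    out <- array(0, d)
    out[, , idx] <- g
    list(out)
  })
}

ad_reshape <- function(a, new_dim) {
  a <- as_node(a); old <- dim(a$value) %||% length(a$value)
  v <- a$value; dim(v) <- new_dim
  new_node(v, list(a), function(g) { dim(g) <- old; list(g) })
}

# ---- convolution (im2col) --------------------------------------------------

.conv_idx_cache <- new.env(parent = emptyenv())

conv_patch_index <- function(H, W, C, kh, kw) {
  key <- paste(H, W, C, kh, kw, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  Hp <- H + 2 * ph; Wp <- W + 2 * pw
  # linear indices into the zero-padded (Hp, Wp, C) array for every output
  # pixel (row-fastest over H, then W) and every (dkh, dkw, c) patch entry
  out_r <- rep(seq_len(H), times = W); out_c <- rep(seq_len(W), each = H)
  npix <- H * W
  cols <- kh * kw * C
  idx <- matrix(0L, npix, cols)
  col <- 0L
  for (c in seq_len(C)) for (dw in seq_len(kw)) for (dh in seq_len(kh)) {
    col <- col + 1L
    rr <- out_r + dh - 1L           # position in padded array
    cc <- out_c + dw - 1L
    idx[, col] <- rr + (cc - 1L) * Hp + (c - 1L) * (Hp * Wp)
  }
  res <- list(idx = idx, Hp = Hp, Wp = Wp, ph = ph, pw = pw)
  .conv_idx_cache[[key]] <- res
  res
}

#' 2D convolution node (same padding, stride 1)
#'
#' @param x `ad_node` with an (H, W, Cin) value (a matrix is treated as
#'   (H, W, 1)).
#' @param w `ad_node` with a (kh, kw, Cin, Cout) kernel.
#' @param b optional `ad_node` with a length-Cout bias.
#' @return `ad_node` with an (H, W, Cout) value.
#' @keywords internal
im2col <- function(xv, kh, kw) {
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]
  ci <- conv_patch_index(H, W, C, kh, kw)
  xp <- array(0, c(ci$Hp, ci$Wp, C))
  xp[ci$ph + seq_len(H), ci$pw + seq_len(W), ] <- xv
  v <- xp[ci$idx]
  dim(v) <- c(H * W, kh * kw * C)
  v
}

# kernel with flipped spatial taps and swapped channel axes: convolving the
# output gradient with it yields the input gradient (zero padding, stride 1)
flip_kernel <- function(wv) {
  wd <- dim(wv)
  wt <- wv[wd[1]:1, wd[2]:1, , , drop = FALSE]
  aperm(wt, c(1, 2, 4, 3))
}

ad_conv2d <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  xv <- x$value
  if (length(dim(xv)) == 2) dim(xv) <- c(dim(xv), 1)
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]
  wd <- dim(w$value); kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  stopifnot(wd[3] == C)
  one_by_one <- kh == 1 && kw == 1
  colmat <- if (one_by_one) { v <- xv; dim(v) <- c(H * W, C); v }
            else im2col(xv, kh, kw)
  wmat <- matrix(w$value, ncol = Cout)
  out <- colmat %*% wmat
  if (!is.null(b)) { b <- as_node(b); out <- out + rep(b$value, each = H * W) }
  dim(out) <- c(H, W, Cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(out, parents, function(g) {
    gm <- g; dim(gm) <- c(H * W, Cout)
    dW <- crossprod(colmat, gm); dim(dW) <- wd
    if (one_by_one) {
      dx <- gm %*% t(wmat)
    } else {
      wt <- matrix(flip_kernel(w$value), ncol = C)
      dx <- im2col(g, kh, kw) %*% wt
    }
    dim(dx) <- if (length(dim(x$value)) == 2) dim(x$value) else d
    res <- list(dx, dW)
    if (!is.null(b)) res <- c(res, list(colSums(gm)))
    res
  })
}

# depth-wise large-kernel convolution: one (kh, kw) filter per channel;
# implemented on the shared im2col machinery with per-channel matmuls
ad_conv2d_depthwise <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  wd <- dim(w$value); kh <- wd[1]; kw <- wd[2]
  stopifnot(wd[3] == C)
  colmat <- im2col(x$value, kh, kw)        # (HW, kh*kw*C)
  k2 <- kh * kw
  out <- array(0, c(H, W, C))
  for (c in seq_len(C)) {
    sel <- (c - 1) * k2 + seq_len(k2)
    out[, , c] <- colmat[, sel, drop = FALSE] %*% as.vector(w$value[, , c])
  }
  if (!is.null(b)) {
    b <- as_node(b)
    out <- out + rep(b$value, each = H * W)
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(out, parents, function(g) {
    dW <- array(0, wd)
    gcol <- im2col(g, kh, kw)              # same layout as colmat
    dx <- array(0, d)
    for (c in seq_len(C)) {
      sel <- (c - 1) * k2 + seq_len(k2)
      gc <- as.vector(g[, , c])
      dW[, , c] <- matrix(crossprod(colmat[, sel, drop = FALSE], gc), kh, kw)
      wf <- as.vector(w$value[kh:1, kw:1, c])
      dx[, , c] <- gcol[, sel, drop = FALSE] %*% wf
    }
    res <- list(dx, dW)
    if (!is.null(b)) res <- c(res, list(apply(g, 3, sum)))
    res
  })
}

# transposed convolution, kernel 2, stride 2 (the classic U-Net up-conv):
# each input pixel expands into a 2x2 output block through 4 weight taps
ad_convtranspose2 <- function(x, w, b = NULL) {
  x <- as_node(x); w <- as_node(w)
  d <- dim(x$value); H <- d[1]; W <- d[2]; Cin <- d[3]
  wd <- dim(w$value); Cout <- wd[4]
  stopifnot(wd[1] == 2, wd[2] == 2, wd[3] == Cin)
  xm <- matrix(x$value, H * W, Cin)
  out <- array(0, c(2 * H, 2 * W, Cout))
  for (di in 1:2) for (dj in 1:2) {
    blk <- xm %*% matrix(w$value[di, dj, , ], Cin, Cout)
    dim(blk) <- c(H, W, Cout)
    out[seq(di, 2 * H, 2), seq(dj, 2 * W, 2), ] <- blk
  }
  if (!is.null(b)) { b <- as_node(b); out <- out + rep(b$value, each = 4 * H * W) }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  new_node(out, parents, function(g) {
    dx <- matrix(0, H * W, Cin); dW <- array(0, wd)
    for (di in 1:2) for (dj in 1:2) {
      gs <- g[seq(di, 2 * H, 2), seq(dj, 2 * W, 2), , drop = FALSE]
      gm <- matrix(gs, H * W, Cout)
      dx <- dx + gm %*% t(matrix(w$value[di, dj, , ], Cin, Cout))
      dW[di, dj, , ] <- crossprod(xm, gm)
    }
    dim(dx) <- d
    res <- list(dx, dW)
    if (!is.null(b)) res <- c(res, list(apply(g, 3, sum)))
    res
  })
}

# ---- normalisation ---------------------------------------------------------

# per-channel normalisation over spatial positions with learned affine;
# the batch-norm realisation at the single-sample granularity this engine
# operates at
ad_channel_norm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]; n <- H * W
  xm <- matrix(x$value, n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  out <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  dim(out) <- d
  new_node(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    gy <- sweep(gm, 2, gamma$value, "*")
    m1 <- colMeans(gy); m2 <- colMeans(gy * xhat)
    dx <- sweep(gy, 2, m1) - sweep(xhat, 2, m2, "*")
    dx <- sweep(dx, 2, istd, "*")
    dim(dx) <- d
    list(dx, dgamma, dbeta)
  })
}

# ---- pooling / resampling --------------------------------------------------

ad_avgpool2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  v <- x$value
  out <- (v[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
            v[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
            v[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
            v[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
  new_node(out, list(x), function(g) {
    dx <- array(0, d)
    gq <- g / 4
    dx[seq(1, H, 2), seq(1, W, 2), ] <- gq
    dx[seq(2, H, 2), seq(1, W, 2), ] <- dx[seq(2, H, 2), seq(1, W, 2), ] + gq
    dx[seq(1, H, 2), seq(2, W, 2), ] <- dx[seq(1, H, 2), seq(2, W, 2), ] + gq
    dx[seq(2, H, 2), seq(2, W, 2), ] <- dx[seq(2, H, 2), seq(2, W, 2), ] + gq
    list(dx)
  })
}

ad_maxpool2 <- function(x) {
  x <- as_node(x)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  v <- x$value
  cand <- array(0, c(H / 2, W / 2, C, 4))
  cand[, , , 1] <- v[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  cand[, , , 2] <- v[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  cand[, , , 3] <- v[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  cand[, , , 4] <- v[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  out <- apply(cand, c(1, 2, 3), max)
  amax <- apply(cand, c(1, 2, 3), which.max)
  new_node(out, list(x), function(g) {
    dx <- array(0, d)
    for (q in 1:4) {
      m <- (amax == q) * g
      ri <- if (q %in% c(1, 3)) seq(1, H, 2) else seq(2, H, 2)
      ci2 <- if (q %in% c(1, 2)) seq(1, W, 2) else seq(2, W, 2)
      dx[ri, ci2, ] <- dx[ri, ci2, ] + m
    }
    list(dx)
  })
}

.upsample_cache <- new.env(parent = emptyenv())

upsample_weights <- function(H, W, f) {
  key <- paste(H, W, f, sep = "_")
  hit <- .upsample_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H * f; Wo <- W * f
  # output pixel centres mapped into input coordinates (align-corners off)
  rs <- (seq_len(Ho) - 0.5) / f + 0.5   # centre alignment
  cs <- (seq_len(Wo) - 0.5) / f + 0.5
  rs <- clamp(rs, 1, H); cs <- clamp(cs, 1, W)
  r0 <- clamp(floor(rs), 1, H); r1 <- clamp(r0 + 1, 1, H); wr <- rs - r0
  c0 <- clamp(floor(cs), 1, W); c1 <- clamp(c0 + 1, 1, W); wc <- cs - c0
  res <- list(r0 = r0, r1 = r1, wr = wr, c0 = c0, c1 = c1, wc = wc,
              Ho = Ho, Wo = Wo)
  .upsample_cache[[key]] <- res
  res
}

# bilinear up-sampling by integer factor f (separable fixed linear map)
ad_upsample_bilinear <- function(x, f) {
  x <- as_node(x)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- if (length(d) == 3) d[3] else 1L
  u <- upsample_weights(H, W, f)
  # row interpolation matrix (Ho x H) and column matrix (Wo x W)
  Rm <- matrix(0, u$Ho, H); Cm <- matrix(0, u$Wo, W)
  Rm[cbind(seq_len(u$Ho), u$r0)] <- Rm[cbind(seq_len(u$Ho), u$r0)] + (1 - u$wr)
  Rm[cbind(seq_len(u$Ho), u$r1)] <- Rm[cbind(seq_len(u$Ho), u$r1)] + u$wr
  Cm[cbind(seq_len(u$Wo), u$c0)] <- Cm[cbind(seq_len(u$Wo), u$c0)] + (1 - u$wc)
  Cm[cbind(seq_len(u$Wo), u$c1)] <- Cm[cbind(seq_len(u$Wo), u$c1)] + u$wc
  xv <- x$value; if (length(d) == 2) dim(xv) <- c(d, 1)
  out <- array(0, c(u$Ho, u$Wo, C))
  for (c in seq_len(C)) out[, , c] <- Rm %*% xv[, , c] %*% t(Cm)
  if (length(d) == 2) dim(out) <- c(u$Ho, u$Wo)
  new_node(out, list(x), function(g) {
    gv <- g; if (length(d) == 2) dim(gv) <- c(u$Ho, u$Wo, 1)
    dx <- array(0, c(H, W, C))
    for (c in seq_len(C)) dx[, , c] <- t(Rm) %*% gv[, , c] %*% Cm
    if (length(d) == 2) dim(dx) <- d
    list(dx)
  })
}

# ---- differentiable bilinear warping --------------------------------------

# backward warp of (H, W, C) features by an (H, W, 2) flow node, with
# gradients to both the features and the flow; edge-clamped sampling
ad_warp <- function(x, flow) {
  x <- as_node(x); flow <- as_node(flow)
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- if (length(d) == 3) d[3] else 1L
  xv <- x$value; if (length(d) == 2) dim(xv) <- c(d, 1)
  g <- grid_coords(H, W)
  rs_raw <- g$r + flow$value[, , 1]; cs_raw <- g$c + flow$value[, , 2]
  in_r <- rs_raw >= 1 & rs_raw <= H; in_c <- cs_raw >= 1 & cs_raw <= W
  rs <- clamp(rs_raw, 1, H); cs <- clamp(cs_raw, 1, W)
  r0 <- clamp(floor(rs), 1, H); r1 <- clamp(r0 + 1, 1, H); wr <- rs - r0
  c0 <- clamp(floor(cs), 1, W); c1 <- clamp(c0 + 1, 1, W); wc <- cs - c0
  i00 <- r0 + (c0 - 1) * H; i10 <- r1 + (c0 - 1) * H
  i01 <- r0 + (c1 - 1) * H; i11 <- r1 + (c1 - 1) * H
  w00 <- (1 - wr) * (1 - wc); w10 <- wr * (1 - wc)
  w01 <- (1 - wr) * wc;       w11 <- wr * wc
  out <- array(0, c(H, W, C))
  for (c in seq_len(C)) {
    xc <- xv[, , c]
    out[, , c] <- w00 * xc[i00] + w10 * xc[i10] + w01 * xc[i01] + w11 * xc[i11]
  }
  if (length(d) == 2) dim(out) <- c(H, W)
  new_node(out, list(x, flow), function(gr) {
    grv <- gr; if (length(d) == 2) dim(grv) <- c(H, W, 1)
    dx <- array(0, c(H, W, C))
    dflow <- array(0, c(H, W, 2))
    for (c in seq_len(C)) {
      gc <- grv[, , c]
      xc <- xv[, , c]
      # gradient wrt features: scatter the bilinear weights (the appended
      # zero block makes rowsum return every pixel, already ordered)
      acc <- rowsum(c(gc * w00, gc * w10, gc * w01, gc * w11, numeric(H * W)),
                    group = c(i00, i10, i01, i11, seq_len(H * W)))
      dx[, , c] <- dx[, , c] + matrix(acc, H, W)
      # gradient wrt flow: image gradient at the sample point
      dI_dr <- (1 - wc) * (xc[i10] - xc[i00]) + wc * (xc[i11] - xc[i01])
      dI_dc <- (1 - wr) * (xc[i01] - xc[i00]) + wr * (xc[i11] - xc[i10])
      dflow[, , 1] <- dflow[, , 1] + gc * dI_dr * in_r
      dflow[, , 2] <- dflow[, , 2] + gc * dI_dc * in_c
    }
    if (length(d) == 2) dim(dx) <- d
    list(dx, dflow)
  })
}

# ---- correlation volumes ---------------------------------------------------

# all-pairs scaled dot products between two (N, C) feature matrices:
# corr[i, j] = <f1[i, ], f2[j, ]> / sqrt(C)
ad_correlation <- function(f1, f2) {
  f1 <- as_node(f1); f2 <- as_node(f2)
  s <- 1 / sqrt(ncol(f1$value))
  ad_scale(ad_matmul(f1, new_node(t(f2$value), list(f2),
                                  function(g) list(t(g)))), s)
}

# average-pool the target dimensions of an (N, Hl*Wl) correlation matrix
ad_pool_corr <- function(corr, Hl, Wl) {
  corr <- as_node(corr)
  N <- nrow(corr$value)
  H2 <- Hl %/% 2; W2 <- Wl %/% 2
  sel <- function(ri, ci) {
    r <- seq(ri, Hl, 2)[seq_len(H2)]; c <- seq(ci, Wl, 2)[seq_len(W2)]
    as.vector(outer(r, (c - 1) * Hl, "+"))
  }
  s1 <- sel(1, 1); s2 <- sel(2, 1); s3 <- sel(1, 2); s4 <- sel(2, 2)
  out <- (corr$value[, s1, drop = FALSE] + corr$value[, s2, drop = FALSE] +
            corr$value[, s3, drop = FALSE] + corr$value[, s4, drop = FALSE]) / 4
  new_node(out, list(corr), function(g) {
    dc <- matrix(0, N, Hl * Wl)
    dc[, s1] <- g / 4; dc[, s2] <- dc[, s2] + g / 4
    dc[, s3] <- dc[, s3] + g / 4; dc[, s4] <- dc[, s4] + g / 4
    list(dc)
  })
}

# windowed bilinear lookup into an (N, Hl*Wl) correlation level at
# per-query fractional centres (N vectors rs, cs) with offsets
# (-radius..radius)^2 in level coordinates; returns (N, (2r+1)^2);
# differentiable wrt the correlation entries and the centres
ad_corr_lookup <- function(corr, Hl, Wl, rc_node, radius) {
  corr <- as_node(corr); rc_node <- as_node(rc_node)  # rc: (N, 2)
  N <- nrow(corr$value)
  offs <- seq(-radius, radius)
  K <- length(offs)^2
  og <- expand.grid(dr = offs, dc = offs)
  rs <- outer(rc_node$value[, 1], og$dr, "+")   # (N, K)
  cs <- outer(rc_node$value[, 2], og$dc, "+")
  in_r <- rs >= 1 & rs <= Hl; in_c <- cs >= 1 & cs <= Wl
  rs <- clamp(rs, 1, Hl); cs <- clamp(cs, 1, Wl)
  r0 <- clamp(floor(rs), 1, Hl); r1 <- clamp(r0 + 1, 1, Hl); wr <- rs - r0
  c0 <- clamp(floor(cs), 1, Wl); c1 <- clamp(c0 + 1, 1, Wl); wc <- cs - c0
  nidx <- matrix(seq_len(N), N, K)
  lin <- function(r, c) (r - 1 + (c - 1) * Hl) * N + nidx
  i00 <- lin(r0, c0); i10 <- lin(r1, c0); i01 <- lin(r0, c1); i11 <- lin(r1, c1)
  cv <- corr$value
  w00 <- (1 - wr) * (1 - wc); w10 <- wr * (1 - wc)
  w01 <- (1 - wr) * wc;       w11 <- wr * wc
  out <- w00 * cv[i00] + w10 * cv[i10] + w01 * cv[i01] + w11 * cv[i11]
  dim(out) <- c(N, K)
  new_node(out, list(corr, rc_node), function(g) {
    ntot <- N * Hl * Wl
    acc <- rowsum(c(g * w00, g * w10, g * w01, g * w11, numeric(ntot)),
                  group = c(i00, i10, i01, i11, seq_len(ntot)))
    dcorr <- as.vector(acc)
    dim(dcorr) <- c(N, Hl * Wl)
    dC_dr <- (1 - wc) * (cv[i10] - cv[i00]) + wc * (cv[i11] - cv[i01])
    dC_dc <- (1 - wr) * (cv[i01] - cv[i00]) + wr * (cv[i11] - cv[i10])
    drc <- cbind(rowSums(g * dC_dr * in_r), rowSums(g * dC_dc * in_c))
    list(dcorr, drc)
  })
}

# ---- softmax ---------------------------------------------------------------

# row softmax of a matrix (used for attention over key positions)
ad_softmax_rows <- function(a) {
  a <- as_node(a)
  m <- a$value - apply(a$value, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  new_node(y, list(a), function(g) {
    list(y * (g - rowSums(g * y)))
  })
}

# channel softmax of an (H, W, C) array (per-pixel class probabilities)
ad_softmax_c <- function(a) {
  a <- as_node(a)
  d <- dim(a$value)
  m <- apply(a$value, c(1, 2), max)
  e <- exp(a$value - as.vector(m))
  s <- apply(e, c(1, 2), sum)
  y <- e / as.vector(s)
  new_node(y, list(a), function(g) {
    dot <- apply(g * y, c(1, 2), sum)
    list(y * (g - as.vector(dot)))
  })
}

# ---- optimizer -------------------------------------------------------------

#' AdamW optimizer state
#'
#' Decoupled weight decay Adam over a flat list of parameter nodes, with
#' an optional cosine-annealed learning rate.
#'
#' @param params list of parameter nodes (`ad_param`).
#' @param lr base learning rate.
#' @param betas Adam moment decays.
#' @param eps numerical floor.
#' @param weight_decay decoupled decay coefficient.
#' @param clip_norm global gradient-norm clip (NULL disables); the usual
#'   stabiliser for recurrent flow networks.
#' @return an optimizer environment with `$step()` and `$zero_grad()`.
#' @export
adamw <- function(params, lr = 1e-4, betas = c(0.9, 0.999), eps = 1e-8,
                  weight_decay = 5e-4, clip_norm = 1) {
  st <- new.env(parent = emptyenv())
  st$params <- params; st$lr <- lr; st$betas <- betas; st$eps <- eps
  st$wd <- weight_decay; st$t <- 0L; st$clip <- clip_norm
  st$m <- lapply(params, function(p) array(0, dim(p$value) %||% length(p$value)))
  st$v <- st$m
  st$step <- function(lr_now = NULL) {
    st$t <- st$t + 1L
    lr_t <- lr_now %||% st$lr
    b1 <- st$betas[1]; b2 <- st$betas[2]
    if (!is.null(st$clip)) {
      gn <- sqrt(sum(vapply(st$params, function(p)
        if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1))))
      if (is.finite(gn) && gn > st$clip) {
        sc <- st$clip / gn
        for (p in st$params) if (!is.null(p$grad)) p$grad <- p$grad * sc
      }
    }
    for (i in seq_along(st$params)) {
      p <- st$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
      st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g^2
      mhat <- st$m[[i]] / (1 - b1^st$t)
      vhat <- st$v[[i]] / (1 - b2^st$t)
      p$value <- p$value - lr_t * (mhat / (sqrt(vhat) + st$eps) + st$wd * p$value)
    }
  }
  st$zero_grad <- function() ad_zero_grads(st$params)
  st
}

#' Cosine-annealed learning rate
#'
#' @param step current step (1-based).
#' @param total total steps.
#' @param lr_max base learning rate.
#' @param lr_min floor learning rate.
#' @return learning rate for this step.
#' @export
cosine_lr <- function(step, total, lr_max, lr_min = lr_max / 100) {
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * (step - 1) / max(total - 1, 1)))
}
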