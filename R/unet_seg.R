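# 2D U-Net segmentation of cine frames into four classes (background, LV
# blood pool, myocardium, RV blood pool), plus pseudo-label generation by
# warping manual end-systolic/end-diastolic masks along estimated motion.

#' U-Net configuration
#'
#' The default arranges eight convolutional blocks over five resolution
#' levels with widths doubling from `base_filters` and capped at
#' `max_filters` (32 to 512 in the default profile); the `"tiny"` profile
#' (3 levels, 8 base filters) is sized for CPU-scale phantom training.
#'
#' @param profile `"tiny"` or `"default"`.
#' @param ... named overrides (`n_levels`, `base_filters`, `max_filters`,
#'   `n_classes`, `seed`).
#' @return a `unet_config` list.
#' @export
unet_config <- function(profile = c("tiny", "default"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "tiny")
    list(n_levels = 3L, base_filters = 8L, max_filters = 32L,
         n_classes = 4L, seed = 1L)
  else
    list(n_levels = 5L, base_filters = 32L, max_filters = 512L,
         n_classes = 4L, seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg$profile <- profile
  structure(cfg, class = "unet_config")
}

unet_widths <- function(cfg)
  pmin(cfg$base_filters * 2^(seq_len(cfg$n_levels) - 1), cfg$max_filters)

#' Build a U-Net model
#'
#' Contracting path of 3x3 convolutions with ReLU and per-channel
#' normalisation and max-pool downsampling; expansive path with 2x2
#' transposed-convolution upsampling and skip concatenation; a final 1x1
#' convolution with `n_classes` filters and per-pixel softmax produces a
#' probabilistic mask. Inputs whose sides are not divisible by
#' `2^(n_levels - 1)` are zero-padded internally and cropped back.
#'
#' @param cfg a [unet_config()].
#' @return a `unet_model` list with `weights` and `cfg`.
#' @export
build_unet <- function(cfg = unet_config()) {
  set.seed(cfg$seed)
  wd <- unet_widths(cfg)
  L <- cfg$n_levels
  enc <- vector("list", L)
  cin <- 1L
  for (l in seq_len(L)) {
    # two conv blocks on the shallower levels, one on the deepest two
    n_conv <- if (l <= max(1, L - 2)) 2L else 1L
    blocks <- vector("list", n_conv)
    for (i in seq_len(n_conv)) {
      blocks[[i]] <- list(w = he_init(3, 3, cin, wd[l]),
                          b = ad_param(numeric(wd[l])),
                          g = ad_param(rep(1, wd[l])),
                          be = ad_param(numeric(wd[l])))
      cin <- wd[l]
    }
    enc[[l]] <- blocks
  }
  dec <- vector("list", L - 1)
  for (l in seq_len(L - 1)) {
    lev <- L - l                       # decoder level producing width wd[lev]
    dec[[l]] <- list(
      up = list(w = he_init(2, 2, wd[lev + 1], wd[lev]),
                b = ad_param(numeric(wd[lev]))),
      conv = list(w = he_init(3, 3, 2 * wd[lev], wd[lev]),
                  b = ad_param(numeric(wd[lev])),
                  g = ad_param(rep(1, wd[lev])),
                  be = ad_param(numeric(wd[lev]))))
  }
  head <- list(w = he_init(1, 1, wd[1], cfg$n_classes),
               b = ad_param(numeric(cfg$n_classes)))
  structure(list(weights = list(enc = enc, dec = dec, head = head),
                 cfg = cfg),
            class = "unet_model")
}

unet_params <- function(model) mopnet_params(model$weights)

conv_bn_relu <- function(x, blk) {
  h <- ad_conv2d(x, blk$w, blk$b)
  ad_relu(ad_channel_norm(h, blk$g, blk$be))
}

#' U-Net forward pass
#'
#' @param model a `unet_model`.
#' @param image (H, W) matrix; min-max normalised to \[-1, 1\] internally.
#' @return an `ad_node` with (H, W, n_classes) per-pixel probabilities
#'   summing to 1.
#' @export
unet_forward <- function(model, image) {
  if (any(!is.finite(image))) stop("non-finite values in segmentation input")
  cfg <- model$cfg; w <- model$weights
  L <- cfg$n_levels
  H <- nrow(image); W <- ncol(image)
  div <- 2^(L - 1)
  Hp <- ceiling(H / div) * div; Wp <- ceiling(W / div) * div
  rng <- range(image)
  img <- if (diff(rng) > 0) 2 * (image - rng[1]) / diff(rng) - 1 else image * 0
  pad <- matrix(0, Hp, Wp)
  pad[seq_len(H), seq_len(W)] <- img
  x <- ad_const(array(pad, c(Hp, Wp, 1)))
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    for (blk in w$enc[[l]]) x <- conv_bn_relu(x, blk)
    skips[[l]] <- x
    if (l < L) x <- ad_maxpool2(x)
  }
  for (l in seq_len(L - 1)) {
    x <- ad_convtranspose2(x, w$dec[[l]]$up$w, w$dec[[l]]$up$b)
    x <- ad_concat_c(x, skips[[L - l]])
    x <- conv_bn_relu(x, w$dec[[l]]$conv)
  }
  logits <- ad_conv2d(x, w$head$w, w$head$b)
  probs <- ad_softmax_c(logits)
  if (Hp != H || Wp != W) {
    full <- probs
    keep_r <- seq_len(H); keep_c <- seq_len(W)
    d <- dim(full$value)
    probs <- new_node(full$value[keep_r, keep_c, , drop = FALSE], list(full),
                      function(g) {
                        out <- array(0, d)
                        out[keep_r, keep_c, ] <- g
                        list(out)
                      })
  }
  probs
}

#' Segment a cine sequence
#'
#' Per-frame forward pass in evaluation mode; deterministic for fixed
#' weights.
#'
#' @param images (H, W, T) array (or a single matrix).
#' @param model a `unet_model`.
#' @return list with `labels` (H, W, T integer array, classes 0..3) and
#'   `probs` (H, W, n_classes, T).
#' @export
segment <- function(images, model) {
  if (length(dim(images)) == 2) images <- array(images, c(dim(images), 1))
  d <- dim(images); T <- d[3]
  probs <- array(0, c(d[1], d[2], model$cfg$n_classes, T))
  labels <- array(0L, c(d[1], d[2], T))
  for (t in seq_len(T)) {
    p <- ad_value(unet_forward(model, images[, , t]))
    probs[, , , t] <- p
    labels[, , t] <- apply(p, c(1, 2), which.max) - 1L
  }
  list(labels = labels, probs = probs)
}

one_hot <- function(labels, n_classes = 4L) {
  d <- dim(labels)
  oh <- array(0, c(d[1], d[2], n_classes))
  for (k in seq_len(n_classes)) oh[, , k] <- labels == (k - 1L)
  oh
}

#' Soft multi-class Dice loss
#'
#' `1 - mean_c (2 sum(p q) + eps) / (sum(p) + sum(q) + eps)` over classes.
#' Accepts plain arrays or autodiff nodes (for training).
#'
#' @param probs (H, W, C) class probabilities (array or node).
#' @param target (H, W, C) one-hot reference.
#' @param eps smoothing constant.
#' @return scalar (or scalar node).
#' @export
soft_dice_loss <- function(probs, target, eps = 1e-5) {
  if (inherits(probs, "ad_node")) {
    C <- dim(probs$value)[3]
    terms <- NULL
    for (k in seq_len(C)) {
      p <- ad_slice_c(probs, k)
      q <- target[, , k]
      num <- ad_add(ad_scale(ad_sum(ad_mul(p, ad_const(array(q, dim(p$value))))), 2), ad_const(eps))
      den <- ad_add(ad_sum(p), ad_const(sum(q) + eps))
      recip <- local({
        dv <- den$value
        new_node(1 / dv, list(den), function(g) list(-g / dv^2))
      })
      frac <- ad_mul(num, recip)
      terms <- if (is.null(terms)) frac else ad_add(terms, frac)
    }
    ad_sub(ad_const(1), ad_scale(terms, 1 / C))
  } else {
    C <- dim(probs)[3]
    vals <- vapply(seq_len(C), function(k) {
      p <- probs[, , k]; q <- target[, , k]
      (2 * sum(p * q) + eps) / (sum(p) + sum(q) + eps)
    }, numeric(1))
    1 - mean(vals)
  }
}

#' Propagate manual masks to unlabelled frames
#'
#' Warps a manual label map (nearest-neighbour, so the label value set is
#' preserved) from its frame to each target frame along the estimated
#' motion; the warped masks serve as pseudo-labels for weakly supervised
#' segmentation training.
#'
#' @param manual_mask (H, W) integer label map.
#' @param flow_table a `flow_table` covering the frames involved.
#' @param target_frames frame indices to propagate to.
#' @param source_frame frame the manual mask belongs to.
#' @return named list of (H, W) label maps, one per target frame.
#' @export
generate_pseudo_labels <- function(manual_mask, flow_table, target_frames,
                                   source_frame = flow_table$reference) {
  out <- lapply(target_frames, function(t) {
    u <- flow_between(flow_table, t, source_frame)
    warp_image(manual_mask, u, mode = "nearest")
  })
  names(out) <- as.character(target_frames)
  out
}

#' Contour overlay of a segmentation on an image
#'
#' Draws the class boundaries (LV pool, myocardium, RV pool) over a
#' greyscale frame; optionally writes a PNG.
#'
#' @param image (H, W) intensity matrix.
#' @param labels (H, W) integer label map.
#' @param file optional PNG path.
#' @param colors boundary colours for classes 1..3.
#' @export
plot_contour_overlay <- function(image, labels, file = NULL,
                                 colors = c("#E41A1C", "#4DAF4A", "#377EB8")) {
  if (!is.null(file)) grDevices::png(file, width = 480, height = 480)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  H <- nrow(image); W <- ncol(image)
  rng <- range(image)
  img01 <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  graphics::plot(NA, xlim = c(0.5, W + 0.5), ylim = c(H + 0.5, 0.5),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(img01, 0.5, H + 0.5, W + 0.5, 0.5)
  for (cl in 1:3) {
    b <- which(mask_boundary(labels == cl), arr.ind = TRUE)
    if (nrow(b) > 0)
      graphics::points(b[, 2], b[, 1], col = colors[cl], pch = 15, cex = 0.4)
  }
  invisible(NULL)
}

#' Flow between two arbitrary frames of a flow table
#'
#' Composes the stored frame-to-reference and reference-to-frame flows:
#' the result lives on the `from` grid and points into frame `to`.
#'
#' @param flow_table a `flow_table`.
#' @param from,to frame indices.
#' @return (H, W, 2) displacement array.
#' @export
flow_between <- function(flow_table, from, to) {
  ref <- flow_table$reference
  if (from == to) {
    d <- dim(flow_table$to_reference[[1]])
    return(array(0, d))
  }
  if (from == ref) return(flow_table$from_reference[[to]])
  if (to == ref) return(flow_table$to_reference[[from]])
  compose_flows(flow_table$from_reference[[to]], flow_table$to_reference[[from]])
}
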