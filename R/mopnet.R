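# Multi-frame bidirectional registration network.
#
# Five consecutive frames are grouped into three overlapping triplets
# (backward, fixed, forward). A shared encoder extracts per-frame features
# at reduced resolution; dual all-pairs correlation volumes relate each
# fixed frame to its backward and forward neighbours. Hidden motion states
# are carried across refinement iterations and warped between triplets by
# the current flow estimates (motion propagation), and a conv-GRU decodes
# residual bidirectional flows which are accumulated from zero. Inference
# slides windows over the cyclic cardiac sequence and composes the forward
# pair flows into a complete frame-to-reference mapping.

#' MOPNet configuration
#'
#' Two profiles are provided: `"tiny"` (1/4 feature resolution, 16
#' channels, 2 correlation levels, K = 4) sized for CPU-scale phantom
#' experiments, and `"default"` (1/8 resolution, 64 channels, 4 levels,
#' K = 6) mirroring the recurrent optical-flow lineage the architecture
#' belongs to. Any field can be overridden.
#'
#' @param profile `"tiny"` or `"default"`.
#' @param ... named overrides of config fields (`K`, `feature_downsample`,
#'   `feature_channels`, `context_channels`, `hidden_channels`,
#'   `corr_levels`, `corr_radius`, `superkernel_size`, `seed`).
#' @return a `mopnet_config` list.
#' @export
mopnet_config <- function(profile = c("tiny", "default"), ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "tiny") {
    list(K = 4L, feature_downsample = 4L, feature_channels = 16L,
         context_channels = 16L, hidden_channels = 16L,
         corr_levels = 2L, corr_radius = 3L, superkernel_size = 7L,
         seed = 1L, max_corr_pixels = 10000L)
  } else {
    list(K = 6L, feature_downsample = 8L, feature_channels = 64L,
         context_channels = 64L, hidden_channels = 64L,
         corr_levels = 4L, corr_radius = 4L, superkernel_size = 7L,
         seed = 1L, max_corr_pixels = 10000L)
  }
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (cfg$K < 0) stop("K must be >= 0")
  if (bitwAnd(cfg$feature_downsample, cfg$feature_downsample - 1L) != 0)
    stop("feature_downsample must be a power of 2")
  cfg$profile <- profile
  structure(cfg, class = "mopnet_config")
}

#' Group five frames into overlapping triplets
#'
#' For frames I1..I5: backward group (I1, I2, I3), fixed group
#' (I2, I3, I4), forward group (I3, I4, I5).
#'
#' @param frames (H, W, 5) array.
#' @return list with `bwd`, `fixed`, `fwd` (H, W, 3) stacks.
#' @export
build_tri_frame_groups <- function(frames) {
  d <- dim(frames)
  if (length(d) != 3 || d[3] != 5)
    stop("exactly 5 frames of identical shape are required, got ",
         if (length(d) == 3) d[3] else "a non-3D array")
  list(bwd = frames[, , 1:3], fixed = frames[, , 2:4], fwd = frames[, , 3:5])
}

# ---- weight initialisation -------------------------------------------------

he_init <- function(kh, kw, cin, cout, scale = 1) {
  ad_param(array(stats::rnorm(kh * kw * cin * cout,
                              sd = scale * sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)))
}

conv_block_init <- function(cin, cout) {
  list(w = he_init(3, 3, cin, cout), b = ad_param(numeric(cout)))
}

sk_block_init <- function(cin, cout, k) {
  # superkernel block: pointwise expand, depth-wise large kernel, pointwise
  # mix, plus a conical 1x1 skip from the input
  list(pw1 = he_init(1, 1, cin, cout), b1 = ad_param(numeric(cout)),
       dw = ad_param(array(stats::rnorm(k * k * cout, sd = sqrt(2 / (k * k))),
                           c(k, k, cout))),
       bdw = ad_param(numeric(cout)),
       pw2 = he_init(1, 1, cout, cout), b2 = ad_param(numeric(cout)),
       skip = he_init(1, 1, cin, cout))
}

encoder_init <- function(cout) {
  list(c1 = conv_block_init(1, cout), c2 = conv_block_init(cout, cout),
       c3 = conv_block_init(cout, cout),
       g2 = ad_param(rep(1, cout)), be2 = ad_param(numeric(cout)))
}

#' Initialise MOPNet weights
#'
#' Seeded He-style initialisation; the same seed reproduces the weights
#' bit-for-bit. The final flow-head convolution starts near zero so early
#' residual updates are small.
#'
#' @param cfg a [mopnet_config()].
#' @return nested list of parameter nodes with attributes `cfg`.
#' @export
mopnet_init <- function(cfg) {
  set.seed(cfg$seed)
  C <- cfg$feature_channels; Cc <- cfg$context_channels
  Ch <- cfg$hidden_channels
  win <- (2 * cfg$corr_radius + 1)^2
  corr_in <- win * cfg$corr_levels * 2      # both directions stacked
  gru_in <- C + C + Cc                      # Fmotion, FAgg, Fcontext
  w <- list(
    fenc = encoder_init(C),
    cenc = encoder_init(Cc),
    wq = he_init(1, 1, Cc, 8), wk = he_init(1, 1, Cc, 8),
    corr_enc = sk_block_init(corr_in, C, cfg$superkernel_size),
    flow_enc = sk_block_init(4, C, cfg$superkernel_size),
    mop_enc = sk_block_init(C + C + 3 * Ch, C, cfg$superkernel_size),
    m_state = conv_block_init(C, Ch),
    m_feat = conv_block_init(C, C),
    gru_z = conv_block_init(Ch + gru_in, Ch),
    gru_r = conv_block_init(Ch + gru_in, Ch),
    gru_q = conv_block_init(Ch + gru_in, Ch),
    head1 = conv_block_init(Ch, C),
    head2 = list(w = he_init(3, 3, C, 4, scale = 0.01),
                 b = ad_param(numeric(4)))
  )
  attr(w, "cfg") <- cfg
  w
}

mopnet_params <- function(weights) {
  out <- list()
  rec <- function(x) {
    if (inherits(x, "ad_node")) out[[length(out) + 1]] <<- x
    else if (is.list(x)) for (e in x) rec(e)
  }
  rec(weights)
  out
}

conv_relu <- function(x, blk) ad_relu(ad_conv2d(x, blk$w, blk$b))

run_encoder <- function(x, enc) {
  # 1/4 resolution: conv-pool, conv-norm-pool, conv
  h <- ad_avgpool2(conv_relu(x, enc$c1))
  h <- ad_conv2d(h, enc$c2$w, enc$c2$b)
  h <- ad_relu(ad_channel_norm(h, enc$g2, enc$be2))
  h <- ad_avgpool2(h)
  ad_conv2d(h, enc$c3$w, enc$c3$b)
}

run_encoder_ds <- function(x, enc, ds) {
  h <- run_encoder(x, enc)
  extra <- as.integer(log2(ds / 4))
  if (extra > 0) for (i in seq_len(extra)) h <- ad_avgpool2(h)
  h
}

sk_block <- function(x, blk) {
  h <- ad_relu(ad_conv2d(x, blk$pw1, blk$b1))
  h <- ad_relu(ad_conv2d_depthwise(h, blk$dw, blk$bdw))
  h <- ad_conv2d(h, blk$pw2, blk$b2)
  ad_relu(ad_add(h, ad_conv2d(x, blk$skip)))
}

#' Extract per-triplet features, context and attention
#'
#' The temporal axis of each triplet is folded into the batch axis: every
#' frame passes individually through the shared 2D feature encoder. The
#' fixed triplet additionally passes through a dedicated context encoder,
#' from which query/key maps build a row-normalised self-attention matrix
#' per fixed frame.
#'
#' @param groups output of [build_tri_frame_groups()].
#' @param cfg a [mopnet_config()].
#' @param weights from [mopnet_init()].
#' @return list with `feat` (per input frame, nodes), `ctx`, `attn`
#'   (per fixed frame), and the feature-grid shape.
#' @export
extract_features <- function(groups, cfg, weights) {
  frames5 <- array(0, c(dim(groups$bwd)[1:2], 5))
  frames5[, , 1:3] <- groups$bwd
  frames5[, , 4:5] <- groups$fwd[, , 2:3]
  ds <- cfg$feature_downsample
  feat <- lapply(1:5, function(t)
    run_encoder_ds(ad_const(frames5[, , t]), weights$fenc, ds))
  ctx <- lapply(1:3, function(m)
    ad_relu(run_encoder_ds(ad_const(groups$fixed[, , m]), weights$cenc, ds)))
  fd <- dim(feat[[1]]$value)
  N <- fd[1] * fd[2]
  attn <- lapply(ctx, function(cm) {
    q <- ad_reshape(ad_conv2d(cm, weights$wq), c(N, 8))
    k <- ad_reshape(ad_conv2d(cm, weights$wk), c(N, 8))
    ad_softmax_rows(ad_scale(ad_matmul(q, new_node(t(k$value), list(k),
                                                   function(g) list(t(g)))),
                             1 / sqrt(8)))
  })
  list(feat = feat, ctx = ctx, attn = attn, grid = fd[1:2])
}

#' Build dual correlation-volume pyramids
#'
#' All-pairs dot products (scaled by 1/sqrt(channels)) between each fixed
#' frame's features and its backward / forward counterparts, with
#' `corr_levels` average-pooled pyramid levels over the target dimensions.
#'
#' @param fs output of [extract_features()].
#' @param cfg a [mopnet_config()].
#' @return list `bwd`/`fwd`, each a list over the 3 frame pairs of
#'   per-level (N, Hl*Wl) correlation nodes plus level shapes.
#' @export
build_correlation_volumes <- function(fs, cfg) {
  h <- fs$grid[1]; w <- fs$grid[2]; N <- h * w
  if (N > cfg$max_corr_pixels)
    stop("feature grid too large for all-pairs correlation (", N, " pixels)")
  C <- dim(fs$feat[[1]]$value)[3]
  flat <- lapply(fs$feat, function(f) ad_reshape(f, c(N, C)))
  pyramid <- function(corr0) {
    lv <- list(list(corr = corr0, h = h, w = w))
    hh <- h; ww <- w
    for (l in seq_len(cfg$corr_levels - 1)) {
      lv[[l + 1]] <- list(corr = ad_pool_corr(lv[[l]]$corr, hh, ww),
                          h = hh %/% 2, w = ww %/% 2)
      hh <- hh %/% 2; ww <- ww %/% 2
    }
    lv
  }
  # pair m: fixed frame m+1 vs backward frame m / forward frame m+2
  bwd <- lapply(1:3, function(m) pyramid(ad_correlation(flat[[m + 1]], flat[[m]])))
  fwd <- lapply(1:3, function(m) pyramid(ad_correlation(flat[[m + 1]], flat[[m + 2]])))
  list(bwd = bwd, fwd = fwd, grid = fs$grid)
}

#' Windowed multiscale correlation lookup
#'
#' For one frame pair: gathers a (2 radius + 1)^2 window of correlation
#' values at every pyramid level, centred at each query pixel displaced by
#' the current flow (bilinear interpolation, edge-clamped); levels are
#' stacked along channels.
#'
#' @param pyr one pyramid from [build_correlation_volumes()].
#' @param flow_node (h, w, 2) flow node at feature resolution.
#' @param cfg a [mopnet_config()].
#' @return (h, w, levels * window^2) feature node.
#' @export
lookup_correlation <- function(pyr, flow_node, cfg) {
  h <- pyr[[1]]$h; w <- pyr[[1]]$w; N <- h * w
  g <- grid_coords(h, w)
  base <- cbind(as.vector(g$r), as.vector(g$c))
  rc <- ad_add(ad_reshape(flow_node, c(N, 2)), ad_const(base))
  out <- vector("list", length(pyr))
  for (l in seq_along(pyr)) {
    rc_l <- if (l == 1) rc else
      ad_add(ad_scale(ad_add(rc, ad_const(matrix(-0.5, N, 2))), 1 / 2^(l - 1)),
             ad_const(matrix(0.5, N, 2)))
    lk <- ad_corr_lookup(pyr[[l]]$corr, pyr[[l]]$h, pyr[[l]]$w, rc_l,
                         cfg$corr_radius)
    out[[l]] <- ad_reshape(lk, c(h, w, (2 * cfg$corr_radius + 1)^2))
  }
  do.call(ad_concat_c, out)
}

#' One motion-propagation update
#'
#' Warps the neighbouring hidden motion states into the fixed frame's
#' domain with the current flows, concatenates them with the fixed state
#' into the MOP feature, runs the motion encoder on (correlation, flow,
#' MOP) features, and re-assigns the warped states as the next
#' backward/forward states.
#'
#' @param states list with `fixed`, `bwd`, `fwd` state nodes for one
#'   temporal slot.
#' @param u_bwd,u_fwd (h, w, 2) flow nodes at feature resolution.
#' @param f_corr,f_flow encoded correlation / flow feature nodes.
#' @param weights,cfg network weights and config.
#' @return list with updated `states` and the motion feature node.
#' @export
mop_update <- function(states, u_bwd, u_fwd, f_corr, f_flow, weights, cfg) {
  m_plus <- ad_warp(states$fwd, u_fwd)
  m_minus <- ad_warp(states$bwd, u_bwd)
  f_mop <- ad_concat_c(states$fixed, m_plus, m_minus)
  enc <- sk_block(ad_concat_c(f_corr, f_flow, f_mop), weights$mop_enc)
  fixed_next <- ad_tanh(ad_conv2d(enc, weights$m_state$w, weights$m_state$b))
  f_motion <- ad_relu(ad_conv2d(enc, weights$m_feat$w, weights$m_feat$b))
  list(states = list(fixed = fixed_next, fwd = m_plus, bwd = m_minus),
       f_motion = f_motion)
}

#' One GRU refinement step
#'
#' Aggregates the motion features with the fixed frame's self-attention,
#' runs a conv-GRU on (motion, aggregated, context) features and decodes
#' bidirectional residual flows at feature resolution.
#'
#' @param f_motion motion feature node (h, w, C).
#' @param attn (N, N) row-stochastic attention node for this fixed frame.
#' @param ctx context feature node.
#' @param hidden GRU hidden state node (tanh-bounded).
#' @param weights,cfg network weights and config.
#' @return list `delta_bwd`, `delta_fwd` ((h, w, 2) nodes), `hidden`.
#' @export
gru_update_step <- function(f_motion, attn, ctx, hidden, weights, cfg) {
  d <- dim(f_motion$value); N <- d[1] * d[2]; C <- d[3]
  f_agg <- ad_reshape(ad_matmul(attn, ad_reshape(f_motion, c(N, C))), d)
  x <- ad_concat_c(f_motion, f_agg, ctx)
  hx <- ad_concat_c(hidden, x)
  z <- ad_sigmoid(ad_conv2d(hx, weights$gru_z$w, weights$gru_z$b))
  r <- ad_sigmoid(ad_conv2d(hx, weights$gru_r$w, weights$gru_r$b))
  q <- ad_tanh(ad_conv2d(ad_concat_c(ad_mul(r, hidden), x),
                         weights$gru_q$w, weights$gru_q$b))
  one <- array(1, dim(z$value))
  hidden_next <- ad_add(ad_mul(ad_sub(ad_const(one), z), hidden), ad_mul(z, q))
  head <- conv_relu(hidden_next, weights$head1)
  delta <- ad_conv2d(head, weights$head2$w, weights$head2$b)
  list(delta_bwd = ad_slice_c(delta, 1:2), delta_fwd = ad_slice_c(delta, 3:4),
       hidden = hidden_next)
}

#' Estimate bidirectional tri-frame motion for a 5-frame window
#'
#' Runs grouping, feature extraction, correlation volumes and `K`
#' refinement iterations of (lookup, motion propagation, GRU update),
#' accumulating residual flows from zero initialisation. With `K = 0` the
#' returned flows are identically zero regardless of the weights.
#'
#' @param frames (H, W, 5) array (intensities are min-max normalised to
#'   \[-1, 1\] internally).
#' @param cfg a [mopnet_config()].
#' @param weights from [mopnet_init()]; freshly initialised if `NULL`.
#' @param keep_tape keep autodiff nodes (needed to train through the call).
#' @return a `flow_pair` list: `ubwd`, `ufwd` (H, W, 2, 3) arrays mapping
#'   fixed-group frame m to its backward/forward neighbour, per-iteration
#'   `snapshots` (full-resolution flow nodes when `keep_tape`), and the
#'   window metadata.
#' @export
estimate_motion <- function(frames, cfg, weights = NULL, keep_tape = FALSE) {
  if (is.null(weights)) weights <- mopnet_init(cfg)
  d <- dim(frames)
  if (length(d) != 3 || d[3] != 5) stop("estimate_motion expects 5 frames")
  H <- d[1]; W <- d[2]; ds <- cfg$feature_downsample
  rng <- range(frames)
  fr <- if (diff(rng) > 0) 2 * (frames - rng[1]) / diff(rng) - 1 else frames * 0
  groups <- build_tri_frame_groups(fr)
  zero_full <- array(0, c(H, W, 2))
  if (cfg$K == 0) {
    z3 <- array(0, c(H, W, 2, 3))
    return(structure(list(ubwd = z3, ufwd = z3, snapshots = list()),
                     class = "flow_pair"))
  }
  fs <- extract_features(groups, cfg, weights)
  cv <- build_correlation_volumes(fs, cfg)
  h <- fs$grid[1]; w <- fs$grid[2]
  Ch <- cfg$hidden_channels
  set.seed(cfg$seed + 1000L)
  minit <- array(stats::rnorm(h * w * Ch), c(h, w, Ch))
  states <- lapply(1:3, function(m)
    list(fixed = ad_const(minit), fwd = ad_const(minit), bwd = ad_const(minit)))
  hidden <- lapply(fs$ctx, function(cm) ad_tanh(cm))
  u_b <- u_f <- lapply(1:3, function(m) ad_const(array(0, c(h, w, 2))))
  snapshots <- vector("list", cfg$K)
  for (k in seq_len(cfg$K)) {
    snap_b <- snap_f <- vector("list", 3)
    for (m in 1:3) {
      lk_b <- lookup_correlation(cv$bwd[[m]], u_b[[m]], cfg)
      lk_f <- lookup_correlation(cv$fwd[[m]], u_f[[m]], cfg)
      f_corr <- sk_block(ad_concat_c(lk_b, lk_f), weights$corr_enc)
      f_flow <- sk_block(ad_concat_c(u_b[[m]], u_f[[m]]), weights$flow_enc)
      mo <- mop_update(states[[m]], u_b[[m]], u_f[[m]], f_corr, f_flow,
                       weights, cfg)
      states[[m]] <- mo$states
      gu <- gru_update_step(mo$f_motion, fs$attn[[m]], fs$ctx[[m]],
                            hidden[[m]], weights, cfg)
      hidden[[m]] <- gu$hidden
      u_b[[m]] <- ad_add(u_b[[m]], gu$delta_bwd)
      u_f[[m]] <- ad_add(u_f[[m]], gu$delta_fwd)
      if (any(!is.finite(u_b[[m]]$value)) || any(!is.finite(u_f[[m]]$value)))
        stop("non-finite flow activation at refinement iteration ", k)
      snap_b[[m]] <- ad_scale(ad_upsample_bilinear(u_b[[m]], ds), ds)
      snap_f[[m]] <- ad_scale(ad_upsample_bilinear(u_f[[m]], ds), ds)
    }
    snapshots[[k]] <- list(ubwd = snap_b, ufwd = snap_f)
  }
  last <- snapshots[[cfg$K]]
  ubwd <- array(0, c(H, W, 2, 3)); ufwd <- array(0, c(H, W, 2, 3))
  for (m in 1:3) {
    ubwd[, , , m] <- last$ubwd[[m]]$value
    ufwd[, , , m] <- last$ufwd[[m]]$value
  }
  structure(list(ubwd = ubwd, ufwd = ufwd,
                 snapshots = if (keep_tape) snapshots else list(),
                 groups = groups),
            class = "flow_pair")
}

#' Full-cycle sliding-window inference
#'
#' Traverses the cyclic frame sequence with 5-frame windows whose starts
#' advance by 3, so the forward estimates of successive windows tile the
#' cyclic adjacent frame pairs; a pair already produced by an earlier
#' window is never emitted twice. Only forward estimates are used. Flows
#' from every frame to the reference frame are then obtained by composing
#' the adjacent-pair flows along the cycle.
#'
#' @param sequence (H, W, T) array, T >= 5; treated as cyclic.
#' @param cfg a [mopnet_config()].
#' @param weights MOPNet weights.
#' @param reference reference frame index (1-based; default 1,
#'   end-diastole by phantom convention).
#' @return a `flow_table` list: `pairs` (data.frame `from`, `to`),
#'   `flows` (named list "from->to" of (H, W, 2) arrays),
#'   `to_reference` (list over frames of flows on the frame grid pointing
#'   into the reference), `from_reference` (reference-grid flows pointing
#'   into each frame, the Lagrangian displacement used for strain), and
#'   `reference`.
#' @export
full_cycle_inference <- function(sequence, cfg, weights, reference = 1L) {
  d <- dim(sequence); T <- d[3]
  if (T < 5) stop("full-cycle inference requires at least 5 frames")
  wrap <- function(i) ((i - 1L) %% T) + 1L
  have <- character(0)
  flows <- list()
  pairs <- NULL
  s <- 1L
  n_windows <- 0L
  key <- function(p) paste0(p[1], "->", p[2])
  while (length(have) < T && n_windows < 2L * T) {
    idx <- wrap(s + 0:4)
    fp <- estimate_motion(sequence[, , idx], cfg, weights)
    for (m in 1:3) {
      p <- c(idx[m + 1], idx[m + 2])
      k <- key(p)
      if (!(k %in% have)) {
        have <- c(have, k)
        flows[[k]] <- fp$ufwd[, , , m]
        pairs <- rbind(pairs, data.frame(from = p[1], to = p[2]))
      }
    }
    s <- wrap(s + 3L)
    n_windows <- n_windows + 1L
  }
  compose_chain <- function(from, to) {
    # forward chain from -> from+1 -> ... -> to (cyclic)
    if (from == to) return(array(0, c(d[1], d[2], 2)))
    u <- flows[[key(c(from, wrap(from + 1L)))]]
    f <- wrap(from + 1L)
    while (f != to) {
      u_next <- flows[[key(c(f, wrap(f + 1L)))]]
      # u maps grid of `from` into frame f; u_next maps f into f+1
      u <- compose_flows(u_next, u)
      f <- wrap(f + 1L)
    }
    u
  }
  to_reference <- lapply(seq_len(T), function(f) compose_chain(f, reference))
  from_reference <- lapply(seq_len(T), function(f) compose_chain(reference, f))
  structure(list(pairs = pairs, flows = flows, to_reference = to_reference,
                 from_reference = from_reference, reference = reference,
                 n_frames = T),
            class = "flow_table")
}

#' Build a flow table from phantom ground truth
#'
#' Convenience constructor giving the same structure as
#' [full_cycle_inference()] but filled with the phantom's exact flows;
#' used to isolate reconstruction and strain from registration error.
#'
#' @param gt a `phantom_truth` object.
#' @param reference reference frame (1-based).
#' @param frames optional subset of frame indices (defaults to all).
#' @return a `flow_table`.
#' @export
phantom_flow_table <- function(gt, reference = 1L, frames = NULL) {
  T <- gt$config$n_frames
  frames <- frames %||% seq_len(T)
  to_reference <- lapply(frames, function(f) gt$true_flows(f, reference))
  from_reference <- lapply(frames, function(f) gt$true_flows(reference, f))
  structure(list(pairs = NULL, flows = NULL, to_reference = to_reference,
                 from_reference = from_reference, reference = reference,
                 n_frames = length(frames)),
            class = "flow_table")
}

#' Save / load MOPNet checkpoints
#'
#' Checkpoints carry the numeric weight values, the config and the seed.
#'
#' @param weights nested weight list.
#' @param path file path (.rds).
#' @export
save_checkpoint <- function(weights, path) {
  vals <- rapply(weights, function(p) if (inherits(p, "ad_node")) p$value else p,
                 how = "replace")
  saveRDS(list(values = vals, cfg = attr(weights, "cfg"), schema = 1L), path)
}

#' @rdname save_checkpoint
#' @return for `load_checkpoint`, the reconstituted weight list.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$schema) || ck$schema != 1L)
    stop("unsupported checkpoint schema version")
  w <- rapply(ck$values, function(v) ad_param(v), how = "replace")
  attr(w, "cfg") <- ck$cfg
  w
}
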