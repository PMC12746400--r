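# Training losses and the three-stage schedule: self-supervised
# registration (photometric + smoothness over all refinement iterations),
# supervised segmentation (soft Dice on labelled frames), then joint
# training with motion-compensated reconstruction in the loop and
# pseudo-label supervision on unlabelled frames.

#' Loss configuration
#'
#' @param lambda1 smoothness weight in the registration loss.
#' @param lambda2 Dice weight in the joint loss.
#' @param lambda3 warped-pseudo-label Dice weight in the joint loss.
#' @param K refinement iterations summed in the registration loss.
#' @return a `loss_config` list.
#' @export
loss_config <- function(lambda1 = 0.04, lambda2 = 0.05, lambda3 = 0.04, K = 6L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 K = as.integer(K)),
            class = "loss_config")
}

#' Training configuration
#'
#' Defaults follow the AdamW regime the networks were designed around
#' (batch 4, learning rate 1e-4, weight decay 5e-4, cosine annealing);
#' CPU-scale phantom runs pass smaller step counts and larger rates.
#'
#' @param batch_size windows per optimizer step.
#' @param learning_rate base AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param steps optimizer steps for the stage.
#' @param scheduler `"cosine"` or `"constant"`.
#' @param seed RNG seed for samplers and initialisation.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 1e-4,
                         weight_decay = 5e-4, steps = 100L,
                         scheduler = c("cosine", "constant"), seed = 1L) {
  scheduler <- match.arg(scheduler)
  stopifnot(steps >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 steps = as.integer(steps), scheduler = scheduler,
                 seed = as.integer(seed)),
            class = "train_config")
}

# mean absolute value of a node (smooth |.|)
ad_l1_mean <- function(a) ad_mean(ad_abs(a))

#' Photometric loss (bidirectional L1)
#'
#' L1 between each fixed-group frame and the warped corresponding
#' backward/forward frame, averaged over the three frame pairs and
#' pixels; the two directional terms are summed.
#'
#' @param groups tri-frame groups (arrays, as from
#'   [build_tri_frame_groups()]).
#' @param ubwd,ufwd lists of 3 (H, W, 2) flows (arrays or nodes).
#' @return scalar (node if the flows are nodes).
#' @export
photometric_loss <- function(groups, ubwd, ufwd) {
  is_node <- inherits(ubwd[[1]], "ad_node")
  total <- NULL
  for (m in 1:3) {
    if (is_node) {
      wb <- ad_warp(ad_const(groups$bwd[, , m]), ubwd[[m]])
      wf <- ad_warp(ad_const(groups$fwd[, , m]), ufwd[[m]])
      term <- ad_add(ad_l1_mean(ad_sub(ad_const(groups$fixed[, , m]), wb)),
                     ad_l1_mean(ad_sub(ad_const(groups$fixed[, , m]), wf)))
      total <- if (is.null(total)) term else ad_add(total, term)
    } else {
      wb <- warp_image(groups$bwd[, , m], ubwd[[m]])
      wf <- warp_image(groups$fwd[, , m], ufwd[[m]])
      term <- mean(abs(groups$fixed[, , m] - wb)) +
        mean(abs(groups$fixed[, , m] - wf))
      total <- (total %||% 0) + term
    }
  }
  if (is_node) ad_scale(total, 1 / 3) else total / 3
}

# L1 of forward spatial differences of one flow node/array: per pixel the
# gradient magnitudes of both components are summed, then averaged over
# pixels and the two axes are added (a unit row-ramp flow scores 1)
fd_l1 <- function(u) {
  nc <- 2
  if (inherits(u, "ad_node")) {
    d <- dim(u$value); H <- d[1]; W <- d[2]
    v <- u$value
    d1 <- v[2:H, , , drop = FALSE] - v[1:(H - 1), , , drop = FALSE]
    d2 <- v[, 2:W, , drop = FALSE] - v[, 1:(W - 1), , drop = FALSE]
    e <- 1e-8
    val <- nc * (mean(sqrt(d1^2 + e)) + mean(sqrt(d2^2 + e)))
    new_node(val, list(u), function(g) {
      s1 <- nc * d1 / sqrt(d1^2 + e) / length(d1)
      s2 <- nc * d2 / sqrt(d2^2 + e) / length(d2)
      du <- array(0, d)
      du[2:H, , ] <- du[2:H, , , drop = FALSE] + s1
      du[1:(H - 1), , ] <- du[1:(H - 1), , , drop = FALSE] - s1
      du[, 2:W, ] <- du[, 2:W, , drop = FALSE] + s2
      du[, 1:(W - 1), ] <- du[, 1:(W - 1), , drop = FALSE] - s2
      list(g * du)
    })
  } else {
    d <- dim(u); H <- d[1]; W <- d[2]
    d1 <- u[2:H, , , drop = FALSE] - u[1:(H - 1), , , drop = FALSE]
    d2 <- u[, 2:W, , drop = FALSE] - u[, 1:(W - 1), , drop = FALSE]
    nc * (mean(abs(d1)) + mean(abs(d2)))
  }
}

#' Smoothness loss (L1 of spatial flow gradients)
#'
#' Mean absolute forward difference of both flow fields along both axes,
#' averaged over the three frame pairs and summed over the two
#' directions. Zero for constant flows; homogeneous of degree 1.
#'
#' @param ubwd,ufwd lists of 3 (H, W, 2) flows (arrays or nodes), or
#'   single (H, W, 2) fields.
#' @return scalar (node if the flows are nodes).
#' @export
smoothness_loss <- function(ubwd, ufwd = NULL) {
  wrap3 <- function(u) if (is.list(u)) u else list(u)
  ub <- wrap3(ubwd)
  uf <- if (is.null(ufwd)) list() else wrap3(ufwd)
  all_u <- c(ub, uf)
  is_node <- inherits(all_u[[1]], "ad_node")
  per_dir <- function(us) {
    if (length(us) == 0) return(NULL)
    tot <- NULL
    for (u in us) {
      t <- fd_l1(u)
      tot <- if (is.null(tot)) t else if (is_node) ad_add(tot, t) else tot + t
    }
    if (is_node) ad_scale(tot, 1 / length(us)) else tot / length(us)
  }
  a <- per_dir(ub); b <- per_dir(uf)
  if (is.null(b)) return(a)
  if (is_node) ad_add(a, b) else a + b
}

#' Registration loss over refinement iterations
#'
#' Unweighted sum over the `K` per-iteration flow snapshots of the
#' photometric loss plus `lambda1` times the smoothness loss.
#'
#' @param flow_pair a `flow_pair` from [estimate_motion()] with
#'   `keep_tape = TRUE`.
#' @param cfg a [loss_config()]; `cfg$K` must match the snapshot count.
#' @return scalar node.
#' @export
registration_loss <- function(flow_pair, cfg = loss_config()) {
  snaps <- flow_pair$snapshots
  if (length(snaps) == 0)
    stop("registration_loss needs per-iteration snapshots ",
         "(run estimate_motion with keep_tape = TRUE)")
  if (length(snaps) != cfg$K)
    stop("snapshot count (", length(snaps), ") does not match K = ", cfg$K)
  total <- NULL
  for (k in seq_along(snaps)) {
    ph <- photometric_loss(flow_pair$groups, snaps[[k]]$ubwd, snaps[[k]]$ufwd)
    sm <- smoothness_loss(snaps[[k]]$ubwd, snaps[[k]]$ufwd)
    term <- ad_add(ph, ad_scale(sm, cfg$lambda1))
    total <- if (is.null(total)) term else ad_add(total, term)
  }
  total
}

#' Joint training loss
#'
#' `L_reg + lambda2 L_Dice + lambda3 L_Dice_warp`; each component may be
#' a scalar or a node.
#'
#' @param reg_term registration loss.
#' @param dice_term Dice loss on labelled frames.
#' @param dice_warp_term Dice loss against propagated pseudo-labels.
#' @param cfg a [loss_config()].
#' @return scalar (node if any input is a node).
#' @export
joint_loss <- function(reg_term, dice_term, dice_warp_term, cfg = loss_config()) {
  nodes <- any(vapply(list(reg_term, dice_term, dice_warp_term),
                      inherits, logical(1), "ad_node"))
  if (!nodes)
    return(reg_term + cfg$lambda2 * dice_term + cfg$lambda3 * dice_warp_term)
  as_n <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)
  ad_add(as_n(reg_term),
         ad_add(ad_scale(as_n(dice_term), cfg$lambda2),
                ad_scale(as_n(dice_warp_term), cfg$lambda3)))
}

#' Assemble a training case from a phantom
#'
#' Bundles the fully sampled images and labels with an undersampled
#' k-space simulation and its zero-filled reconstruction at acceleration
#' `R`, as the joint stage consumes them.
#'
#' @param gt a `phantom_truth`.
#' @param R acceleration factor.
#' @param n_coils coils for the simulation.
#' @param acs_lines always-sampled central lines.
#' @param seed mask/noise seed.
#' @return a `train_case` list.
#' @export
make_training_case <- function(gt, R = 8, n_coils = 4, acs_lines = 4,
                               seed = 1L) {
  d <- dim(gt$images)
  coils <- generate_coil_maps(n_coils, d[1:2])
  mask <- generate_kt_mask(c(d[3], d[1]), R = R, acs_lines = acs_lines,
                           seed = seed)
  bundle <- simulate_kspace(gt$images_clean, coils, mask,
                            noise_sigma = gt$config$noise_sigma / sqrt(2),
                            seed = seed + 1L)
  zf <- zero_filled_recon(bundle)
  list(gt = gt, bundle = bundle, zf = zf, R = R)
}

# sample a 5-frame joint-stage window: a labelled frame (ED or ES) sits at
# position 1 or 5, the interior frames are drawn sorted between the
# labelled endpoints
sample_joint_window <- function(ed, es, T) {
  lo <- min(ed, es); hi <- max(ed, es)
  if (hi - lo < 4) stop("labelled frames too close for a 5-frame window")
  interior <- sort(sample((lo + 1):(hi - 1), 3))
  idx <- c(lo, interior, hi)
  if (stats::runif(1) < 0.5) idx <- rev(idx)
  idx
}

#' Run one training stage
#'
#' `"registration"`: self-supervised MOPNet training on random 5-frame
#' windows of the fully sampled sequences. `"segmentation"`: supervised
#' U-Net training on labelled (end-diastolic and end-systolic) frames.
#' `"joint"`: both networks optimized together; each window places a
#' labelled frame at position 1 or 5, the current motion estimates drive
#' a motion-compensated reconstruction (treated as a fixed operator, no
#' gradients through the solver), the U-Net segments the reconstructed
#' frames, and pseudo-labels warped from the manual masks supervise the
#' unlabelled frames via the warped Dice term.
#'
#' @param stage `"registration"`, `"segmentation"` or `"joint"`.
#' @param data list of `phantom_truth` objects (registration,
#'   segmentation) or of [make_training_case()] lists (joint).
#' @param train_cfg a [train_config()].
#' @param loss_cfg a [loss_config()]; its `K` must match `reg_cfg$K`.
#' @param reg_cfg,reg_weights MOPNet config and (optionally pre-trained)
#'   weights.
#' @param seg_model a `unet_model` (built fresh if `NULL`).
#' @param moco_cfg reconstruction config for the joint stage.
#' @param checkpoint_path optional path to write a checkpoint to.
#' @param log_path optional path for a per-step TSV loss log.
#' @param weight_average_from optional step index: parameters are
#'   tail-averaged (Polyak) over the steps after it, which damps the
#'   step-to-step jitter of small-batch training.
#' @return list with `reg_weights`, `seg_model`, `log` (data.frame of
#'   per-step losses).
#' @export
run_training_stage <- function(stage = c("registration", "segmentation", "joint"),
                               data, train_cfg = train_config(),
                               loss_cfg = loss_config(),
                               reg_cfg = mopnet_config("tiny"),
                               reg_weights = NULL, seg_model = NULL,
                               moco_cfg = moco_config(n_iters = 6),
                               checkpoint_path = NULL, log_path = NULL,
                               weight_average_from = NULL) {
  stage <- match.arg(stage)
  set.seed(train_cfg$seed)
  if (stage %in% c("registration", "joint") && is.null(reg_weights))
    reg_weights <- mopnet_init(reg_cfg)
  if (stage %in% c("segmentation", "joint") && is.null(seg_model))
    seg_model <- build_unet(unet_config("tiny", seed = train_cfg$seed))
  loss_cfg$K <- reg_cfg$K
  params <- switch(stage,
    registration = mopnet_params(reg_weights),
    segmentation = unet_params(seg_model),
    joint = c(mopnet_params(reg_weights), unet_params(seg_model)))
  opt <- adamw(params, lr = train_cfg$learning_rate,
               weight_decay = train_cfg$weight_decay)
  log <- data.frame(step = integer(0), loss = numeric(0))
  avg <- NULL; n_avg <- 0L
  for (step in seq_len(train_cfg$steps)) {
    lr_now <- if (train_cfg$scheduler == "cosine")
      cosine_lr(step, train_cfg$steps, train_cfg$learning_rate)
    else train_cfg$learning_rate
    opt$zero_grad()
    batch_loss <- 0
    for (bi in seq_len(train_cfg$batch_size)) {
      case <- data[[sample(length(data), 1)]]
      loss_node <- switch(stage,
        registration = {
          gt <- case
          T <- dim(gt$images)[3]
          s <- sample(T - 4, 1)
          fp <- estimate_motion(gt$images[, , s:(s + 4)], reg_cfg,
                                reg_weights, keep_tape = TRUE)
          registration_loss(fp, loss_cfg)
        },
        segmentation = {
          gt <- case
          t <- sample(c(1L, gt$es_frame), 1)
          probs <- unet_forward(seg_model, gt$images[, , t])
          soft_dice_loss(probs, one_hot(gt$labels[, , t]))
        },
        joint = joint_step_loss(case, reg_cfg, reg_weights, seg_model,
                                loss_cfg, moco_cfg))
      if (!is.finite(ad_value(loss_node)))
        stop("NaN loss at training step ", step)
      ad_backward(loss_node)
      batch_loss <- batch_loss + ad_value(loss_node)
    }
    # average the accumulated batch gradients
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad / train_cfg$batch_size
    opt$step(lr_now)
    log <- rbind(log, data.frame(step = step,
                                 loss = batch_loss / train_cfg$batch_size))
    if (!is.null(weight_average_from) && step > weight_average_from) {
      vals <- lapply(params, function(p) p$value)
      avg <- if (is.null(avg)) vals else Map(`+`, avg, vals)
      n_avg <- n_avg + 1L
    }
  }
  if (n_avg > 0)
    for (i in seq_along(params)) params[[i]]$value <- avg[[i]] / n_avg
  if (!is.null(checkpoint_path) && stage != "segmentation")
    save_checkpoint(reg_weights, checkpoint_path)
  if (!is.null(log_path))
    utils::write.table(log, log_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(reg_weights = reg_weights, seg_model = seg_model, log = log)
}

# one joint-stage window: registration on zero-filled frames, fixed-point
# reconstruction, segmentation Dice on the labelled endpoint, and a
# differentiable warped-Dice term that back-propagates into both networks
joint_step_loss <- function(case, reg_cfg, reg_weights, seg_model,
                            loss_cfg, moco_cfg) {
  gt <- case$gt
  idx <- sample_joint_window(1L, gt$es_frame, dim(gt$images)[3])
  frames_zf <- case$zf[, , idx]
  fp <- estimate_motion(frames_zf, reg_cfg, reg_weights, keep_tape = TRUE)
  reg_term <- registration_loss(fp, loss_cfg)
  # reconstruction as a fixed operator on the window (no solver gradients)
  sub_mask <- case$bundle$mask[idx, , drop = FALSE]
  sub_y <- case$bundle$y[, , , idx, drop = FALSE]
  sub_bundle <- structure(list(y = sub_y, y_full = case$bundle$y_full[, , , idx, drop = FALSE],
                               coils = case$bundle$coils, mask = sub_mask,
                               R = case$R),
                          class = "kspace_bundle")
  ft <- window_flow_table(fp, reference_position = 1L)
  rec <- tryCatch(ktslr_reconstruct(sub_bundle, ft, moco_cfg),
                  error = function(e) NULL)
  imgs <- if (is.null(rec)) frames_zf else rec$recon
  # Dice on the labelled endpoints (positions 1 and 5 hold ED/ES frames)
  lab_pos <- c(1L, 5L)
  dice_term <- NULL
  for (pos in lab_pos) {
    probs <- unet_forward(seg_model, imgs[, , pos])
    term <- soft_dice_loss(probs, one_hot(gt$labels[, , idx[pos]]))
    dice_term <- if (is.null(dice_term)) term else ad_add(dice_term, term)
  }
  dice_term <- ad_scale(dice_term, 0.5)
  # warped-Dice on one interior frame: manual endpoint one-hot mask warped
  # differentiably along the forward flows (gradients reach the flows)
  mid_pos <- sample(2:4, 1)
  u_chain <- chain_forward_flows(fp, from_pos = 1L, to_pos = mid_pos)
  oh <- one_hot(gt$labels[, , idx[1]])
  probs_mid <- unet_forward(seg_model, imgs[, , mid_pos])
  # pseudo-label: mask of the labelled frame seen from the mid frame
  pseudo <- ad_warp(ad_const(oh), u_chain)
  dice_warp <- soft_dice_node_vs_node(probs_mid, pseudo)
  joint_loss(reg_term, dice_term, dice_warp, loss_cfg)
}

# flow table over a 5-frame window from the forward estimates of one
# flow_pair (positions 1..5; reference at a window position)
window_flow_table <- function(fp, reference_position = 1L) {
  H <- dim(fp$ufwd)[1]; W <- dim(fp$ufwd)[2]
  zero <- array(0, c(H, W, 2))
  # adjacent forward flows: position p -> p+1 for p = 2..4
  adj <- list(NULL, fp$ufwd[, , , 1], fp$ufwd[, , , 2], fp$ufwd[, , , 3], NULL)
  # backward flows give position p -> p-1 for p = 2..4
  adjb <- list(NULL, fp$ubwd[, , , 1], fp$ubwd[, , , 2], fp$ubwd[, , , 3], NULL)
  ref <- reference_position
  go <- function(from, to) {
    if (from == to) return(zero)
    u <- NULL; p <- from
    while (p != to) {
      step_u <- if (to > p) adj[[p]] else adjb[[p]]
      if (is.null(step_u)) return(NULL)
      u <- if (is.null(u)) step_u else compose_flows(step_u, u)
      p <- p + if (to > p) 1L else -1L
    }
    u
  }
  to_ref <- lapply(1:5, function(p) go(p, ref) %||% zero)
  from_ref <- lapply(1:5, function(p) go(ref, p) %||% zero)
  structure(list(pairs = NULL, flows = NULL, to_reference = to_ref,
                 from_reference = from_ref, reference = ref, n_frames = 5L),
            class = "flow_table")
}

# compose the forward flow nodes from window position `from_pos` to
# `to_pos` differentiably (used by the warped-Dice term)
chain_forward_flows <- function(fp, from_pos = 1L, to_pos) {
  # flow on the grid of to_pos pointing back to from_pos: going backward
  # through positions to_pos-1, ..., from_pos using backward estimates
  # would skip slot 1; instead use forward estimates inverted implicitly:
  # the backward estimates ubwd map fixed position p into p-1
  stopifnot(to_pos >= 2, to_pos <= 4)
  u <- fp_snapshot_node(fp, "ubwd", to_pos - 1L)   # slot for fixed pos to_pos
  p <- to_pos - 1L
  while (p > from_pos) {
    u_prev <- fp_snapshot_node(fp, "ubwd", p - 1L)
    u <- ad_compose_flows(u_prev, u)
    p <- p - 1L
  }
  u
}

fp_snapshot_node <- function(fp, dir, slot) {
  snaps <- fp$snapshots
  if (length(snaps) == 0) stop("flow_pair carries no tape")
  snaps[[length(snaps)]][[dir]][[slot]]
}

# differentiable flow composition on nodes:
# (u_ab o u_bc)(p) = u_bc(p) + u_ab(p + u_bc(p))
ad_compose_flows <- function(u_ab, u_bc) {
  ad_add(u_bc, ad_warp(u_ab, u_bc))
}

# soft dice where both prediction and target are nodes
soft_dice_node_vs_node <- function(probs, target, eps = 1e-5) {
  C <- dim(probs$value)[3]
  terms <- NULL
  for (k in seq_len(C)) {
    p <- ad_slice_c(probs, k); q <- ad_slice_c(target, k)
    num <- ad_add(ad_scale(ad_sum(ad_mul(p, q)), 2), ad_const(eps))
    den <- ad_add(ad_add(ad_sum(p), ad_sum(q)), ad_const(eps))
    recip <- local({
      dv <- den$value
      new_node(1 / dv, list(den), function(g) list(-g / dv^2))
    })
    frac <- ad_mul(num, recip)
    terms <- if (is.null(terms)) frac else ad_add(terms, frac)
  }
  ad_sub(ad_const(1), ad_scale(terms, 1 / C))
}
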