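test_that("the photometric loss matches closed forms", {
  set.seed(1)
  base <- matrix(rnorm(64), 8, 8)
  frames <- array(base, c(8, 8, 5))
  g <- build_tri_frame_groups(frames)
  z3 <- lapply(1:3, function(m) array(0, c(8, 8, 2)))
  expect_equal(photometric_loss(g, z3, z3), 0)
  # forward frames offset by a constant 0.1: the forward term contributes 0.1
  frames2 <- frames
  frames2[, , 3:5] <- frames2[, , 3:5] + 0.1
  g2 <- build_tri_frame_groups(frames2)
  # bwd group frames 1,2 differ from fixed 2,3 -> mixed; use a clean split:
  gm <- list(bwd = g$fixed, fixed = g$fixed, fwd = g$fixed + 0.1)
  expect_equal(photometric_loss(gm, z3, z3), 0.1, tolerance = 1e-12)
  set.seed(2)
  uf <- lapply(1:3, function(m) smooth_flow(8, 8, 1, m))
  expect_gte(photometric_loss(g, uf, uf), 0)
})

test_that("the smoothness loss is zero for constant flows and homogeneous", {
  const_u <- array(0.7, c(8, 8, 2))
  expect_equal(smoothness_loss(list(const_u, const_u, const_u),
                               list(const_u, const_u, const_u)), 0)
  # linear ramp along rows with unit slope: mean gradient 1 on one axis
  g <- grid_coords(8, 8)
  ramp <- array(0, c(8, 8, 2)); ramp[, , 1] <- g$r
  expect_equal(smoothness_loss(ramp), 1, tolerance = 1e-6)
  u <- smooth_flow(8, 8, 1, 1)
  expect_equal(smoothness_loss(lapply(1:3, function(i) 2 * u)),
               2 * smoothness_loss(lapply(1:3, function(i) u)),
               tolerance = 1e-4)
})

test_that("the registration loss sums photometric + weighted smoothness over iterations", {
  ad <- asNamespace("cinemop")
  set.seed(3)
  frames <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  g <- build_tri_frame_groups(frames)
  mk_snap <- function(seed) {
    set.seed(seed)
    list(ubwd = lapply(1:3, function(m) ad$ad_const(array(rnorm(32) * 0.3, c(4, 4, 2)))),
         ufwd = lapply(1:3, function(m) ad$ad_const(array(rnorm(32) * 0.3, c(4, 4, 2)))))
  }
  snaps <- list(mk_snap(1), mk_snap(2))
  fp <- list(groups = g, snapshots = snaps)
  cfg <- loss_config(K = 2L)
  got <- ad_value(registration_loss(fp, cfg))
  manual <- 0
  for (k in 1:2) {
    ub <- lapply(snaps[[k]]$ubwd, ad_value); uf <- lapply(snaps[[k]]$ufwd, ad_value)
    manual <- manual + photometric_loss(g, ub, uf) +
      cfg$lambda1 * smoothness_loss(ub, uf)
  }
  expect_equal(got, manual, tolerance = 1e-6)
  expect_error(registration_loss(list(groups = g, snapshots = snaps),
                                 loss_config(K = 3L)), "does not match")
  # K = 1 reduces to a single term
  fp1 <- list(groups = g, snapshots = snaps[1])
  expect_equal(ad_value(registration_loss(fp1, loss_config(K = 1L))),
               photometric_loss(g, lapply(snaps[[1]]$ubwd, ad_value),
                                lapply(snaps[[1]]$ufwd, ad_value)) +
                 0.04 * smoothness_loss(lapply(snaps[[1]]$ubwd, ad_value),
                                        lapply(snaps[[1]]$ufwd, ad_value)),
               tolerance = 1e-6)
})

test_that("the joint loss is the documented weighted sum", {
  cfg <- loss_config()
  expect_equal(joint_loss(0.5, 0.2, 0.3, cfg), 0.5 + 0.05 * 0.2 + 0.04 * 0.3)
  expect_equal(joint_loss(0.5, 0.2, 0.3, cfg), 0.522)
  expect_equal(joint_loss(1.1, 0.9, 0.8, loss_config(lambda2 = 0, lambda3 = 0)),
               1.1)
  # monotone non-decreasing in each component
  expect_gte(joint_loss(0.6, 0.2, 0.3, cfg), joint_loss(0.5, 0.2, 0.3, cfg))
  expect_gte(joint_loss(0.5, 0.4, 0.3, cfg), joint_loss(0.5, 0.2, 0.3, cfg))
})

test_that("joint-stage windows always put a labelled frame at the ends", {
  set.seed(9)
  for (i in 1:50) {
    idx <- cinemop:::sample_joint_window(1L, 7L, 9L)
    expect_length(idx, 5)
    ends <- c(idx[1], idx[5])
    expect_true(all(sort(ends) == c(1, 7)))
    expect_true(all(diff(idx) > 0) || all(diff(idx) < 0))
    expect_true(all(idx[2:4] > min(ends) & idx[2:4] < max(ends)))
  }
})

test_that("a short smoke run of each stage completes and checkpoints", {
  gt <- memo("train_smoke_phantom", {
    generate_cine_phantom(phantom_config(grid_size = 32, n_frames = 9,
                                         n_slices = 1, heart_scale = 1.6,
                                         seed = 17))
  })
  ck <- tempfile(fileext = ".rds")
  tc <- train_config(batch_size = 1L, learning_rate = 1e-3, steps = 3L, seed = 2)
  res <- run_training_stage("registration", list(gt), tc, loss_config(),
                            reg_cfg = mopnet_config("tiny", K = 2L),
                            checkpoint_path = ck)
  expect_true(file.exists(ck))
  expect_equal(nrow(res$log), 3)
  expect_true(all(is.finite(res$log$loss)))

  res_seg <- run_training_stage("segmentation", list(gt), tc, loss_config())
  expect_equal(nrow(res_seg$log), 3)

  case <- make_training_case(gt, R = 6, n_coils = 3, seed = 4)
  res_joint <- run_training_stage("joint", list(case), tc, loss_config(),
                                  reg_cfg = mopnet_config("tiny", K = 2L),
                                  reg_weights = res$reg_weights,
                                  seg_model = res_seg$seg_model,
                                  moco_cfg = moco_config(n_iters = 3))
  expect_equal(nrow(res_joint$log), 3)
  expect_true(all(is.finite(res_joint$log$loss)))
})
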