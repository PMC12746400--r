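test_that("the warp operator is linear, exact for identity and phantom flows", {
  gt <- fix_phantom()
  T <- dim(gt$images)[3]
  ft_id <- phantom_flow_table(
    generate_cine_phantom(phantom_config(grid_size = 48, n_frames = 9,
                                         n_slices = 1, contraction_amplitude = 0,
                                         rotation_amplitude = 0, seed = 1)),
    frames = 1:9)
  x <- matrix(rnorm(48 * 48), 48, 48)
  expect_equal(motion_warp_operator(x, ft_id, 5), x, tolerance = 1e-12)

  ft <- phantom_flow_table(gt, frames = 1:T)
  for (t in c(3, gt$es_frame)) {
    pred <- motion_warp_operator(gt$images_clean[, , 1], ft, t)
    expect_lt(mean(abs(pred - gt$images_clean[, , t])),
              2 * gt$config$noise_sigma)
  }
  a <- matrix(rnorm(48 * 48), 48, 48); b <- matrix(rnorm(48 * 48), 48, 48)
  lhs <- motion_warp_operator(1.3 * a + 0.4 * b, ft, 4)
  rhs <- 1.3 * motion_warp_operator(a, ft, 4) + 0.4 * motion_warp_operator(b, ft, 4)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("the motion-compensated operator passes the dot-product test", {
  gt <- fix_phantom()
  ft <- phantom_flow_table(gt, frames = 1:5)
  coils <- generate_coil_maps(3, c(16, 16))
  mask <- generate_kt_mask(c(5, 16), R = 2, acs_lines = 2, seed = 4)
  # crop flows to a 16x16 instance
  ft16 <- ft
  ft16$to_reference <- lapply(ft$to_reference[1:5], function(u) u[1:16, 1:16, , drop = FALSE])
  ft16$from_reference <- lapply(ft$from_reference[1:5], function(u) u[1:16, 1:16, , drop = FALSE])
  set.seed(5)
  X <- array(complex(real = rnorm(16 * 16 * 5), imaginary = rnorm(16 * 16 * 5)),
             c(16, 16, 5))
  Y <- array(complex(real = rnorm(16 * 16 * 3 * 5), imaginary = rnorm(16 * 16 * 3 * 5)),
             c(16, 16, 3, 5))
  lhs <- sum(Conj(Y) * mc_forward(X, ft16, coils, mask))
  rhs <- sum(Conj(mc_adjoint(Y, ft16, coils, mask)) * X)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  expect_equal(max(abs(mc_forward(X * 0, ft16, coils, mask))), 0)
})

test_that("kt-SLR with zero weights at R = 1 reproduces the zero-filled recon", {
  # static phantom: the warp operators are the identity, so the data-term-
  # only solve must converge to the zero-filled solution
  gts <- generate_cine_phantom(phantom_config(grid_size = 48, n_frames = 9,
                                              n_slices = 1,
                                              contraction_amplitude = 0,
                                              rotation_amplitude = 0,
                                              seed = 8))
  d <- dim(gts$images)
  coils <- generate_coil_maps(4, d[1:2])
  mask1 <- generate_kt_mask(c(5, d[1]), R = 1, seed = 1)
  b <- simulate_kspace(gts$images_clean[, , 1:5], coils, mask1)
  ft <- phantom_flow_table(gts, frames = 1:5)
  res <- ktslr_reconstruct(b, ft, moco_config(lambda_lowrank = 0,
                                              lambda_sparse = 0, n_iters = 25))
  zf <- zero_filled_recon(b)
  expect_lt(max(abs(res$recon - zf)) / max(zf), 1e-3)
})

test_that("motion-compensated recon beats zero-filling at R = 8 with a monotone objective", {
  gt <- fix_phantom()
  bundle <- fix_bundle(8)
  T <- dim(gt$images)[3]
  ft <- phantom_flow_table(gt, frames = 1:T)
  res <- ktslr_reconstruct(bundle, ft, moco_config(n_iters = 25))
  ref <- zero_filled_recon(bundle, use_full = TRUE)
  zf <- zero_filled_recon(bundle)
  expect_lt(nrmse(res$recon, ref), nrmse(zf, ref))
  mean_ssim <- function(x) mean(vapply(seq_len(T), function(t)
    ssim(x[, , t], ref[, , t]), numeric(1)))
  expect_gt(mean_ssim(res$recon), mean_ssim(zf))
  o <- res$objective
  expect_true(all(diff(o) <= 1e-5 * pmax(abs(o[-length(o)]), 1e-12)))
})

test_that("perfectly aligned noise-free frames are near rank one", {
  cfg <- phantom_config(grid_size = 48, n_frames = 9, n_slices = 1,
                        noise_sigma = 0, texture_amplitude = 0.12, seed = 31)
  gt <- generate_cine_phantom(cfg)
  aligned <- array(0, c(48, 48, 5))
  for (t in 1:5)
    aligned[, , t] <- warp_image(gt$images_clean[, , t], gt$true_flows(1, t))
  s <- svd(matrix(aligned, 48 * 48, 5), nu = 0, nv = 0)$d
  expect_lt(s[2] / s[1], 0.05)
})

test_that("reconstruction quality degrades with acceleration on average", {
  mean_ssim_at <- function(R, seed) {
    cfg <- phantom_config(grid_size = 32, n_frames = 5, n_slices = 1,
                          heart_scale = 1.4, seed = seed)
    gt <- generate_cine_phantom(cfg)
    coils <- generate_coil_maps(3, c(32, 32))
    mask <- generate_kt_mask(c(5, 32), R = R, acs_lines = 4, seed = seed + 100)
    b <- simulate_kspace(gt$images_clean, coils, mask, noise_sigma = 0.002,
                         seed = seed)
    ft <- phantom_flow_table(gt, frames = 1:5)
    res <- ktslr_reconstruct(b, ft, moco_config(n_iters = 12))
    ref <- zero_filled_recon(b, use_full = TRUE)
    mean(vapply(1:5, function(t) ssim(res$recon[, , t], ref[, , t]), numeric(1)))
  }
  seeds <- 1:5
  s_low <- mean(vapply(seeds, function(s) mean_ssim_at(2, s), numeric(1)))
  s_mid <- mean(vapply(seeds, function(s) mean_ssim_at(4, s), numeric(1)))
  s_high <- mean(vapply(seeds, function(s) mean_ssim_at(8, s), numeric(1)))
  expect_gt(s_low, s_mid)
  expect_gt(s_mid, s_high)
})
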