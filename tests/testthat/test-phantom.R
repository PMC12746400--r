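test_that("config invariants are enforced", {
  expect_error(phantom_config(grid_size = 16), "grid_size")
  expect_error(phantom_config(n_frames = 3), "n_frames")
  expect_error(phantom_config(contraction_amplitude = 0.6),
               "self-intersection")
})

test_that("a static phantom produces identical frames and zero flows", {
  cfg <- phantom_config(grid_size = 32, n_frames = 5, n_slices = 1,
                        contraction_amplitude = 0, rotation_amplitude = 0,
                        noise_sigma = 0, seed = 4)
  gt <- generate_cine_phantom(cfg)
  for (t in 2:5)
    expect_equal(gt$images[, , t], gt$images[, , 1], tolerance = 1e-12)
  u <- gt$true_flows(1, 4)
  expect_equal(max(abs(u)), 0)
})

test_that("contraction shrinks the LV pool and EF matches the closed form", {
  gt <- fix_phantom()
  areas <- vapply(1:dim(gt$labels)[3], function(t) sum(gt$labels[, , t] == 1L),
                  numeric(1))
  expect_lt(min(areas), areas[1])
  expect_equal(which.min(areas), gt$es_frame)

  # LV boundary sits where the radial weight is 1, so the area ratio is
  # (1 - alpha_es)^2 exactly
  a_es <- gt$config$contraction_amplitude *
    (1 - cos(2 * pi * (gt$es_frame - 1) / gt$config$n_frames)) / 2
  ef_closed <- 100 * (1 - (1 - a_es)^2)
  expect_lt(abs(phantom_true_ef(gt)$lvef - ef_closed), 1)
})

test_that("phantoms are deterministic in the seed", {
  cfg <- phantom_config(grid_size = 32, n_frames = 5, n_slices = 1, seed = 7)
  g1 <- generate_cine_phantom(cfg)
  g2 <- generate_cine_phantom(cfg)
  expect_identical(g1$images, g2$images)
  g3 <- generate_cine_phantom(phantom_config(grid_size = 32, n_frames = 5,
                                             n_slices = 1, seed = 8))
  expect_false(identical(g1$images, g3$images))
})

test_that("ground-truth flows are self-consistent with the rendered frames", {
  gt <- fix_phantom()
  # self-flow is identically zero
  expect_equal(max(abs(gt$true_flows(3, 3))), 0)
  # warping frame t by flow(1 -> t) recovers frame 1 below 2x noise
  for (t in c(4, gt$es_frame)) {
    u <- gt$true_flows(1, t)
    w <- warp_image(gt$images_clean[, , t], u)
    expect_lt(mean(abs(w - gt$images_clean[, , 1])),
              2 * gt$config$noise_sigma)
  }
  # labels are mutually exclusive and exhaustive
  expect_true(all(gt$labels %in% 0:3))
  # label maps deform with the same analytic map
  u <- gt$true_flows(1, gt$es_frame)
  warped_lab <- warp_image(gt$labels[, , gt$es_frame], u, mode = "nearest")
  agree <- mean(warped_lab == gt$labels[, , 1])
  expect_gt(agree, 0.97)
})

test_that("coil maps are smooth, positive in quadrature and reproducible", {
  C <- generate_coil_maps(8, c(24, 24))
  sos <- sqrt(apply(abs(C)^2, c(1, 2), sum))
  expect_true(all(sos > 0))
  expect_lt(max(abs(sos - 1)), 1e-10)   # normalised profile
  C1 <- generate_coil_maps(1, c(16, 16))
  expect_equal(abs(C1[, , 1]), matrix(1, 16, 16), tolerance = 1e-12)
})

test_that("k-t masks hit the acceleration budget with a guaranteed ACS block", {
  m1 <- generate_kt_mask(c(5, 64), R = 1, acs_lines = 4, seed = 1)
  expect_true(all(m1 == 1))

  m8 <- generate_kt_mask(c(25, 192), R = 8, acs_lines = 4, seed = 2)
  per_frame <- rowSums(m8)
  expect_true(all(per_frame == round(192 / 8)))
  expect_lt(abs(attr(m8, "R_realized") - 8) / 8, 0.1)
  # central ACS lines sampled in every frame
  ctr <- floor(192 / 2) + 1
  expect_true(all(m8[, (ctr - 2):(ctr + 1)] == 1))
  # incoherent across frames
  expect_gt(length(unique(apply(m8, 1, paste, collapse = ""))), 1)

  expect_identical(generate_kt_mask(c(5, 64), R = 8, acs_lines = 4, seed = 9),
                   generate_kt_mask(c(5, 64), R = 8, acs_lines = 4, seed = 9))
  expect_error(generate_kt_mask(c(5, 64), R = 32, acs_lines = 10),
               "infeasible")
})

test_that("k-space simulation is exact at R = 1 and energy-contractive", {
  gt <- fix_phantom()
  H <- dim(gt$images)[1]
  uniform <- array(1 + 0i, c(H, H, 1))
  mask1 <- generate_kt_mask(c(dim(gt$images)[3], H), R = 1, seed = 1)
  b <- simulate_kspace(gt$images_clean, uniform, mask1)
  rec <- Re(ifft2c(b$y[, , 1, 3]))
  expect_lt(max(abs(rec - gt$images_clean[, , 3])), 1e-9)

  b8 <- fix_bundle(8)
  expect_lte(sum(abs(b8$y)^2), sum(abs(b8$y_full)^2))
  zf <- zero_filled_recon(b8)
  ref <- zero_filled_recon(b8, use_full = TRUE)
  expect_gt(nrmse(zf, ref), 0)
})
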