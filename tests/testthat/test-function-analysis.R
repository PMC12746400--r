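test_that("volume summation and EF arithmetic are exact", {
  m <- array(0L, c(20, 20, 2))
  m[1:10, 1:10, 1] <- 1L   # 100 LV pixels at frame 1
  m[1:5, 1:10, 2] <- 1L    # 50 at frame 2
  vc <- ventricular_volumes(m, spacing = 2, slice_thickness = 8)
  expect_equal(vc$volumes$lv_ml[1], 100 * 4 * 8 / 1000)
  expect_equal(vc$lv$ed_frame, 1)
  expect_equal(ejection_fraction(vc$lv$edv, vc$lv$esv), 50)
  expect_equal(ejection_fraction(100, 50), 50)
  expect_equal(ejection_fraction(80, 80), 0)
  expect_error(ejection_fraction(0, 0), "EDV")
  # static masks: EDV = ESV
  ms <- array(m[, , 1], c(20, 20, 3))
  vs <- ventricular_volumes(ms, 2, 8)
  expect_equal(vs$lv$edv, vs$lv$esv)
  expect_error(ventricular_volumes(array(0L, c(8, 8, 2)), 1, 1), "empty")
})

test_that("phantom volumes match the analytic deformation within 3%", {
  gt <- fix_phantom3()
  vc <- ventricular_volumes(gt$slice_labels, gt$spacing, gt$slice_thickness)
  rel <- abs(vc$volumes$lv_ml - gt$true_volumes$lv_ml) / gt$true_volumes$lv_ml
  expect_lt(max(rel), 0.03)
  ef_true <- phantom_true_ef(gt)
  ef_est <- ejection_fraction(vc$lv$edv, vc$lv$esv)
  expect_lt(abs(ef_est - ef_true$lvef), 2)
})

test_that("Green-Lagrange strain matches closed forms", {
  # zero displacement
  E0 <- green_lagrange(array(0, c(10, 10, 2)))
  expect_equal(max(abs(unlist(E0))), 0)

  # homogeneous scaling u = alpha p: E = (alpha + alpha^2/2) I
  alpha <- 0.1
  g <- grid_coords(16, 16)
  u <- array(0, c(16, 16, 2))
  u[, , 1] <- alpha * (g$r - 8.5); u[, , 2] <- alpha * (g$c - 8.5)
  E <- green_lagrange(u)
  expected <- alpha + alpha^2 / 2
  i <- 2:15
  expect_lt(max(abs(E$E11[i, i] - expected)), 1e-6)
  expect_lt(max(abs(E$E22[i, i] - expected)), 1e-6)
  expect_lt(max(abs(E$E12[i, i])), 1e-6)

  # pure rotation: E = 0 (rigid motion invariance)
  th <- 0.3
  ur <- array(0, c(16, 16, 2))
  dr <- g$r - 8.5; dc <- g$c - 8.5
  ur[, , 1] <- (cos(th) * dr - sin(th) * dc) - dr
  ur[, , 2] <- (sin(th) * dr + cos(th) * dc) - dc
  Er <- green_lagrange(ur)
  expect_lt(max(abs(Er$E11[i, i])), 1e-6)
  expect_lt(max(abs(Er$E22[i, i])), 1e-6)
  expect_lt(max(abs(Er$E12[i, i])), 1e-6)
})

test_that("local coordinates give an orthonormal radial frame", {
  # perfect circle: r is the outward normal within 2 degrees
  g <- grid_coords(40, 40)
  rr <- sqrt((g$r - 20.5)^2 + (g$c - 20.5)^2)
  mask <- matrix(0L, 40, 40)
  mask[rr <= 12] <- 2L; mask[rr <= 7] <- 1L
  co <- local_coordinates(mask)
  ang_dev <- acos(pmin(1, abs(co$r1 * (g$r - co$center[1]) / pmax(rr, 1e-9) +
                                co$r2 * (g$c - co$center[2]) / pmax(rr, 1e-9))))
  expect_lt(max(ang_dev[co$myo_mask]) * 180 / pi, 2)
  # orthonormality everywhere defined
  expect_lt(max(abs(co$r1^2 + co$r2^2 - 1)), 1e-9)
  expect_lt(max(abs(co$r1 * co$c1 + co$r2 * co$c2)), 1e-12)
  # translation equivariance
  mask2 <- matrix(0L, 40, 40)
  mask2[cbind(pmin(pmax(which(mask > 0, arr.ind = TRUE)[, 1] + 3, 1), 40),
              which(mask > 0, arr.ind = TRUE)[, 2])] <- mask[mask > 0]
  co2 <- local_coordinates(mask2)
  expect_equal(co2$center[1], co$center[1] + 3, tolerance = 0.1)
  expect_error(local_coordinates(matrix(0L, 10, 10)), "contour")
})

test_that("strain projection respects isotropy and the trace identity", {
  g <- grid_coords(12, 12)
  mask <- matrix(0L, 12, 12)
  rr <- sqrt((g$r - 6.5)^2 + (g$c - 6.5)^2)
  mask[rr <= 5] <- 2L; mask[rr <= 2] <- 1L
  co <- local_coordinates(mask)
  beta <- 0.07
  E <- list(E11 = matrix(beta, 12, 12), E12 = matrix(0, 12, 12),
            E22 = matrix(beta, 12, 12))
  ps <- project_strain(E, co)
  expect_lt(max(abs(ps$Err - beta)), 1e-10)
  expect_lt(max(abs(ps$Ecc - beta)), 1e-10)
  # Err + Ecc = trace(E) for any symmetric tensor
  set.seed(3)
  Er <- list(E11 = matrix(rnorm(144), 12, 12), E12 = matrix(rnorm(144), 12, 12),
             E22 = matrix(rnorm(144), 12, 12))
  pr <- project_strain(Er, co)
  expect_lt(max(abs(pr$Err + pr$Ecc - (Er$E11 + Er$E22))), 1e-9)
})

test_that("phantom strain from truth flows matches the analytic value within 15%", {
  gt <- fix_phantom()
  es <- gt$es_frame
  u <- gt$true_flows(1, es)       # Lagrangian ED -> ES displacement
  E <- green_lagrange(u)
  co <- local_coordinates(gt$labels[, , 1])
  ps <- project_strain(E, co, myo_mask = gt$true_strain$myo_mask)
  expect_gt(ps$mGRS, 0)   # wall thickening
  expect_lt(ps$mGCS, 0)   # circumferential shortening
  expect_lt(abs(ps$mGRS - gt$true_strain$mGRS) / abs(gt$true_strain$mGRS), 0.15)
  expect_lt(abs(ps$mGCS - gt$true_strain$mGCS) / abs(gt$true_strain$mGCS), 0.15)
})

test_that("AHA-17 segmentation of the myocardium behaves as a partition", {
  g <- grid_coords(40, 40)
  rr <- sqrt((g$r - 20.5)^2 + (g$c - 20.5)^2)
  myo <- rr <= 12 & rr > 7
  ctr <- c(20.5, 20.5)
  uniform <- matrix(0.3, 40, 40)
  segs <- aha17_bullseye(list(uniform, uniform, uniform),
                         list(myo, myo, myo), list(ctr, ctr, ctr))
  filled <- !is.na(segs)
  expect_equal(sum(filled), 16)           # apex cap missing without a cap slice
  expect_true(all(abs(segs[filled] - 0.3) < 1e-12))
  expect_true(is.na(segs[17]))

  # a hot wedge in one basal sector elevates exactly one basal segment
  hot <- uniform
  ang <- atan2(g$r - ctr[1], g$c - ctr[2]) %% (2 * pi)
  hot[ang < pi / 3] <- 1.5
  segs2 <- aha17_bullseye(list(hot, uniform, uniform),
                          list(myo, myo, myo), list(ctr, ctr, ctr))
  expect_equal(sum(segs2[1:6] > 0.4, na.rm = TRUE), 1)
  expect_true(all(abs(segs2[7:12] - 0.3) < 1e-12))
})

test_that("the full functional report runs on a 3-slice phantom", {
  gt <- fix_phantom3()
  ft <- phantom_flow_table(gt, frames = seq_len(gt$config$n_frames))
  rep <- analyze_function(gt$slice_labels, ft, gt$spacing, gt$slice_thickness)
  ef_true <- phantom_true_ef(gt)
  expect_lt(abs(rep$lvef - ef_true$lvef), 2)
  expect_gt(rep$strain$mGRS, 0)
  expect_lt(rep$strain$mGCS, 0)
  expect_equal(length(rep$bullseye_err), 17)
})
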