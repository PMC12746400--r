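test_that("tri-frame grouping follows the overlapping layout", {
  frames <- array(0, c(4, 4, 5))
  for (t in 1:5) frames[, , t] <- t
  g <- build_tri_frame_groups(frames)
  expect_equal(g$bwd[1, 1, ], c(1, 2, 3))
  expect_equal(g$fixed[1, 1, ], c(2, 3, 4))
  expect_equal(g$fwd[1, 1, ], c(3, 4, 5))
  same <- array(7, c(4, 4, 5))
  gs <- build_tri_frame_groups(same)
  expect_identical(gs$bwd, gs$fwd)
  expect_error(build_tri_frame_groups(frames[, , 1:4]), "5 frames")
})

test_that("the shared encoder and attention meet their contracts", {
  set.seed(2)
  cfg <- mopnet_config("tiny")
  w <- mopnet_init(cfg)
  frames <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  # palindromic frames make the backward and forward stacks identical
  frames[, , 4] <- frames[, , 2]; frames[, , 5] <- frames[, , 1]
  g <- build_tri_frame_groups(frames)
  fs <- extract_features(g, cfg, w)
  expect_equal(ad_value(fs$feat[[1]]), ad_value(fs$feat[[5]]))
  expect_equal(fs$grid, dim(frames)[1:2] / cfg$feature_downsample)
  for (m in 1:3) {
    rows <- rowSums(ad_value(fs$attn[[m]]))
    expect_lt(max(abs(rows - 1)), 1e-5)
  }
})

test_that("correlation volumes match the brute-force all-pairs oracle", {
  ad <- asNamespace("cinemop")
  set.seed(3)
  C <- 8
  f1 <- matrix(rnorm(36 * C), 36, C)   # 6x6 grid
  f2 <- matrix(rnorm(36 * C), 36, C)
  corr <- ad$ad_value(ad$ad_correlation(ad$ad_const(f1), ad$ad_const(f2)))
  oracle <- matrix(0, 36, 36)
  for (i in 1:36) for (j in 1:36)
    oracle[i, j] <- sum(f1[i, ] * f2[j, ]) / sqrt(C)
  expect_lt(max(abs(corr - oracle)), 1e-5)
  # self-correlation of unit-norm features: the best match of each query
  # is itself (for raw dot products a longer vector could win)
  f1n <- f1 / sqrt(rowSums(f1^2))
  self_corr <- ad$ad_value(ad$ad_correlation(ad$ad_const(f1n), ad$ad_const(f1n)))
  expect_equal(apply(self_corr, 1, which.max), 1:36)
})

test_that("windowed lookup matches a nested-loop gather oracle", {
  ad <- asNamespace("cinemop")
  set.seed(4)
  Hl <- 5; Wl <- 5; N <- Hl * Wl
  corr <- matrix(rnorm(N * N), N, N)    # level-0 volume on a 5x5 grid
  rc <- cbind(rep(1:Hl, Wl) + runif(N, -0.4, 0.4),
              rep(1:Wl, each = Hl) + runif(N, -0.4, 0.4))
  radius <- 1
  lk <- ad$ad_value(ad$ad_corr_lookup(ad$ad_const(corr), Hl, Wl,
                                      ad$ad_const(rc), radius))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  bil <- function(q, r, c) {
    r <- min(max(r, 1), Hl); c <- min(max(c, 1), Wl)
    r0 <- min(max(floor(r), 1), Hl); r1 <- min(r0 + 1, Hl)
    c0 <- min(max(floor(c), 1), Wl); c1 <- min(c0 + 1, Wl)
    wr <- r - r0; wc <- c - c0
    v <- function(rr, cc) corr[q, rr + (cc - 1) * Hl]
    (1 - wr) * (1 - wc) * v(r0, c0) + wr * (1 - wc) * v(r1, c0) +
      (1 - wr) * wc * v(r0, c1) + wr * wc * v(r1, c1)
  }
  oracle <- matrix(0, N, nrow(offs))
  for (q in 1:N) for (k in seq_len(nrow(offs)))
    oracle[q, k] <- bil(q, rc[q, 1] + offs$dr[k], rc[q, 2] + offs$dc[k])
  expect_lt(max(abs(lk - oracle)), 1e-5)
  # zero displacement keeps the window centred on the query pixel
  rc0 <- cbind(rep(1:Hl, Wl), rep(1:Wl, each = Hl))
  lk0 <- ad$ad_value(ad$ad_corr_lookup(ad$ad_const(corr), Hl, Wl,
                                       ad$ad_const(rc0), 0))
  expect_equal(as.vector(lk0), corr[cbind(1:N, (rc0[, 2] - 1) * Hl + rc0[, 1])])
})

test_that("motion propagation warps and reassigns hidden states", {
  ad <- asNamespace("cinemop")
  set.seed(5)
  cfg <- mopnet_config("tiny")
  w <- mopnet_init(cfg)
  h <- 8; Ch <- cfg$hidden_channels; C <- cfg$feature_channels
  st <- list(fixed = ad$ad_const(array(rnorm(h * h * Ch), c(h, h, Ch))),
             fwd = ad$ad_const(array(rnorm(h * h * Ch), c(h, h, Ch))),
             bwd = ad$ad_const(array(rnorm(h * h * Ch), c(h, h, Ch))))
  zero_u <- ad$ad_const(array(0, c(h, h, 2)))
  fc <- ad$ad_const(array(rnorm(h * h * C), c(h, h, C)))
  ff <- ad$ad_const(array(rnorm(h * h * C), c(h, h, C)))
  mo <- mop_update(st, zero_u, zero_u, fc, ff, w, cfg)
  # identity warps: neighbour states pass through exactly (Mk+ = Mfwd)
  expect_equal(ad_value(mo$states$fwd), ad_value(st$fwd), tolerance = 1e-12)
  expect_equal(ad_value(mo$states$bwd), ad_value(st$bwd), tolerance = 1e-12)
  # fixed state is re-encoded and tanh-bounded
  expect_true(all(abs(ad_value(mo$states$fixed)) < 1))
})

test_that("the GRU step is bounded and produces residual flows of the right shape", {
  ad <- asNamespace("cinemop")
  set.seed(6)
  cfg <- mopnet_config("tiny")
  w <- mopnet_init(cfg)
  h <- 8; C <- cfg$feature_channels; Cc <- cfg$context_channels
  fm <- ad$ad_const(array(rnorm(h * h * C), c(h, h, C)))
  attn <- ad$ad_softmax_rows(ad$ad_const(matrix(rnorm(h^4), h^2, h^2)))
  ctx <- ad$ad_const(array(rnorm(h * h * Cc), c(h, h, Cc)))
  hid <- ad$ad_tanh(ad$ad_const(array(rnorm(h * h * cfg$hidden_channels),
                                      c(h, h, cfg$hidden_channels))))
  gu <- gru_update_step(fm, attn, ctx, hid, w, cfg)
  expect_equal(dim(ad_value(gu$delta_bwd)), c(h, h, 2))
  expect_equal(dim(ad_value(gu$delta_fwd)), c(h, h, 2))
  expect_true(all(abs(ad_value(gu$hidden)) < 1))
})

test_that("motion estimation is zero at K = 0 and deterministic", {
  set.seed(7)
  cfg <- mopnet_config("tiny")
  w <- mopnet_init(cfg)
  frames <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  fp0 <- estimate_motion(frames, mopnet_config("tiny", K = 0L), w)
  expect_equal(max(abs(fp0$ufwd)), 0)
  expect_equal(max(abs(fp0$ubwd)), 0)
  fp1 <- estimate_motion(frames, cfg, w)
  fp2 <- estimate_motion(frames, cfg, w)
  expect_identical(fp1$ufwd, fp2$ufwd)
  # K snapshots are retained when training through the call
  fp3 <- estimate_motion(frames, cfg, w, keep_tape = TRUE)
  expect_length(fp3$snapshots, cfg$K)
})

test_that("full-cycle inference tiles the cyclic pairs exactly once and reaches all frames", {
  set.seed(8)
  cfg <- mopnet_config("tiny", K = 1L)
  w <- mopnet_init(cfg)
  gt <- memo("phantom_t12", {
    generate_cine_phantom(phantom_config(grid_size = 32, n_frames = 12,
                                         n_slices = 1, heart_scale = 1.5,
                                         seed = 13))
  })
  ft <- full_cycle_inference(gt$images, cfg, w)
  T <- 12
  keys <- paste0(ft$pairs$from, "->", ft$pairs$to)
  expect_equal(anyDuplicated(keys), 0)
  # every pair is a cyclic adjacent step
  expect_true(all((ft$pairs$to - ft$pairs$from) %% T == 1))
  # transitive closure reaches the reference from every frame
  reach <- function(f) {
    seen <- f
    while (utils::tail(seen, 1) != ft$reference) {
      nxt <- ft$pairs$to[ft$pairs$from == utils::tail(seen, 1)]
      if (length(nxt) == 0) return(FALSE)
      seen <- c(seen, nxt[1])
      if (length(seen) > T + 1) return(FALSE)
    }
    TRUE
  }
  expect_true(all(vapply(1:T, reach, logical(1))))
  # the cyclic wrap pair is present
  expect_true(any(ft$pairs$from == T & ft$pairs$to == 1))
  # composed flows exist for every frame in both directions
  expect_length(ft$to_reference, T)
  expect_length(ft$from_reference, T)
  expect_error(full_cycle_inference(gt$images[, , 1:4], cfg, w), "at least 5")
})

test_that("checkpoints round-trip weights, config and seed", {
  cfg <- mopnet_config("tiny", seed = 42L)
  w <- mopnet_init(cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(w, path)
  w2 <- load_checkpoint(path)
  expect_equal(attr(w2, "cfg")$seed, 42L)
  expect_equal(ad_value(w2$fenc$c1$w), ad_value(w$fenc$c1$w))
  bad <- readRDS(path); bad$schema <- 99L
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "schema")
})
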