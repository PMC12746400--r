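# Shared fixtures, memoised so expensive phantoms are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 48x48 whole-FOV phantom, 9 frames, one slice: geometry/k-space tests
fix_phantom <- function() memo("phantom48", {
  generate_cine_phantom(phantom_config(grid_size = 48, n_frames = 9,
                                       n_slices = 1, n_coils = 4, seed = 11))
})

# 3-slice phantom for volumes / strain / AHA tests
fix_phantom3 <- function() memo("phantom3sl", {
  generate_cine_phantom(phantom_config(grid_size = 48, n_frames = 9,
                                       n_slices = 3, n_coils = 4,
                                       heart_scale = 1.2, seed = 21))
})

# heart-cropped 32x32 patch phantom (registration-scale motion)
fix_patch <- function(seed = 5) memo(paste0("patch", seed), {
  generate_cine_phantom(phantom_config(grid_size = 32, n_frames = 5,
                                       n_slices = 1, heart_scale = 2,
                                       seed = seed))
})

# k-space bundle of the 48x48 phantom at a given acceleration
fix_bundle <- function(R = 8) memo(paste0("bundle", R), {
  gt <- fix_phantom()
  d <- dim(gt$images)
  coils <- generate_coil_maps(4, d[1:2])
  mask <- generate_kt_mask(c(d[3], d[1]), R = R, acs_lines = 4, seed = 2)
  simulate_kspace(gt$images_clean, coils, mask, noise_sigma = 0.002, seed = 3)
})

# brute-force bilinear sampling oracle (independent of warp_image)
oracle_warp <- function(src, flow) {
  H <- nrow(src); W <- ncol(src)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    r <- min(max(i + flow[i, j, 1], 1), H)
    c <- min(max(j + flow[i, j, 2], 1), W)
    r0 <- min(max(floor(r), 1), H); r1 <- min(r0 + 1, H)
    c0 <- min(max(floor(c), 1), W); c1 <- min(c0 + 1, W)
    wr <- r - r0; wc <- c - c0
    out[i, j] <- (1 - wr) * (1 - wc) * src[r0, c0] + wr * (1 - wc) * src[r1, c0] +
      (1 - wr) * wc * src[r0, c1] + wr * wc * src[r1, c1]
  }
  out
}

# smooth small random flow for property tests
smooth_flow <- function(H, W, amp = 1, seed = 1) {
  set.seed(seed)
  sm <- function() {
    z <- matrix(stats::rnorm(H * W), H, W)
    k <- matrix(1 / 9, 3, 3)
    p <- z
    for (rep in 1:4) {
      q <- p
      for (i in 2:(H - 1)) for (j in 2:(W - 1))
        q[i, j] <- sum(p[(i - 1):(i + 1), (j - 1):(j + 1)] * k)
      p <- q
    }
    p / max(abs(p)) * amp
  }
  u <- array(0, c(H, W, 2)); u[, , 1] <- sm(); u[, , 2] <- sm()
  u
}
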