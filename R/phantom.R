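# Synthetic 2D+t short-axis cine phantom with analytically known motion.
#
# The scene is an annular myocardium around a circular LV blood pool, an
# adjacent crescent-shaped RV blood pool and a static background. The
# deformation is a radially weighted contraction plus twist about the LV
# centre,
#     r' = r * (1 - alpha(t) * w(r)),   theta' = theta + beta(t) * w(r),
# with a smooth radial weight w(r) that equals 1 inside the LV pool,
# decays across the myocardium (fast enough that the wall thickens as it
# contracts, as a real myocardium does) and vanishes in the far field so
# the background is static. alpha(t) and beta(t) follow a raised-cosine
# cardiac cycle: frame 1 is end-diastole, mid-cycle is end-systole. The
# radial profile g(r) = r (1 - alpha w(r)) is strictly monotone for
# alpha < 0.5, so its inverse (needed for rendering and for ground-truth
# flow between any two frames) is obtained exactly by a few Newton steps
# on a 1-D monotone function.

#' Phantom configuration
#'
#' Defaults emulate the acquisition the package targets: 25 cardiac phases,
#' 1.9 mm in-plane resolution, 8 mm slices on a 192x192 grid, with a peak
#' radial contraction of 0.2 (LV area EF of 36% per slice) and a small
#' twist. `n_slices` short-axis slices are generated with apically
#' decreasing radii for volumetric and AHA-17 work.
#'
#' @param grid_size integer (H, W), each >= 32.
#' @param n_frames number of cardiac phases T (>= 5).
#' @param pixel_spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @param n_slices number of short-axis slices.
#' @param contraction_amplitude peak radial shrink fraction alpha_max in \[0, 0.5).
#' @param rotation_amplitude peak twist, radians.
#' @param noise_sigma sd of additive Gaussian intensity noise (intensity
#'   scale is roughly \[0, 1\]).
#' @param texture_amplitude amplitude of the smooth tissue texture that is
#'   advected with the deformation (gives optical flow local contrast, as
#'   trabeculation and coil shading do in vivo).
#' @param n_coils number of synthetic receiver coils.
#' @param heart_scale field-of-view zoom: 1 shows the whole thorax-like
#'   FOV, larger values emulate a patch cropped around the heart (the
#'   ventricular radii grow by this factor relative to the grid).
#' @param seed integer RNG seed; same seed gives bit-identical phantoms.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_size = c(192, 192), n_frames = 25,
                           pixel_spacing = 1.9, slice_thickness = 8,
                           n_slices = 3, contraction_amplitude = 0.2,
                           rotation_amplitude = 0.1, noise_sigma = 0.02,
                           texture_amplitude = 0.12, n_coils = 8,
                           heart_scale = 1, seed = 1L) {
  grid_size <- as.integer(grid_size)
  if (length(grid_size) == 1) grid_size <- c(grid_size, grid_size)
  if (any(grid_size < 32)) stop("grid_size must be >= 32 in each dimension")
  if (n_frames < 5) stop("n_frames must be >= 5")
  if (contraction_amplitude < 0 || contraction_amplitude >= 0.5)
    stop("contraction_amplitude must lie in [0, 0.5) (annulus self-intersection)")
  structure(list(
    grid_size = grid_size, n_frames = as.integer(n_frames),
    pixel_spacing = pixel_spacing, slice_thickness = slice_thickness,
    n_slices = as.integer(n_slices),
    contraction_amplitude = contraction_amplitude,
    rotation_amplitude = rotation_amplitude,
    noise_sigma = noise_sigma, texture_amplitude = texture_amplitude,
    n_coils = as.integer(n_coils), heart_scale = heart_scale,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# geometry derived from the grid: radii in pixels, LV centre slightly right
# of the image centre so the RV crescent (on the left) stays in the FOV
phantom_geometry <- function(cfg) {
  H <- cfg$grid_size[1]; W <- cfg$grid_size[2]
  S <- min(H, W) * (cfg$heart_scale %||% 1)
  r_lv <- 0.14 * S
  r_epi <- 0.24 * S
  list(
    H = H, W = W,
    center = c((H + 1) / 2, (W + 1) / 2 + 0.05 * S),
    r_lv = r_lv, r_epi = r_epi,
    r_taper_end = 1.3 * r_epi,            # w(r) support; RV is mostly static
    rv_center_off = -1.35 * r_epi,        # column offset of the RV disk
    rv_radius = 0.95 * r_epi,
    rv_wall = 0.18 * r_epi,
    slice_scale = if (cfg$n_slices == 1) 1 else
      1 - 0.25 * (seq_len(cfg$n_slices) - 1) / (cfg$n_slices - 1)
  )
}

# radial deformation weight and derivative: 1 inside the LV pool, cosine
# taper to 0 at r_taper_end (steeper than 1/r across the wall -> thickening)
radial_weight <- function(r, geom, deriv = FALSE) {
  r0 <- geom$r_lv; r2 <- geom$r_taper_end
  x <- (r - r0) / (r2 - r0)
  w <- ifelse(r <= r0, 1, ifelse(r >= r2, 0, 0.5 * (1 + cos(pi * x))))
  if (!deriv) return(w)
  dw <- ifelse(r <= r0 | r >= r2, 0, -0.5 * pi * sin(pi * x) / (r2 - r0))
  list(w = w, dw = dw)
}

# raised-cosine cycle: 0 at frame 1 (ED), peak mid-cycle (ES)
phase_profile <- function(t, T) (1 - cos(2 * pi * (t - 1) / T)) / 2

phantom_alpha <- function(cfg, t) cfg$contraction_amplitude * phase_profile(t, cfg$n_frames)
phantom_beta  <- function(cfg, t) cfg$rotation_amplitude  * phase_profile(t, cfg$n_frames)

# forward map (reference -> frame t) applied to reference polar coords
forward_radius <- function(r, alpha, geom) r * (1 - alpha * radial_weight(r, geom))

# invert r' = r (1 - alpha w(r)) by Newton; monotone for alpha < 0.5
inverse_radius <- function(rp, alpha, geom) {
  if (alpha == 0) return(rp)
  r <- rp
  for (i in 1:50) {
    wd <- radial_weight(r, geom, deriv = TRUE)
    g <- r * (1 - alpha * wd$w)
    gp <- 1 - alpha * (wd$w + r * wd$dw)
    step <- (g - rp) / pmax(gp, 0.05)
    r <- pmax(r - step, 0)
    if (max(abs(step)) < 1e-12) break
  }
  r
}

# map points in frame-t coordinates back to reference coordinates
phantom_inverse_map <- function(pr, pc, cfg, geom, t, slice_scale = 1) {
  gs <- phantom_geometry_scaled(geom, slice_scale)
  dr <- pr - gs$center[1]; dc <- pc - gs$center[2]
  rp <- sqrt(dr^2 + dc^2); th <- atan2(dr, dc)
  r0 <- inverse_radius(rp, phantom_alpha(cfg, t), gs)
  th0 <- th - phantom_beta(cfg, t) * radial_weight(r0, gs)
  list(r = gs$center[1] + r0 * sin(th0), c = gs$center[2] + r0 * cos(th0))
}

# map reference coordinates forward into frame-t coordinates
phantom_forward_map <- function(pr, pc, cfg, geom, t, slice_scale = 1) {
  gs <- phantom_geometry_scaled(geom, slice_scale)
  dr <- pr - gs$center[1]; dc <- pc - gs$center[2]
  r <- sqrt(dr^2 + dc^2); th <- atan2(dr, dc)
  w <- radial_weight(r, gs)
  rt <- r * (1 - phantom_alpha(cfg, t) * w)
  tht <- th + phantom_beta(cfg, t) * w
  list(r = gs$center[1] + rt * sin(tht), c = gs$center[2] + rt * cos(tht))
}

phantom_geometry_scaled <- function(geom, s) {
  g <- geom
  for (f in c("r_lv", "r_epi", "r_taper_end", "rv_center_off", "rv_radius", "rv_wall"))
    g[[f]] <- geom[[f]] * s
  g
}

# tissue class of reference-frame positions: 0 bg, 1 LV pool, 2 myo, 3 RV pool
phantom_class <- function(pr, pc, geom, slice_scale = 1) {
  gs <- phantom_geometry_scaled(geom, slice_scale)
  dr <- pr - gs$center[1]; dc <- pc - gs$center[2]
  r <- sqrt(dr^2 + dc^2)
  rv_c <- c(gs$center[1], gs$center[2] + gs$rv_center_off)
  r_rv <- sqrt((pr - rv_c[1])^2 + (pc - rv_c[2])^2)
  lab <- integer(length(r)); dim(lab) <- dim(r)
  lab[r_rv <= gs$rv_radius & r > gs$r_epi + gs$rv_wall] <- 3L
  lab[r <= gs$r_epi] <- 2L
  lab[r <= gs$r_lv] <- 1L
  lab
}

tissue_intensity <- c(`0` = 0.15, `1` = 0.95, `2` = 0.40, `3` = 0.90)

# smooth unit-variance random field (Gaussian-filtered white noise, FFT)
smooth_random_field <- function(H, W, sigma = 2.5) {
  z <- matrix(stats::rnorm(H * W), H, W)
  kr <- c(0:(floor(H / 2)), -((ceiling(H / 2) - 1):1)) / H
  kc <- c(0:(floor(W / 2)), -((ceiling(W / 2) - 1):1)) / W
  K <- exp(-2 * pi^2 * sigma^2 * (outer(kr^2, rep(1, W)) + outer(rep(1, H), kc^2)))
  f <- Re(stats::fft(stats::fft(z) * K, inverse = TRUE)) / (H * W)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a deforming cardiac cine phantom with ground truth
#'
#' Renders `n_frames` frames of the analytic phantom per slice, together
#' with 4-class label maps (0 background, 1 LV pool, 2 myocardium, 3 RV
#' pool), exact dense displacement fields between any two frames, analytic
#' per-frame ventricular volumes and the analytic end-systolic
#' radial/circumferential strain of the imposed deformation.
#'
#' The returned `true_flows(i, j)` closure evaluates the exact flow field
#' from frame `i` to frame `j` (backward-warp convention: warping frame `j`
#' with it resamples it onto frame `i`'s geometry) on demand; storing all
#' T^2 fields densely would be wasteful.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_truth` list with elements `images` (H, W, T, mid
#'   slice), `images_clean`, `labels` (H, W, T), `slice_labels`
#'   (H, W, T, n_slices), `true_flows(i, j, slice)`, `true_volumes`
#'   (data.frame frame/lv_ml/rv_ml), `true_strain`, `config`, `geom`.
#' @export
generate_cine_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config; geom <- phantom_geometry(cfg)
  H <- geom$H; W <- geom$W; T <- cfg$n_frames
  set.seed(cfg$seed)
  texture <- smooth_random_field(H, W, sigma = 2.5)
  bias <- 0.08 * smooth_random_field(H, W, sigma = min(H, W) / 4)
  noise <- array(stats::rnorm(H * W * T, sd = cfg$noise_sigma), c(H, W, T))

  g <- grid_coords(H, W)
  mid_slice <- (cfg$n_slices + 1) %/% 2
  render_slice <- function(s) {
    imgs <- array(0, c(H, W, T)); labs <- array(0L, c(H, W, T))
    for (t in seq_len(T)) {
      ref <- phantom_inverse_map(g$r, g$c, cfg, geom, t, geom$slice_scale[s])
      lab <- phantom_class(ref$r, ref$c, geom, geom$slice_scale[s])
      base <- tissue_intensity[as.character(lab)]
      dim(base) <- c(H, W)
      tex <- sample_bilinear(texture, ref$r, ref$c)
      imgs[, , t] <- base * (1 + bias) + cfg$texture_amplitude * tex
      labs[, , t] <- lab
    }
    list(images = imgs, labels = labs)
  }

  slice_labels <- array(0L, c(H, W, T, cfg$n_slices))
  images_clean <- NULL; labels_mid <- NULL
  for (s in seq_len(cfg$n_slices)) {
    sl <- render_slice(s)
    slice_labels[, , , s] <- sl$labels
    if (s == mid_slice) { images_clean <- sl$images; labels_mid <- sl$labels }
  }
  images <- images_clean + noise

  true_flows <- function(i, j, slice = mid_slice) {
    stopifnot(i >= 1, i <= T, j >= 1, j <= T)
    s <- geom$slice_scale[slice]
    ref <- phantom_inverse_map(g$r, g$c, cfg, geom, i, s)
    tgt <- phantom_forward_map(ref$r, ref$c, cfg, geom, j, s)
    u <- array(0, c(H, W, 2))
    u[, , 1] <- tgt$r - g$r; u[, , 2] <- tgt$c - g$c
    u
  }

  # analytic volumes: LV pool radius maps in closed form; RV crescent area
  # integrated on a 2x refined grid through the exact inverse map
  px_area_mm2 <- cfg$pixel_spacing^2
  lv_ml <- rv_ml <- numeric(T)
  fine <- 2
  gf <- grid_coords(H * fine, W * fine)
  gf$r <- (gf$r - 0.5) / fine + 0.25; gf$c <- (gf$c - 0.5) / fine + 0.25
  for (t in seq_len(T)) {
    a <- phantom_alpha(cfg, t)
    for (s in seq_len(cfg$n_slices)) {
      ss <- geom$slice_scale[s]
      r_lv_t <- forward_radius(geom$r_lv * ss, a, phantom_geometry_scaled(geom, ss))
      lv_ml[t] <- lv_ml[t] + pi * r_lv_t^2 * px_area_mm2 * cfg$slice_thickness / 1000
      ref <- phantom_inverse_map(gf$r, gf$c, cfg, geom, t, ss)
      lab <- phantom_class(ref$r, ref$c, geom, ss)
      rv_ml[t] <- rv_ml[t] + sum(lab == 3L) / fine^2 * px_area_mm2 *
        cfg$slice_thickness / 1000
    }
  }
  true_volumes <- data.frame(frame = seq_len(T), lv_ml = lv_ml, rv_ml = rv_ml)

  es_frame <- which.min(lv_ml)
  true_strain <- phantom_analytic_strain(cfg, geom, es_frame, labels_mid[, , 1])

  structure(list(
    images = images, images_clean = images_clean, labels = labels_mid,
    slice_labels = slice_labels, mid_slice = mid_slice,
    true_flows = true_flows, true_volumes = true_volumes,
    true_strain = true_strain, es_frame = es_frame,
    config = cfg, geom = geom,
    spacing = cfg$pixel_spacing, slice_thickness = cfg$slice_thickness
  ), class = "phantom_truth")
}

# analytic Green-Lagrange strain of the imposed ED->ES map, evaluated on
# the ED myocardium: for r' = g(r), theta' = theta + h(r),
#   Err = (g'^2 + g^2 h'^2 - 1) / 2,  Ecc = ((g/r)^2 - 1) / 2.
phantom_analytic_strain <- function(cfg, geom, es_frame, ed_labels) {
  gs <- phantom_geometry_scaled(geom, geom$slice_scale[(cfg$n_slices + 1) %/% 2])
  H <- geom$H; W <- geom$W
  g <- grid_coords(H, W)
  dr <- g$r - gs$center[1]; dc <- g$c - gs$center[2]
  r <- sqrt(dr^2 + dc^2)
  a <- phantom_alpha(cfg, es_frame); b <- phantom_beta(cfg, es_frame)
  wd <- radial_weight(r, gs, deriv = TRUE)
  gr <- r * (1 - a * wd$w)
  gp <- 1 - a * (wd$w + r * wd$dw)
  hp <- b * wd$dw
  Err <- (gp^2 + gr^2 * hp^2 - 1) / 2
  Ecc <- ((gr / pmax(r, 1e-9))^2 - 1) / 2
  myo <- ed_labels == 2L
  list(Err = Err, Ecc = Ecc, myo_mask = myo,
       mGRS = mean(Err[myo]), mGCS = mean(Ecc[myo]), es_frame = es_frame)
}

#' Closed-form ejection fractions of the imposed contraction
#'
#' The LV pool boundary sits where the radial weight is 1, so its
#' end-systolic radius is `r_lv (1 - alpha_es)` exactly; the EF follows
#' from the analytic per-slice areas. RV EF is derived from the analytic
#' volume curve.
#'
#' @param gt a `phantom_truth` object.
#' @return list with `lvef`, `rvef` (percent) and the ED/ES frame indices.
#' @export
phantom_true_ef <- function(gt) {
  v <- gt$true_volumes
  ed <- which.max(v$lv_ml); es <- which.min(v$lv_ml)
  list(
    lvef = 100 * (v$lv_ml[ed] - v$lv_ml[es]) / v$lv_ml[ed],
    rvef = 100 * (max(v$rv_ml) - min(v$rv_ml)) / max(v$rv_ml),
    ed_frame = ed, es_frame = es
  )
}

#' Synthesize smooth complex coil sensitivity maps
#'
#' Gaussian-weighted lobes centred outside the FOV at equally spaced
#' angles, each with a mild linear phase ramp. By default the maps are
#' normalised so the root-sum-of-squares magnitude is 1 at every pixel
#' (which makes the coil-combined forward operator unit-norm).
#'
#' @param n_coils number of coils (>= 1).
#' @param grid integer (H, W).
#' @param normalize normalise to unit root-sum-of-squares.
#' @return complex array (H, W, n_coils).
#' @export
generate_coil_maps <- function(n_coils, grid, normalize = TRUE) {
  stopifnot(n_coils >= 1)
  grid <- as.integer(grid)
  if (length(grid) == 1) grid <- c(grid, grid)
  H <- grid[1]; W <- grid[2]
  g <- grid_coords(H, W)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  rad <- 0.65 * max(H, W); sig <- 0.55 * max(H, W)
  C <- array(0i, c(H, W, n_coils))
  for (k in seq_len(n_coils)) {
    ang <- 2 * pi * (k - 1) / n_coils
    cc <- ctr + rad * c(sin(ang), cos(ang))
    d2 <- (g$r - cc[1])^2 + (g$c - cc[2])^2
    mag <- exp(-d2 / (2 * sig^2))
    phase <- 2 * pi * 0.3 * ((g$r - ctr[1]) * sin(ang + pi / 4) +
                               (g$c - ctr[2]) * cos(ang + pi / 4)) / max(H, W)
    C[, , k] <- mag * exp(1i * phase)
  }
  if (normalize) {
    sos <- sqrt(apply(abs(C)^2, c(1, 2), sum))
    for (k in seq_len(n_coils)) C[, , k] <- C[, , k] / sos
  }
  C
}

#' Variable-density incoherent k-t Cartesian sampling mask
#'
#' Binary ky-t mask for retrospective undersampling at acceleration `R`.
#' A central block of `acs_lines` auto-calibration lines is sampled in
#' every frame; the remaining per-frame budget is drawn without
#' replacement from a centre-weighted Gaussian density, independently per
#' frame, so the patterns are incoherent along time.
#'
#' @param shape integer (T, H_ky).
#' @param R nominal acceleration (>= 1).
#' @param acs_lines number of always-sampled central lines.
#' @param seed RNG seed.
#' @return binary matrix (T, H_ky) with attribute `R_realized`.
#' @export
generate_kt_mask <- function(shape, R, acs_lines = 4, seed = 1L) {
  T <- as.integer(shape[1]); H <- as.integer(shape[2])
  stopifnot(R >= 1, acs_lines >= 0, acs_lines < H)
  n_keep <- max(1L, as.integer(round(H / R)))
  if (acs_lines > n_keep)
    stop("infeasible mask: acs_lines (", acs_lines, ") exceed the per-frame ",
         "budget of ", n_keep, " lines at R = ", R)
  set.seed(as.integer(seed))
  center <- floor(H / 2) + 1L
  acs_idx <- if (acs_lines > 0)
    center - floor(acs_lines / 2) + seq_len(acs_lines) - 1L else integer(0)
  acs_idx <- acs_idx[acs_idx >= 1 & acs_idx <= H]
  mask <- matrix(0L, T, H)
  dens <- exp(-((seq_len(H) - center)^2) / (2 * (H / 6)^2))
  for (t in seq_len(T)) {
    mask[t, acs_idx] <- 1L
    rest <- setdiff(seq_len(H), acs_idx)
    n_extra <- n_keep - length(acs_idx)
    if (n_extra > 0) {
      pick <- sample(rest, size = min(n_extra, length(rest)), prob = dens[rest])
      mask[t, pick] <- 1L
    }
  }
  structure(mask, R_realized = T * H / sum(mask))
}

#' Simulate masked multi-coil k-space from a cine sequence
#'
#' Per coil and frame, k-space is `mask * F(C_c * image)` with the
#' centred orthonormal 2D Fourier transform. The fully sampled k-space is
#' retained alongside for reference metrics. Optionally adds complex
#' Gaussian noise in k-space (magnitude images then carry Rician noise).
#'
#' @param images real or complex array (H, W, T).
#' @param coils complex array (H, W, n_coils).
#' @param mask binary (T, H_ky) matrix (ky lines broadcast along kx).
#' @param noise_sigma sd of complex Gaussian k-space noise (0 = none).
#' @param seed RNG seed for the noise.
#' @return a `kspace_bundle` list: `y` (masked, H x W x n_coils x T),
#'   `y_full`, `coils`, `mask`, `R`.
#' @export
simulate_kspace <- function(images, coils, mask, noise_sigma = 0, seed = 1L) {
  d <- dim(images); H <- d[1]; W <- d[2]; T <- d[3]
  if (!all(dim(coils)[1:2] == c(H, W)))
    stop("coil map grid does not match the image grid")
  if (!all(dim(mask) == c(T, H)))
    stop("mask shape must be (T, H_ky) = (", T, ", ", H, ")")
  nc <- dim(coils)[3]
  y_full <- array(0i, c(H, W, nc, T))
  y <- array(0i, c(H, W, nc, T))
  if (noise_sigma > 0) set.seed(as.integer(seed))
  for (t in seq_len(T)) {
    for (k in seq_len(nc)) {
      kf <- fft2c(coils[, , k] * images[, , t])
      if (noise_sigma > 0)
        kf <- kf + complex(real = stats::rnorm(H * W, sd = noise_sigma),
                           imaginary = stats::rnorm(H * W, sd = noise_sigma))
      y_full[, , k, t] <- kf
      y[, , k, t] <- kf * mask[t, ]
    }
  }
  structure(list(y = y, y_full = y_full, coils = coils, mask = mask,
                 R = attr(mask, "R_realized")),
            class = "kspace_bundle")
}
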