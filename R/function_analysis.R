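# Ventricular function analysis: volume curves and ejection fractions
# from segmentation masks, Green-Lagrange strain from end-diastolic
# displacement fields, radial/circumferential projections in a
# contour-derived local coordinate frame, and AHA 17-segment summaries.

#' Ventricular volume curve from segmentation masks
#'
#' Simpson-style slice summation: per frame, volume = sum over slices of
#' (pool pixel count x pixel area x slice thickness). End-diastole is the
#' frame of maximal LV volume, end-systole the minimal.
#'
#' @param masks integer label array (H, W, T) for a single slice or
#'   (H, W, T, S) for S slices; classes 0 background, 1 LV pool, 2
#'   myocardium, 3 RV pool.
#' @param spacing in-plane pixel size, mm.
#' @param slice_thickness slice thickness, mm.
#' @return a `volume_curve` list: `volumes` (data.frame frame, lv_ml,
#'   rv_ml), `lv` and `rv` sublists with `edv`, `esv`, `ed_frame`,
#'   `es_frame`.
#' @export
ventricular_volumes <- function(masks, spacing, slice_thickness) {
  d <- dim(masks)
  if (length(d) == 3) { masks <- array(masks, c(d, 1)); d <- dim(masks) }
  T <- d[3]; S <- d[4]
  px_ml <- spacing^2 * slice_thickness / 1000
  count <- function(cl) vapply(seq_len(T), function(t)
    sum(masks[, , t, ] == cl), numeric(1))
  lv <- count(1L) * px_ml
  rv <- count(3L) * px_ml
  if (all(lv == 0)) stop("LV blood pool empty in every frame")
  curve <- function(v) {
    list(edv = max(v), esv = min(v),
         ed_frame = which.max(v), es_frame = which.min(v))
  }
  structure(list(volumes = data.frame(frame = seq_len(T), lv_ml = lv,
                                      rv_ml = rv),
                 lv = curve(lv), rv = if (any(rv > 0)) curve(rv) else NULL),
            class = "volume_curve")
}

#' Ejection fraction
#'
#' `100 (EDV - ESV) / EDV`, in percent.
#'
#' @param edv,esv end-diastolic / end-systolic volumes (any unit).
#' @return percentage.
#' @export
ejection_fraction <- function(edv, esv) {
  if (edv <= 0) stop("EDV must be positive")
  100 * (edv - esv) / edv
}

#' Green-Lagrange strain tensor of a displacement field
#'
#' `E = (grad(u) + grad(u)^T + grad(u)^T grad(u)) / 2` with
#' central-difference gradients (one-sided at borders). `u` is the
#' displacement from end-diastole to the frame of interest as a function
#' of end-diastolic position, in pixels; with isotropic pixel spacing the
#' strain is dimensionless and spacing-independent. Zero for any rigid
#' motion (translation or rotation).
#'
#' @param u (H, W, 2) displacement array, (row, col) components.
#' @return list of matrices `E11`, `E12`, `E22` (symmetric tensor fields).
#' @export
green_lagrange <- function(u) {
  stopifnot(all(is.finite(u)))
  g11 <- fd_gradient(u[, , 1], 1); g12 <- fd_gradient(u[, , 1], 2)
  g21 <- fd_gradient(u[, , 2], 1); g22 <- fd_gradient(u[, , 2], 2)
  list(
    E11 = 0.5 * (2 * g11 + g11^2 + g21^2),
    E12 = 0.5 * (g12 + g21 + g11 * g12 + g21 * g22),
    E22 = 0.5 * (2 * g22 + g12^2 + g22^2)
  )
}

#' Local radial/circumferential coordinate frame
#'
#' The epicardial contour is the boundary of (LV pool union myocardium)
#' in the end-diastolic mask; its centre of mass defines the origin.
#' Radial unit vectors point from the centre to each pixel (the contour
#' definition extended to the interior by angle), circumferential vectors
#' are their 90-degree counter-clockwise rotation, so `r . c = 0` and
#' both have unit norm wherever defined.
#'
#' @param ed_mask (H, W) integer label map at end-diastole.
#' @return list with unit-vector fields `r1`, `r2`, `c1`, `c2` (row/col
#'   components), `center`, `myo_mask`, and the contour point matrix.
#' @export
local_coordinates <- function(ed_mask) {
  epi <- ed_mask == 1L | ed_mask == 2L
  contour <- boundary_points(epi)
  if (is.null(contour) || nrow(contour) < 8)
    stop("epicardial contour degenerate (< 8 points)")
  center <- colMeans(contour)
  H <- nrow(ed_mask); W <- ncol(ed_mask)
  g <- grid_coords(H, W)
  dr <- g$r - center[1]; dc <- g$c - center[2]
  nrm <- pmax(sqrt(dr^2 + dc^2), 1e-9)
  r1 <- dr / nrm; r2 <- dc / nrm
  list(r1 = r1, r2 = r2, c1 = -r2, c2 = r1,
       center = center, myo_mask = ed_mask == 2L, contour = contour)
}

#' Project the strain tensor onto radial/circumferential directions
#'
#' `Err = r^T E r`, `Ecc = c^T E c` per pixel; with an orthonormal local
#' frame `Err + Ecc = trace(E)`. Global means (mGRS, mGCS) are taken over
#' the myocardial mask. Sign conventions: radial thickening gives
#' positive Err, circumferential shortening negative Ecc.
#'
#' @param E tensor fields from [green_lagrange()].
#' @param coords local frame from [local_coordinates()].
#' @param myo_mask optional logical mask overriding the frame's.
#' @return list with `Err`, `Ecc` fields and `mGRS`, `mGCS` scalars.
#' @export
project_strain <- function(E, coords, myo_mask = coords$myo_mask) {
  Err <- coords$r1^2 * E$E11 + 2 * coords$r1 * coords$r2 * E$E12 +
    coords$r2^2 * E$E22
  Ecc <- coords$c1^2 * E$E11 + 2 * coords$c1 * coords$c2 * E$E12 +
    coords$c2^2 * E$E22
  list(Err = Err, Ecc = Ecc,
       mGRS = mean(Err[myo_mask]), mGCS = mean(Ecc[myo_mask]))
}

#' AHA 17-segment bull's-eye summary
#'
#' Slices are classed basal / mid / apical by thirds of their position
#' (base first). Basal and mid slices contribute 6 segments of 60
#' degrees, apical slices 4 segments of 90 degrees, and segment 17 (apex
#' cap) is only filled when an apex-cap slice is supplied; an empty
#' segment is reported as `NA`, never as zero. The angular origin is the
#' anterior RV insertion (derived from the RV mask when present).
#'
#' @param strain_slices list over slices of per-pixel strain fields.
#' @param myo_slices list over slices of logical myocardium masks.
#' @param centers list over slices of (row, col) LV centres.
#' @param rv_masks optional list of RV masks used to derive the angular
#'   reference; defaults to angle 0 (image column axis).
#' @param apex_values optional values for segment 17.
#' @return numeric vector of length 17 (segment means, NA if empty) with
#'   attribute `slice_class`.
#' @export
aha17_bullseye <- function(strain_slices, myo_slices, centers,
                           rv_masks = NULL, apex_values = NULL) {
  S <- length(strain_slices)
  stopifnot(S >= 3, length(myo_slices) == S, length(centers) == S)
  third <- ceiling(seq_len(S) / (S / 3))
  cls <- c("basal", "mid", "apical")[pmin(third, 3)]
  seg_means <- rep(NA_real_, 17)
  seg_counts <- integer(17)
  seg_sums <- numeric(17)
  for (s in seq_len(S)) {
    myo <- myo_slices[[s]]
    if (!any(myo)) next
    ctr <- centers[[s]]
    ref_angle <- 0
    if (!is.null(rv_masks) && any(rv_masks[[s]])) {
      rv_pts <- which(rv_masks[[s]], arr.ind = TRUE)
      # anterior insertion: RV pixel of smallest row (most anterior)
      ins <- rv_pts[which.min(rv_pts[, 1]), ]
      ref_angle <- atan2(ins[1] - ctr[1], ins[2] - ctr[2])
    }
    pts <- which(myo, arr.ind = TRUE)
    ang <- (atan2(pts[, 1] - ctr[1], pts[, 2] - ctr[2]) - ref_angle) %% (2 * pi)
    vals <- strain_slices[[s]][myo]
    if (cls[s] %in% c("basal", "mid")) {
      sector <- pmin(floor(ang / (pi / 3)) + 1L, 6L)
      base_id <- if (cls[s] == "basal") 0L else 6L
    } else {
      sector <- pmin(floor(ang / (pi / 2)) + 1L, 4L)
      base_id <- 12L
    }
    for (k in unique(sector)) {
      id <- base_id + k
      seg_sums[id] <- seg_sums[id] + sum(vals[sector == k])
      seg_counts[id] <- seg_counts[id] + sum(sector == k)
    }
  }
  filled <- seg_counts > 0
  seg_means[filled] <- seg_sums[filled] / seg_counts[filled]
  if (!is.null(apex_values)) seg_means[17] <- mean(apex_values)
  structure(seg_means, slice_class = cls)
}

#' Render a 17-segment bull's-eye plot
#'
#' Standard polar layout: basal ring outermost, apex at the centre.
#'
#' @param segments numeric vector of length 17 (NA allowed).
#' @param file optional PNG path.
#' @param main plot title.
#' @param palette colour ramp function.
#' @export
plot_bullseye <- function(segments, file = NULL, main = "",
                          palette = grDevices::colorRampPalette(
                            c("#2166AC", "#F7F7F7", "#B2182B"))) {
  if (!is.null(file)) grDevices::png(file, width = 480, height = 480)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  rng <- range(segments, na.rm = TRUE)
  if (!is.finite(rng[1])) rng <- c(0, 1)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  cols <- palette(64)
  col_of <- function(v) if (is.na(v)) "grey85"
    else cols[pmax(1, pmin(64, ceiling(64 * (v - rng[1]) / diff(rng))))]
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  ring <- function(ids, r_in, r_out, n_seg) {
    for (k in seq_len(n_seg)) {
      a <- seq((k - 1) * 2 * pi / n_seg, k * 2 * pi / n_seg, length.out = 30)
      xs <- c(r_out * cos(a), rev(r_in * cos(a)))
      ys <- c(r_out * sin(a), rev(r_in * sin(a)))
      graphics::polygon(xs, ys, col = col_of(segments[ids[k]]), border = "white")
    }
  }
  ring(1:6, 0.75, 1, 6)
  ring(7:12, 0.5, 0.75, 6)
  ring(13:16, 0.25, 0.5, 4)
  a <- seq(0, 2 * pi, length.out = 60)
  graphics::polygon(0.25 * cos(a), 0.25 * sin(a),
                    col = col_of(segments[17]), border = "white")
  invisible(segments)
}

#' Strain map overlaid on an image frame
#'
#' Renders the per-pixel strain over the myocardium on top of the
#' greyscale frame with a diverging colour ramp; optionally writes a PNG.
#'
#' @param image (H, W) intensity matrix (typically the end-systolic frame).
#' @param field (H, W) strain field (Err or Ecc).
#' @param myo_mask logical myocardium mask selecting the shown pixels.
#' @param file optional PNG path.
#' @param palette diverging colour ramp.
#' @export
plot_strain_overlay <- function(image, field, myo_mask, file = NULL,
                                palette = grDevices::colorRampPalette(
                                  c("#2166AC", "#F7F7F7", "#B2182B"))) {
  if (!is.null(file)) grDevices::png(file, width = 480, height = 480)
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  H <- nrow(image); W <- ncol(image)
  rng <- range(image)
  img01 <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  graphics::plot(NA, xlim = c(0.5, W + 0.5), ylim = c(H + 0.5, 0.5),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(img01, 0.5, H + 0.5, W + 0.5, 0.5)
  vals <- field[myo_mask]
  if (length(vals) > 0) {
    lim <- max(abs(vals))
    cols <- palette(64)
    idx <- pmax(1, pmin(64, ceiling(32 + 32 * field[myo_mask] / max(lim, 1e-9))))
    pts <- which(myo_mask, arr.ind = TRUE)
    graphics::points(pts[, 2], pts[, 1], col = cols[idx], pch = 15, cex = 0.5)
  }
  invisible(NULL)
}

#' End-to-end functional assessment
#'
#' Computes volume curves, ejection fractions, end-systolic
#' radial/circumferential strain from the end-diastolic displacement
#' field, and (with 3 or more slices) the AHA-17 segment table.
#'
#' @param masks label array (H, W, T) or (H, W, T, S).
#' @param flow_table a `flow_table` whose reference is end-diastole.
#' @param spacing,slice_thickness geometry in mm.
#' @param es_frame optional end-systolic frame override (defaults to the
#'   LV volume minimum).
#' @return a `function_report` list: `volumes`, `lvef`, `rvef`, `strain`
#'   (fields + mGRS/mGCS), optionally `bullseye_err`/`bullseye_ecc`.
#' @export
analyze_function <- function(masks, flow_table, spacing, slice_thickness,
                             es_frame = NULL) {
  vc <- ventricular_volumes(masks, spacing, slice_thickness)
  lvef <- ejection_fraction(vc$lv$edv, vc$lv$esv)
  rvef <- if (!is.null(vc$rv)) ejection_fraction(vc$rv$edv, vc$rv$esv) else NA_real_
  es <- es_frame %||% vc$lv$es_frame
  d <- dim(masks)
  masks4 <- if (length(d) == 3) array(masks, c(d, 1)) else masks
  S <- dim(masks4)[4]
  mid <- (S + 1) %/% 2
  ed <- vc$lv$ed_frame
  u <- flow_table$from_reference[[es]]
  E <- green_lagrange(u)
  coords <- local_coordinates(masks4[, , ed, mid])
  strain <- project_strain(E, coords)
  out <- list(volumes = vc, lvef = lvef, rvef = rvef, strain = strain,
              es_frame = es, ed_frame = ed)
  if (S >= 3) {
    sl_strain_rr <- sl_strain_cc <- sl_myo <- sl_ctr <- sl_rv <- vector("list", S)
    for (s in seq_len(S)) {
      cs <- local_coordinates(masks4[, , ed, s])
      ps <- project_strain(E, cs)
      sl_strain_rr[[s]] <- ps$Err; sl_strain_cc[[s]] <- ps$Ecc
      sl_myo[[s]] <- cs$myo_mask; sl_ctr[[s]] <- cs$center
      sl_rv[[s]] <- masks4[, , ed, s] == 3L
    }
    out$bullseye_err <- aha17_bullseye(sl_strain_rr, sl_myo, sl_ctr, sl_rv)
    out$bullseye_ecc <- aha17_bullseye(sl_strain_cc, sl_myo, sl_ctr, sl_rv)
  }
  class(out) <- "function_report"
  out
}
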