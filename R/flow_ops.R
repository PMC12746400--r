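# Dense displacement-field utilities shared by registration, reconstruction,
# pseudo-labelling and strain analysis.
#
# Convention (important): a flow field `u` is an (H, W, 2) array in pixel
# units with component 1 = row offset and component 2 = column offset, and
# warping is *backward*: warped(p) = source(p + u(p)). Out-of-domain sample
# coordinates are edge-clamped (replicated border), which keeps the static
# background of cine frames free of spurious photometric error.

grid_coords <- function(H, W) {
  list(
    r = matrix(rep(seq_len(H), times = W), H, W),
    c = matrix(rep(seq_len(W), each = H), H, W)
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a 2D field at fractional coordinates
#'
#' Bilinear (or nearest-neighbour) interpolation with edge-clamped
#' coordinates. Workhorse behind [warp_image()] and flow composition.
#'
#' @param source numeric matrix (H, W).
#' @param rs,cs numeric arrays of row/column sample coordinates (1-based).
#' @param mode `"linear"` or `"nearest"`.
#' @return array shaped like `rs` with interpolated values.
#' @keywords internal
sample_bilinear <- function(source, rs, cs, mode = "linear") {
  H <- nrow(source); W <- ncol(source)
  rs <- clamp(rs, 1, H); cs <- clamp(cs, 1, W)
  if (mode == "nearest") {
    idx <- round(rs) + (round(cs) - 1) * H
    out <- source[idx]
  } else {
    r0 <- clamp(floor(rs), 1, H); c0 <- clamp(floor(cs), 1, W)
    r1 <- clamp(r0 + 1, 1, H);    c1 <- clamp(c0 + 1, 1, W)
    wr <- rs - r0; wc <- cs - c0
    i00 <- r0 + (c0 - 1) * H; i10 <- r1 + (c0 - 1) * H
    i01 <- r0 + (c1 - 1) * H; i11 <- r1 + (c1 - 1) * H
    out <- (1 - wr) * (1 - wc) * source[i00] + wr * (1 - wc) * source[i10] +
      (1 - wr) * wc * source[i01] + wr * wc * source[i11]
  }
  dim(out) <- dim(rs)
  out
}

#' Warp an image or label map by a dense displacement field
#'
#' Backward warping through a spatial transformer: the output at pixel `p`
#' samples `source` at `p + u(p)`. Linear interpolation is used for
#' intensity images, nearest-neighbour for label maps (so the label value
#' set is preserved). Sample positions outside the image are edge-clamped.
#'
#' @param source numeric matrix (H, W); complex matrices are warped by
#'   warping real and imaginary parts.
#' @param flow (H, W, 2) displacement array, pixel units, (row, col) order.
#' @param mode `"linear"` (default) or `"nearest"`.
#' @return warped matrix (H, W).
#' @examples
#' img <- matrix(rnorm(64), 8, 8)
#' u0 <- array(0, c(8, 8, 2))
#' stopifnot(identical(warp_image(img, u0), img))
#' @export
warp_image <- function(source, flow, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(flow)) == 3, dim(flow)[3] == 2)
  if (any(!is.finite(flow))) stop("flow field contains non-finite values")
  H <- nrow(source); W <- ncol(source)
  stopifnot(dim(flow)[1] == H, dim(flow)[2] == W)
  g <- grid_coords(H, W)
  rs <- g$r + flow[, , 1]; cs <- g$c + flow[, , 2]
  if (is.complex(source)) {
    out <- sample_bilinear(Re(source), rs, cs, mode) +
      1i * sample_bilinear(Im(source), rs, cs, mode)
  } else {
    out <- sample_bilinear(source, rs, cs, mode)
  }
  out
}

#' Compose two displacement fields
#'
#' Returns the field of the composite backward warp: warping by the result
#' equals warping by `u_bc` first and then by `u_ab`,
#' `(u_ab o u_bc)(p) = u_bc(p) + u_ab(p + u_bc(p))`,
#' with linear interpolation of `u_ab` at the displaced positions. Used to
#' chain frame-to-frame flows into frame-to-reference flows.
#'
#' @param u_ab,u_bc (H, W, 2) displacement arrays.
#' @return (H, W, 2) composed displacement array.
#' @export
compose_flows <- function(u_ab, u_bc) {
  stopifnot(all(dim(u_ab) == dim(u_bc)))
  H <- dim(u_ab)[1]; W <- dim(u_ab)[2]
  g <- grid_coords(H, W)
  rs <- g$r + u_bc[, , 1]; cs <- g$c + u_bc[, , 2]
  out <- array(0, dim(u_ab))
  out[, , 1] <- u_bc[, , 1] + sample_bilinear(u_ab[, , 1], rs, cs)
  out[, , 2] <- u_bc[, , 2] + sample_bilinear(u_ab[, , 2], rs, cs)
  out
}

#' Jacobian determinant of a deformation
#'
#' Per-pixel determinant of `I + grad(u)` using central differences in the
#' interior and one-sided differences at the borders. Values <= 0 indicate
#' folding of the deformation `p -> p + u(p)`.
#'
#' @param flow (H, W, 2) displacement array.
#' @return (H, W) matrix of determinants.
#' @export
jacobian_determinant <- function(flow) {
  stopifnot(all(is.finite(flow)))
  d1r <- fd_gradient(flow[, , 1], 1); d1c <- fd_gradient(flow[, , 1], 2)
  d2r <- fd_gradient(flow[, , 2], 1); d2c <- fd_gradient(flow[, , 2], 2)
  (1 + d1r) * (1 + d2c) - d1c * d2r
}

# finite-difference gradient along rows (axis 1) or columns (axis 2):
# central in the interior, one-sided at the first/last line
fd_gradient <- function(m, axis) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  if (axis == 1) {
    if (H >= 3) out[2:(H - 1), ] <- (m[3:H, ] - m[1:(H - 2), ]) / 2
    out[1, ] <- m[2, ] - m[1, ]
    out[H, ] <- m[H, ] - m[H - 1, ]
  } else {
    if (W >= 3) out[, 2:(W - 1)] <- (m[, 3:W] - m[, 1:(W - 2)]) / 2
    out[, 1] <- m[, 2] - m[, 1]
    out[, W] <- m[, W] - m[, W - 1]
  }
  out
}

#' Percentage of nonpositive Jacobian determinants
#'
#' The share of pixels at which `det(I + grad(u)) <= 0`, in percent. A 0%
#' rate indicates a topology-preserving (diffeomorphic-like) deformation;
#' positive values flag folding.
#'
#' @param flow (H, W, 2) displacement array.
#' @return scalar percentage in \[0, 100\].
#' @export
nonpositive_jacobian_fraction <- function(flow) {
  detj <- jacobian_determinant(flow)
  100 * sum(detj <= 0) / length(detj)
}

#' Render a flow field with the optical-flow colour wheel
#'
#' Hue encodes direction, saturation encodes magnitude (normalised by the
#' field's maximum unless `max_norm` is given). Returns an (H, W, 3) RGB
#' array in \[0, 1\] and optionally writes a PNG.
#'
#' @param flow (H, W, 2) displacement array.
#' @param file optional PNG path.
#' @param max_norm optional normalisation magnitude (pixels).
#' @return invisibly, the RGB array.
#' @export
flow_to_color <- function(flow, file = NULL, max_norm = NULL) {
  mag <- sqrt(flow[, , 1]^2 + flow[, , 2]^2)
  if (is.null(max_norm)) max_norm <- max(mag, 1e-9)
  ang <- atan2(flow[, , 1], flow[, , 2])        # [-pi, pi]
  hue <- (ang + pi) / (2 * pi)
  sat <- clamp(mag / max_norm, 0, 1)
  hsv_col <- grDevices::hsv(h = as.vector(hue), s = as.vector(sat), v = 1)
  rgb <- grDevices::col2rgb(hsv_col) / 255
  out <- array(0, c(nrow(mag), ncol(mag), 3))
  out[, , 1] <- rgb[1, ]; out[, , 2] <- rgb[2, ]; out[, , 3] <- rgb[3, ]
  if (!is.null(file)) {
    grDevices::png(file, width = ncol(mag), height = nrow(mag))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new(); graphics::rasterImage(out, 0, 0, 1, 1)
    graphics::par(op); grDevices::dev.off()
  }
  invisible(out)
}
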