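# The Cartesian MR forward operation A = phi F C, its adjoint, coil
# combination and zero-filled reconstruction.
#
# FFT convention: centred (fftshifted) orthonormal transform, so that the
# operator norm of F is exactly 1 and solver step sizes are simple.

fftshift2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c((floor(H / 2) + 1):H, 1:floor(H / 2)),
    c((floor(W / 2) + 1):W, 1:floor(W / 2))]
}

ifftshift2 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c((H - floor(H / 2) + 1):H, 1:(H - floor(H / 2))),
    c((W - floor(W / 2) + 1):W, 1:(W - floor(W / 2)))]
}

#' Centred orthonormal 2D Fourier transform and inverse
#'
#' `ifft2c(fft2c(x))` recovers `x` to floating-point accuracy and both
#' transforms preserve the l2 norm (Parseval).
#'
#' @param x complex (or real) matrix.
#' @return complex matrix of the same shape.
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(as.matrix(x)))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(as.matrix(x)), inverse = TRUE)) / sqrt(length(x))
}

expand_mask <- function(phi, H, W) {
  # per-frame ky-line mask broadcast along kx; accept full (H, W) masks too
  if (is.null(dim(phi)) && length(phi) == H) {
    matrix(rep(phi, W), H, W)
  } else if (all(dim(phi) == c(H, W))) {
    phi
  } else stop("mask shape mismatch")
}

#' Forward MR operation A x = phi F (C x)
#'
#' Applies coil sensitivities, the centred orthonormal Fourier transform
#' and the sampling mask to a single image frame. Linear in `x`.
#'
#' @param x complex or real (H, W) image.
#' @param coils complex (H, W, n_coils) sensitivity maps.
#' @param phi binary ky-line vector (length H) or full (H, W) mask.
#' @return complex (H, W, n_coils) masked k-space.
#' @export
apply_forward <- function(x, coils, phi) {
  H <- nrow(x); W <- ncol(x)
  if (!all(dim(coils)[1:2] == c(H, W))) stop("coil map shape mismatch")
  m <- expand_mask(phi, H, W)
  nc <- dim(coils)[3]
  out <- array(0i, c(H, W, nc))
  for (k in seq_len(nc)) out[, , k] <- m * fft2c(coils[, , k] * x)
  out
}

#' Adjoint MR operation A^H y = C^H F^-1 (phi y)
#'
#' Exact adjoint of [apply_forward()] under the standard complex inner
#' product; passes the dot-product test to 1e-6 relative.
#'
#' @param y complex (H, W, n_coils) k-space.
#' @param coils complex (H, W, n_coils) sensitivity maps.
#' @param phi binary ky-line vector or full (H, W) mask.
#' @return complex (H, W) image.
#' @export
apply_adjoint <- function(y, coils, phi) {
  H <- dim(y)[1]; W <- dim(y)[2]; nc <- dim(y)[3]
  if (!all(dim(coils) == c(H, W, nc))) stop("coil map shape mismatch")
  m <- expand_mask(phi, H, W)
  out <- matrix(0i, H, W)
  for (k in seq_len(nc)) out <- out + Conj(coils[, , k]) * ifft2c(m * y[, , k])
  out
}

#' Coil-combined image from per-coil images
#'
#' Conjugate-coil-map combination `sum(Conj(C_c) x_c) / sum(|C_c|^2)` when
#' maps are supplied (they are exact in the phantom), root-sum-of-squares
#' otherwise.
#'
#' @param x_coils complex (H, W, n_coils) per-coil images.
#' @param coils optional complex (H, W, n_coils) sensitivity maps.
#' @return (H, W) combined image (complex for map-combine, real for RSS).
#' @export
coil_combine <- function(x_coils, coils = NULL) {
  nc <- dim(x_coils)[3]
  if (is.null(coils)) {
    return(sqrt(apply(abs(x_coils)^2, c(1, 2), sum)))
  }
  num <- matrix(0i, dim(x_coils)[1], dim(x_coils)[2])
  den <- matrix(0, dim(x_coils)[1], dim(x_coils)[2])
  for (k in seq_len(nc)) {
    num <- num + Conj(coils[, , k]) * x_coils[, , k]
    den <- den + abs(coils[, , k])^2
  }
  num / pmax(den, 1e-12)
}

#' Zero-filled reconstruction of a k-space bundle
#'
#' Inverse Fourier transform of the masked k-space with missing samples
#' left at zero, coil-combined per frame. The aliased baseline every
#' accelerated method is compared against.
#'
#' @param bundle a `kspace_bundle` from [simulate_kspace()].
#' @param use_full reconstruct from the fully sampled k-space instead.
#' @return real array (H, W, T) of magnitude images.
#' @export
zero_filled_recon <- function(bundle, use_full = FALSE) {
  y <- if (use_full) bundle$y_full else bundle$y
  d <- dim(y); H <- d[1]; W <- d[2]; nc <- d[3]; T <- d[4]
  out <- array(0, c(H, W, T))
  for (t in seq_len(T)) {
    xc <- array(0i, c(H, W, nc))
    for (k in seq_len(nc)) xc[, , k] <- ifft2c(y[, , k, t])
    out[, , t] <- abs(coil_combine(xc, bundle$coils))
  }
  out
}
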