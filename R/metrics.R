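# Evaluation metrics for segmentation (DSC, Hausdorff, mean contour
# distance), registration (overlap score, nonpositive-Jacobian fraction)
# and reconstruction (NRMSE, SSIM).

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` for one class of two label maps. Two empty
#' masks count as perfect agreement (DSC 1).
#'
#' @param pred,ref label matrices (or logical masks).
#' @param class label value to score; ignored when inputs are logical.
#' @return DSC in \[0, 1\].
#' @export
dice <- function(pred, ref, class = 1L) {
  stopifnot(all(dim(pred) == dim(ref)))
  a <- if (is.logical(pred)) pred else pred == class
  b <- if (is.logical(ref)) ref else ref == class
  if (!any(a) && !any(b)) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# boundary of a binary mask: pixels of the mask with a 4-neighbour outside
mask_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 2:(W + 1)] & pad[1:H, 2:(W + 1)] &
    pad[3:(H + 2), 2:(W + 1)] & pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  m & !inner
}

boundary_points <- function(m) {
  b <- which(mask_boundary(m), arr.ind = TRUE)
  if (nrow(b) == 0) NULL else b
}

directed_nn_dist <- function(from, to) {
  # nearest-neighbour distance from each row of `from` to the set `to`
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric worst-case boundary distance in millimetres (`spacing` scales
#' pixel distances). `NA` if either mask is empty.
#'
#' @param pred,ref logical masks or label matrices scored at `class`.
#' @param spacing pixel size in mm.
#' @param class label value when inputs are label maps.
#' @return distance in mm, or `NA_real_`.
#' @export
hausdorff <- function(pred, ref, spacing = 1, class = 1L) {
  a <- boundary_points(if (is.logical(pred)) pred else pred == class)
  b <- boundary_points(if (is.logical(ref)) ref else ref == class)
  if (is.null(a) || is.null(b)) return(NA_real_)
  spacing * max(max(directed_nn_dist(a, b)), max(directed_nn_dist(b, a)))
}

#' Mean contour distance between mask boundaries
#'
#' Symmetric mean of nearest-neighbour distances between the two boundary
#' point sets, in millimetres. Always `<=` the Hausdorff distance.
#'
#' @inheritParams hausdorff
#' @return distance in mm, or `NA_real_`.
#' @export
mean_contour_distance <- function(pred, ref, spacing = 1, class = 1L) {
  a <- boundary_points(if (is.logical(pred)) pred else pred == class)
  b <- boundary_points(if (is.logical(ref)) ref else ref == class)
  if (is.null(a) || is.null(b)) return(NA_real_)
  spacing * (mean(directed_nn_dist(a, b)) + mean(directed_nn_dist(b, a))) / 2
}

#' Overlap score of a motion estimate
#'
#' DSC between a manual mask and its motion-propagated counterpart,
#' evaluated in both directions (ED mask warped to ES compared against the
#' ES mask, and vice versa) and averaged. The registration-quality proxy
#' used alongside image-based errors.
#'
#' @param mask_ed,mask_es label matrices at end-diastole / end-systole.
#' @param flow_ed_to_es flow on the ED grid pointing into the ES frame
#'   (warping the ES mask with it propagates it to ED geometry).
#' @param flow_es_to_ed flow on the ES grid pointing into the ED frame.
#' @param class label value to score.
#' @return averaged DSC in \[0, 1\].
#' @export
overlap_score <- function(mask_ed, mask_es, flow_ed_to_es, flow_es_to_ed,
                          class = 1L) {
  es_on_ed <- warp_image(mask_es, flow_ed_to_es, mode = "nearest")
  ed_on_es <- warp_image(mask_ed, flow_es_to_ed, mode = "nearest")
  (dice(es_on_ed, mask_ed, class) + dice(ed_on_es, mask_es, class)) / 2
}

#' Normalised root-mean-square error
#'
#' RMSE divided by the intensity range of the reference.
#'
#' @param test,ref numeric arrays of identical shape.
#' @return NRMSE (>= 0); error if the reference is constant.
#' @export
nrmse <- function(test, ref) {
  stopifnot(all(dim(test) == dim(ref)))
  rng <- max(ref) - min(ref)
  if (rng == 0) stop("NRMSE undefined for a constant reference image")
  sqrt(mean((test - ref)^2)) / rng
}

# uniform box filter via padded cumulative sums (reflective padding)
box_filter <- function(m, w) {
  H <- nrow(m); W <- ncol(m); r <- (w - 1) %/% 2
  idx_r <- clamp(seq_len(H + 2 * r) - r, 1, H)
  idx_c <- clamp(seq_len(W + 2 * r) - r, 1, W)
  p <- m[idx_r, idx_c]
  cs <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  csp <- matrix(0, nrow(cs) + 1, ncol(cs) + 1)
  csp[-1, -1] <- cs
  i1 <- seq_len(H); i2 <- i1 + w - 1
  j1 <- seq_len(W); j2 <- j1 + w - 1
  (csp[i2 + 1, j2 + 1] - csp[i1, j2 + 1] - csp[i2 + 1, j1] + csp[i1, j1]) / w^2
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with a uniform 7x7 window, k1 = 0.01, k2 = 0.03 and the
#' dynamic range of the reference.
#'
#' @param test,ref numeric matrices of identical shape.
#' @param window odd window width.
#' @param k1,k2 stabilisation constants.
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(test, ref, window = 7, k1 = 0.01, k2 = 0.03) {
  stopifnot(all(dim(test) == dim(ref)))
  L <- max(ref) - min(ref); if (L == 0) L <- 1
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mu_x <- box_filter(test, window); mu_y <- box_filter(ref, window)
  sxx <- box_filter(test^2, window) - mu_x^2
  syy <- box_filter(ref^2, window) - mu_y^2
  sxy <- box_filter(test * ref, window) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}

#' Boxplot export of grouped metric values
#'
#' Simple boxplot of a metric column split by a grouping column
#' (structure, acceleration, method ...); optionally writes a PNG.
#'
#' @param df data.frame of metric values.
#' @param value name of the numeric column.
#' @param group name of the grouping column.
#' @param file optional PNG path.
#' @param main plot title.
#' @export
plot_metric_box <- function(df, value, group, file = NULL, main = value) {
  if (!is.null(file)) grDevices::png(file, width = 480, height = 400)
  op <- graphics::par(mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); if (!is.null(file)) grDevices::dev.off() })
  graphics::boxplot(df[[value]] ~ df[[group]], xlab = group, ylab = value,
                    main = main, col = "grey90")
  invisible(NULL)
}

#' Full metric report for one frame pair
#'
#' Convenience wrapper collecting the segmentation, registration and
#' reconstruction metrics into one list, for report tables.
#'
#' @param pred,ref label matrices; `classes` named vector of label values.
#' @param spacing pixel size in mm.
#' @param classes label values to score (default LV pool, myocardium, RV pool).
#' @return data.frame with one row per structure.
#' @export
metric_report <- function(pred, ref, spacing = 1,
                          classes = c(lv = 1L, myo = 2L, rv = 3L)) {
  rows <- lapply(names(classes), function(nm) {
    cl <- classes[[nm]]
    data.frame(structure = nm,
               dsc = dice(pred, ref, cl),
               hdd_mm = hausdorff(pred, ref, spacing, cl),
               mcd_mm = mean_contour_distance(pred, ref, spacing, cl))
  })
  do.call(rbind, rows)
}
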