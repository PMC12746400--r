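# Gradient checks of the autodiff engine against central differences.

num_grad <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

expect_grad <- function(fn_node, x, tol = 1e-4) {
  p <- cinemop:::ad_param(x)
  loss <- fn_node(p)
  cinemop:::ad_backward(loss)
  ng <- num_grad(function(xx) cinemop:::ad_value(fn_node(cinemop:::ad_param(xx))), x)
  expect_lt(max(abs(p$grad - ng)) / max(abs(ng), 1e-8), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution family matches numerical gradients", {
  ad <- asNamespace("cinemop")
  set.seed(1)
  x <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  wc <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4)); b <- rnorm(4) * 0.1
  w1 <- array(rnorm(1 * 1 * 3 * 4) * 0.3, c(1, 1, 3, 4))
  wdw <- array(rnorm(5 * 5 * 3) * 0.2, c(5, 5, 3))
  wt <- array(rnorm(2 * 2 * 3 * 2) * 0.3, c(2, 2, 3, 2))
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_conv2d(p, ad$ad_const(wc), ad$ad_const(b)))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_conv2d(ad$ad_const(x), p, ad$ad_const(b)))), wc)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_conv2d(p, ad$ad_const(w1)))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_conv2d_depthwise(p, ad$ad_const(wdw)))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_conv2d_depthwise(ad$ad_const(x), p))), wdw)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_convtranspose2(p, ad$ad_const(wt)))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_convtranspose2(ad$ad_const(x), p))), wt)
})

test_that("warping, correlation and lookup nodes match numerical gradients", {
  ad <- asNamespace("cinemop")
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  fl <- array(rnorm(6 * 6 * 2) * 0.7, c(6, 6, 2))
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_warp(p, ad$ad_const(fl)))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_warp(ad$ad_const(x), p))), fl)
  f1 <- matrix(rnorm(16 * 3), 16, 3); f2 <- matrix(rnorm(16 * 3), 16, 3)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_correlation(p, ad$ad_const(f2)))), f1)
  corr <- matrix(rnorm(16 * 16), 16, 16)
  rc <- cbind(runif(16, 1.2, 3.8), runif(16, 1.2, 3.8))
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_corr_lookup(p, 4, 4, ad$ad_const(rc), 1))), corr)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_corr_lookup(ad$ad_const(corr), 4, 4, p, 1))), rc)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_pool_corr(p, 4, 4))), corr)
})

test_that("normalisation, pooling and softmax nodes match numerical gradients", {
  ad <- asNamespace("cinemop")
  set.seed(3)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  gam <- rnorm(3); bet <- rnorm(3)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_channel_norm(p, ad$ad_const(gam), ad$ad_const(bet)))), x, tol = 5e-4)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_maxpool2(p))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_avgpool2(p))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_upsample_bilinear(p, 2))), x)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_softmax_c(p))), x)
  m <- matrix(rnorm(25), 5, 5)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_softmax_rows(p))), m)
  expect_grad(function(p) ad$ad_mean(ad$ad_square(ad$ad_slice_c(ad$ad_concat_c(p, ad$ad_const(x)), c(2, 4)))), x)
})

test_that("AdamW minimises a quadratic and the cosine schedule anneals", {
  ad <- asNamespace("cinemop")
  set.seed(4)
  target <- rnorm(5)
  p <- ad$ad_param(rep(0, 5))
  opt <- adamw(list(p), lr = 0.1, weight_decay = 0)
  for (i in 1:200) {
    loss <- ad$ad_mean(ad$ad_square(ad$ad_sub(p, ad$ad_const(target))))
    opt$zero_grad(); ad$ad_backward(loss); opt$step()
  }
  expect_lt(max(abs(p$value - target)), 1e-2)
  expect_equal(cosine_lr(1, 100, 1e-3), 1e-3)
  expect_lt(cosine_lr(100, 100, 1e-3), 2e-5)
  expect_true(all(diff(vapply(1:100, cosine_lr, numeric(1),
                              total = 100, lr_max = 1e-3)) <= 0))
})
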