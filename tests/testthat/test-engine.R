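# The convolution kernels and layer gradients are the numerical core of
# both networks; check them against a slow reference implementation and
# finite differences.

test_that("C++ convolution matches the reference implementation", {
  set.seed(1)
  for (k in c(3, 5)) {
    x <- array(rnorm(10 * 12 * 2), c(10, 12, 2))
    w <- matrix(rnorm(k * k * 2 * 3), k * k * 2, 3)
    b <- rnorm(3)
    fast <- lesionforge:::lf_conv_fwd(x, w, b, k)
    slow <- reference_conv(x, w, b, k)
    expect_equal(fast, slow, tolerance = 1e-5)  # single-precision gemm
  }
})

test_that("conv backward agrees with finite differences", {
  set.seed(2)
  k <- 3
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- matrix(rnorm(k * k * 2 * 2, sd = 0.5), k * k * 2, 2)
  b <- rnorm(2)
  dout <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  bw <- lesionforge:::lf_conv_bwd(x, w, dout, k)
  loss <- function(xx, ww, bb) {
    sum(lesionforge:::lf_conv_fwd(xx, ww, bb, k) * dout)
  }
  h <- 1e-3
  for (probe in list(c(1, 1), c(9, 2), c(14, 1))) {
    wp <- w; wp[probe[1], probe[2]] <- wp[probe[1], probe[2]] + h
    wm <- w; wm[probe[1], probe[2]] <- wm[probe[1], probe[2]] - h
    num <- (loss(x, wp, b) - loss(x, wm, b)) / (2 * h)
    expect_equal(bw$dW[probe[1], probe[2]], num, tolerance = 1e-2)
  }
  xp <- x; xp[3, 3, 1] <- xp[3, 3, 1] + h
  xm <- x; xm[3, 3, 1] <- xm[3, 3, 1] - h
  expect_equal(bw$dx[3, 3, 1], (loss(xp, w, b) - loss(xm, w, b)) / (2 * h),
               tolerance = 1e-2)
  expect_equal(as.vector(bw$db), apply(dout, 3, sum), tolerance = 1e-4)
})

test_that("max pooling forward/backward route values and gradients correctly", {
  x <- array(0, c(4, 4, 1))
  x[, , 1] <- matrix(1:16, 4, 4)
  mp <- lesionforge:::lf_maxpool_fwd(x, 2L)
  expect_equal(mp$out[, , 1], matrix(c(6, 8, 14, 16), 2, 2))
  dout <- array(1, c(2, 2, 1))
  dx <- lesionforge:::lf_maxpool_bwd(dout, mp$idx, 4L, 4L, 2L)
  expect_equal(sum(dx), 4)
  expect_equal(dx[2, 2, 1], 1)   # position of value 6
  expect_equal(dx[1, 1, 1], 0)
})

test_that("nearest-neighbour upsampling and its adjoint block-sum", {
  x <- array(1:4, c(2, 2, 1)) * 1.0
  up <- lesionforge:::lf_upsample_fwd(x, 2L)
  expect_equal(dim(up), c(4, 4, 1))
  expect_equal(up[1:2, 1:2, 1], matrix(1, 2, 2))
  dout <- array(1, c(4, 4, 1))
  expect_equal(lesionforge:::lf_upsample_bwd(dout, 2L)[, , 1],
               matrix(4, 2, 2))
})

test_that("softmax cross-entropy loss and gradient are consistent", {
  z <- c(2, -1, 0.5)
  lo <- lesionforge:::loss_cross_entropy(z, 2L)
  p <- exp(z - max(z)) / sum(exp(z - max(z)))
  expect_equal(lo$loss, -log(p[2]))
  expect_equal(sum(lo$dlogits), 0, tolerance = 1e-12)
  h <- 1e-5
  for (j in 1:3) {
    zp <- z; zp[j] <- zp[j] + h
    zm <- z; zm[j] <- zm[j] - h
    num <- (lesionforge:::loss_cross_entropy(zp, 2L)$loss -
              lesionforge:::loss_cross_entropy(zm, 2L)$loss) / (2 * h)
    expect_equal(lo$dlogits[j], num, tolerance = 1e-6)
  }
})

test_that("soft-Jaccard loss: perfect and empty predictions, gradient sign", {
  mask <- exact_mask(16, 4, 4)
  perfect <- lesionforge:::loss_soft_jaccard(mask * 1.0, mask, eps = 1)
  expect_equal(perfect$loss, 0)
  empty <- lesionforge:::loss_soft_jaccard(mask * 0.0, mask, eps = 1e-9)
  expect_equal(empty$loss, 1, tolerance = 1e-6)
  # raising probability on a true-foreground pixel lowers the loss
  p <- matrix(0.5, 4, 4)
  g <- lesionforge:::loss_soft_jaccard(p, mask, eps = 1)$dprobs
  expect_true(all(g[mask == 1] < 0))
  expect_true(all(g[mask == 0] > 0))
})

test_that("batchnorm normalises activations and passes its gradient check", {
  set.seed(3)
  ly <- list(gamma = c(1.5, 0.7), beta = c(0.2, -0.1),
             run_mean = c(0, 0), run_var = c(1, 1))
  pre <- array(rnorm(8 * 8 * 2, mean = 3, sd = 2), c(8, 8, 2))
  fw <- lesionforge:::bn_forward(pre, ly, train = TRUE)
  flat <- matrix(fw$out, 64, 2)
  expect_equal(colMeans(flat), ly$beta, tolerance = 1e-8)
  expect_equal(apply(flat, 2, sd) * sqrt(63 / 64), ly$gamma, tolerance = 1e-3)
  dout <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  bb <- lesionforge:::bn_backward(dout, fw, ly)
  h <- 1e-4
  prep <- pre; prep[2, 2, 1] <- prep[2, 2, 1] + h
  prem <- pre; prem[2, 2, 1] <- prem[2, 2, 1] - h
  num <- (sum(lesionforge:::bn_forward(prep, ly, TRUE)$out * dout) -
            sum(lesionforge:::bn_forward(prem, ly, TRUE)$out * dout)) / (2 * h)
  expect_equal(bb$dx[2, 2, 1], num, tolerance = 1e-3)
})
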