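test_that("depthwise-then-pointwise factorization equals the dense convolution oracle", {
  set.seed(11)
  x <- rand_arr(5, 5, 3, 1)
  dw <- dwconv2d(3, kernel = 3, dilation = 2)
  pw <- conv2d(3, 4, kernel = 1)
  y <- nn_forward(pw, nn_forward(dw, x))
  # equivalent dense kernel: block-diagonal depthwise followed by channel mixing
  Wd <- array(0, c(3, 3, 3, 4))
  for (o in 1:4) for (cc in 1:3)
    Wd[, , cc, o] <- dw$params$W[, , cc] * pw$params$W[1, 1, cc, o]
  expect_lt(max(abs(y - brute_conv(x, Wd, pad = c(2, 2), dil = c(2, 2)))), 1e-6)
})

test_that("DSDConv block: zero input maps to zero, parameter arithmetic beats dense", {
  set.seed(12)
  b <- dsd_conv_block(64, 64, kernel = 3)
  bn_identity(b)
  y <- nn_forward(b, array(0, c(4, 4, 64, 1)))
  expect_true(all(y == 0))
  # conv weights only: 64 kernels of 9 + 64x64 pointwise vs dense 3x3
  convs <- Filter(function(m) inherits(m, c("conv2d", "dwconv2d")), nn_modules(b))
  n_w <- sum(vapply(convs, function(m) length(m$params$W), numeric(1)))
  expect_identical(n_w, 64 * 9 + 64 * 64)
  expect_identical(n_w, 4672)
  expect_lt(n_w, 36864)
  expect_error(dsd_conv_block(8, 8, kernel = 4), "odd")
})

test_that("inverted residual: identity under zeroed projection, shapes, composed oracle", {
  set.seed(13)
  # stride 1, in = out, zeroed projection path -> exact identity
  b <- inverted_residual_block(6, 6, stride = 1, expansion = 6)
  b$children$path$children$project$params$W[] <- 0
  x <- rand_arr(5, 5, 6, 2)
  expect_identical(nn_forward(b, x), x)

  # stride 2: halved spatial size, no residual
  b2 <- inverted_residual_block(16, 16, stride = 2, expansion = 6)
  y2 <- nn_forward(b2, rand_arr(8, 8, 16, 1))
  expect_shape(y2, c(4, 4, 16, 1))
  expect_false(b2$use_res)
  expect_error(inverted_residual_block(4, 4, stride = 3), "stride")

  # composed oracle: run the three stages independently and add the input
  b3 <- inverted_residual_block(24, 24, stride = 1, expansion = 6)
  x3 <- rand_arr(4, 4, 24, 1)
  p <- b3$children$path$children
  ref <- nn_forward(p$expand_act, nn_forward(p$expand_bn, nn_forward(p$expand, x3)))
  ref <- nn_forward(p$dw_act, nn_forward(p$dw_bn, nn_forward(p$dw, ref)))
  ref <- nn_forward(p$project_bn, nn_forward(p$project, ref)) + x3
  expect_equal(nn_forward(b3, x3), ref, tolerance = 1e-12)
})

test_that("strip pooling reproduces the hand-worked 2x2 example", {
  sp <- strip_pool_block(1, internal = NULL)
  bn_identity(sp)
  conv_identity(sp$children$hconv)
  conv_identity(sp$children$vconv)
  conv_identity(sp$children$fuse)
  x <- array(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE), c(2, 2, 1, 1))
  # row means [1.5, 3.5]; column means [2, 3];
  # fused y[i,j] = yh[i] + yv[j] = [[3.5, 4.5], [5.5, 6.5]]; z = x * sigmoid(y)
  yfused <- matrix(c(3.5, 4.5, 5.5, 6.5), 2, 2, byrow = TRUE)
  z <- nn_forward(sp, x)
  expect_equal(z[, , 1, 1], x[, , 1, 1] / (1 + exp(-yfused)), tolerance = 1e-6)
})

test_that("strip pooling: constant input, shape preservation, transpose symmetry", {
  sp <- strip_pool_block(1, internal = NULL)
  bn_identity(sp)
  conv_identity(sp$children$hconv)
  conv_identity(sp$children$vconv)
  conv_identity(sp$children$fuse)
  cst <- 0.7
  xc <- array(cst, c(3, 4, 1, 1))
  zc <- nn_forward(sp, xc)
  expect_equal(as.vector(zc), rep(cst / (1 + exp(-2 * cst)), 12), tolerance = 1e-6)

  set.seed(14)
  x <- rand_arr(3, 5, 1, 1)
  z <- nn_forward(sp, x)
  expect_shape(z, dim(x))
  # identical h/v transforms: transposing the input transposes the output
  xt <- array(t(x[, , 1, 1]), c(5, 3, 1, 1))
  zt <- nn_forward(sp, xt)
  expect_equal(zt[, , 1, 1], t(z[, , 1, 1]), tolerance = 1e-6)

  # default (reduced) variant preserves shape and gates in (0,1)
  spr <- strip_pool_block(8)
  xr <- rand_arr(6, 7, 8, 2)
  zr <- nn_forward(spr, xr)
  expect_shape(zr, dim(xr))
  expect_true(all(abs(zr) <= abs(xr) + 1e-12))
  expect_error(nn_forward(spr, array(0, c(0, 4, 8, 1))), "input error")
})

test_that("channel attention follows the shared-perceptron formula", {
  ca <- channel_attention_block(2, ratio = 1)
  # zero input, no biases -> sigmoid(0) = 0.5 everywhere
  expect_equal(as.vector(nn_forward(ca, array(0, c(3, 3, 2, 1)))), c(0.5, 0.5))

  # hand evaluation with given small weights on a 2-channel 2x2 input
  ca$params$W1 <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  ca$params$W2 <- matrix(c(0.4, 0.2, -0.3, 0.6), 2, 2)
  x <- array(c(1, 2, 3, 4, -1, 0, 1, 2), c(2, 2, 2, 1))
  avg <- c(mean(x[, , 1, 1]), mean(x[, , 2, 1]))
  mx <- c(max(x[, , 1, 1]), max(x[, , 2, 1]))
  mlp <- function(v) ca$params$W2 %*% pmax(ca$params$W1 %*% v, 0)
  expect_equal(as.vector(nn_forward(ca, x)),
               as.vector(1 / (1 + exp(-(mlp(avg) + mlp(mx))))), tolerance = 1e-12)

  # constant input c per channel with identity perceptron -> sigmoid(2c)
  ca2 <- channel_attention_block(1, ratio = 1)
  ca2$params$W1[] <- 1
  ca2$params$W2[] <- 1
  expect_equal(as.vector(nn_forward(ca2, array(0.3, c(4, 4, 1, 1)))),
               1 / (1 + exp(-0.6)), tolerance = 1e-12)
  expect_error(channel_attention_block(24, ratio = 16), "divisible")
})

test_that("spatial attention matches a direct window-sum oracle", {
  sa <- spatial_attention_block(kernel = 7)
  # zero input, zero kernel -> 0.5 everywhere, input-sized
  y0 <- nn_forward(sa, array(0, c(5, 9, 3, 1)))
  expect_shape(y0, c(5, 9, 1, 1))
  expect_true(all(y0 == 0.5))

  set.seed(15)
  sa$children$conv$params$W[] <- 1
  x <- rand_arr(4, 4, 3, 1)
  y <- nn_forward(sa, x)
  meanmap <- apply(x[, , , 1], c(1, 2), mean)
  maxmap <- apply(x[, , , 1], c(1, 2), max)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    acc <- 0
    for (di in -3:3) for (dj in -3:3) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 4 && jj >= 1 && jj <= 4)
        acc <- acc + meanmap[ii, jj] + maxmap[ii, jj]
    }
    ref[i, j] <- 1 / (1 + exp(-acc))
  }
  expect_equal(y[, , 1, 1], ref, tolerance = 1e-9)
})

test_that("CBAM composes the two attentions and bounds its output", {
  set.seed(16)
  cb <- cbam_block(8, ratio = 4)
  x <- rand_arr(5, 6, 8, 2)
  y <- nn_forward(cb, x)
  expect_shape(y, dim(x))
  expect_true(all(nn_forward(cb, array(0, c(4, 4, 8, 1))) == 0))
  expect_true(all(abs(y) <= abs(x) + 1e-12))

  # composition oracle from the two sub-blocks
  mc <- nn_forward(cb$children$ca, x)
  g <- x * array(rep(as.vector(mc), each = 30), dim(x))
  ms <- nn_forward(cb$children$sa, g)
  msf <- aperm(array(rep(as.vector(ms), 8), c(5, 6, 2, 8)), c(1, 2, 4, 3))
  expect_equal(y, g * msf, tolerance = 1e-12)

  # gates strictly inside (0,1) for finite inputs
  expect_true(all(mc > 0 & mc < 1))
  expect_true(all(ms > 0 & ms < 1))
})

test_that("hand-derived backward passes agree with numerical differentiation", {
  set.seed(17)
  grad_err <- function(m, xdim, eps = 1e-5) {
    x <- rand_arr(xdim[1], xdim[2], xdim[3], xdim[4])
    r <- dscseg:::nn_fwd(m, x, training = TRUE, grad = TRUE)
    dy <- array(rnorm(length(r$y)), dim(r$y))
    dscseg:::nn_zero_grad(m)
    dx <- r$vjp(dy)
    f <- function(xx) sum(dscseg:::nn_fwd(m, xx, training = TRUE, grad = FALSE)$y * dy)
    errs <- c()
    for (k in sample(length(x), 4)) {
      xp <- x; xp[k] <- xp[k] + eps
      xm <- x; xm[k] <- xm[k] - eps
      errs <- c(errs, abs((f(xp) - f(xm)) / (2 * eps) - dx[k]))
    }
    for (lf in nn_modules(m)) for (pn in names(lf$params)) {
      k <- sample(length(lf$params[[pn]]), 1)
      orig <- lf$params[[pn]][k]
      lf$params[[pn]][k] <- orig + eps; fp <- f(x)
      lf$params[[pn]][k] <- orig - eps; fm <- f(x)
      lf$params[[pn]][k] <- orig
      errs <- c(errs, abs((fp - fm) / (2 * eps) - lf$grads[[pn]][k]))
    }
    max(errs)
  }
  expect_lt(grad_err(dsd_conv_block(3, 4, dilation = 2), c(6, 6, 3, 2)), 1e-6)
  expect_lt(grad_err(inverted_residual_block(4, 4, 1, 6), c(6, 6, 4, 2)), 1e-6)
  expect_lt(grad_err(strip_pool_block(8), c(5, 6, 8, 2)), 1e-6)
  expect_lt(grad_err(cbam_block(8, ratio = 4), c(5, 5, 8, 2)), 1e-6)
})
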