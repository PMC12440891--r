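test_that("S-ASPP preserves spatial size and collapses to plain ASPP when disabled", {
  set.seed(31)
  cfg <- model_config()
  aspp <- s_aspp_block(320, cfg)
  x <- rand_arr(8, 8, 320, 1)
  expect_shape(nn_forward(aspp, x), c(8, 8, 256, 1))
  expect_identical(aspp$n_branch, 6)

  plain <- s_aspp_block(320, make_ablation_variant("group1"))
  expect_identical(plain$n_branch, 5)
  expect_null(plain$children$strip)
  expect_null(plain$children$cbam)
  expect_shape(nn_forward(plain, x), c(8, 8, 256, 1))
  expect_error(model_config(aspp_rates = c(6, 6, 12)), "increasing")

  # constant input: the global mean of a constant is the constant, so the 1x1
  # branch and the pooling branch feed identical values through a shared conv
  xc <- array(1.3, c(4, 4, 320, 1))
  shared <- plain$children$b1$children$conv
  b1 <- nn_forward(shared, xc)
  b5 <- nn_forward(shared, array(.colMeans(xc, 16, 320), c(1, 1, 320, 1)))
  expect_equal(b1[1, 1, , 1], b5[1, 1, , 1], tolerance = 1e-12)
})

test_that("C-CFF matches hand evaluation on a 4x4 / 2x2 pair", {
  set.seed(32)
  cfg <- model_config(cff_width = 1)
  cff <- c_cff_block(1, 1, cfg)
  bn_identity(cff)
  conv_identity(cff$children$kappa)
  # phi is 3x3: make it pass the center tap only
  W <- cff$children$phi$params$W; W[] <- 0; W[2, 2, 1, 1] <- 1
  cff$children$phi$params$W <- W
  # identity channel-attention perceptron, zero spatial kernel (gate = 0.5)
  cff$children$att$children$ca$params$W1[] <- 1
  cff$children$att$children$ca$params$W2[] <- 1
  cff$children$att$children$sa$children$conv$params$W[] <- 0

  f1 <- array(matrix(c(1, -2, 0.5, 3, -1, 2, 0.25, -0.5,
                       1.5, 0.75, -0.25, 2, 0.1, -1.2, 0.6, 1), 4, 4), c(4, 4, 1, 1))
  cst <- 0.8
  f2 <- array(cst, c(2, 2, 1, 1))                  # constant: upsampling-exact
  out <- c_cff_forward(cff, f1, f2)
  f3 <- f1[, , 1, 1] + cst                         # F3 = kappa(F1) + phi(up2(F2))
  mlp <- function(v) pmax(v, 0)                    # identity two-layer perceptron
  mc <- 1 / (1 + exp(-(mlp(mean(f3)) + mlp(max(f3)))))
  g <- mc * f3                                     # channel-recalibrated map
  tau <- 0.5 * g                                   # spatial gate sigmoid(0)
  expect_equal(out[, , 1, 1], pmax(tau, 0), tolerance = 1e-4)

  # zero inputs give an identically zero fused map; output is always >= 0
  z <- c_cff_forward(cff, array(0, c(4, 4, 1, 1)), array(0, c(2, 2, 1, 1)))
  expect_true(all(z == 0))
  cff2 <- c_cff_block(32, 96, model_config())
  o2 <- c_cff_forward(cff2, rand_arr(8, 8, 32, 1), rand_arr(4, 4, 96, 1))
  expect_true(all(o2 >= 0))
  expect_shape(o2, c(8, 8, 48, 1))
  expect_error(c_cff_forward(cff2, rand_arr(8, 8, 32, 1), rand_arr(3, 4, 96, 1)),
               "twice")
})

test_that("assembled model emits logits at the input resolution", {
  set.seed(33)
  model <- assemble_model(model_config(), seed = 33)
  y <- nn_forward(model, rand_arr(64, 64, 3, 1))
  expect_shape(y, c(64, 64, 3, 1))
  # non-square input, different batch
  y2 <- nn_forward(model, rand_arr(32, 48, 3, 2))
  expect_shape(y2, c(32, 48, 3, 2))
  expect_error(nn_forward(model, rand_arr(40, 64, 3, 1)), "divisible")
})

test_that("ablation variants toggle exactly the flagged modules", {
  cfgs <- lapply(c("group1", "group2", "group3", "group4"), make_ablation_variant)
  expect_identical(cfgs[[4]], model_config())
  expect_error(make_ablation_variant("group5"))

  models <- lapply(cfgs, assemble_model, seed = 41)
  p <- vapply(models, nn_param_count, numeric(1))
  # parameter monotonicity across the ablation axes
  expect_lt(p[1], p[2]); expect_lt(p[2], p[4])
  expect_lt(p[1], p[3]); expect_lt(p[3], p[4])

  # structural diff: group2 adds only strip-pooling + CBAM weights (and widens
  # the ASPP projection); group3 adds only the C-CFF block (and widens the
  # first decoder stage)
  n1 <- names(nn_parameters(models[[1]]))
  n2 <- names(nn_parameters(models[[2]]))
  n3 <- names(nn_parameters(models[[3]]))
  expect_true(all(grepl("aspp\\.(strip|cbam)", setdiff(n2, n1))))
  expect_true(all(grepl("ccff", setdiff(n3, n1))))
  expect_length(setdiff(n1, n2), 0)
  expect_length(setdiff(n1, n3), 0)

  # layer-walk difference oracle: params(full) - params(no C-CFF) equals the
  # independently counted C-CFF weight total plus the decoder widening
  ccff_params <- (32 * 48 + 2 * 48) +        # kappa + BN
    (9 * 96 * 48 + 2 * 48) +                 # phi (3x3 dense) + BN
    (2 * 48 * 3) +                           # CBAM shared perceptron (hidden 3)
    (7 * 7 * 2)                              # CBAM spatial kernel
  decoder_widening <- 9 * 48 + 2 * 48 +      # wider depthwise stage + BN
    48 * 256                                 # wider pointwise stage
  expect_identical(p[4] - p[2], ccff_params + decoder_widening)
})

test_that("every spatial convolution in ASPP dilated branches and decoder is separable", {
  model <- assemble_model(model_config(), seed = 42)
  leaves <- nn_modules(model)
  spatial_dense <- Filter(function(m) {
    inherits(m, "conv2d") && any(dim(m$params$W)[1:2] > 1)
  }, leaves)
  # the only dense spatial kernels allowed: the stem 3x3, the C-CFF dilated
  # alignment conv, and the CBAM 7x7 spatial-attention kernels
  ok <- grepl("backbone\\.stem|ccff\\.phi|\\.sa\\.conv", names(spatial_dense))
  expect_true(all(ok))
  # decoder stages and ASPP dilated branches are DSDConv modules
  expect_s3_class(model$children$dec1, "dsd_conv")
  expect_s3_class(model$children$dec2, "dsd_conv")
  for (b in c("b2", "b3", "b4"))
    expect_s3_class(model$children$aspp$children[[b]], "dsd_conv")
})
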