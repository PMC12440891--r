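# Brute-force dense convolution by nested loops: the independent oracle for
# every convolution-factorization check.
brute_conv <- function(x, w, stride = c(1, 1), pad = c(0, 0), dil = c(1, 1)) {
  d <- dim(x); wd <- dim(w)
  Ho <- (d[1] + 2 * pad[1] - dil[1] * (wd[1] - 1) - 1) %/% stride[1] + 1
  Wo <- (d[2] + 2 * pad[2] - dil[2] * (wd[2] - 1) - 1) %/% stride[2] + 1
  y <- array(0, c(Ho, Wo, wd[4], d[4]))
  for (n in seq_len(d[4])) for (o in seq_len(wd[4]))
    for (j in seq_len(Wo)) for (i in seq_len(Ho))
      for (cc in seq_len(wd[3])) for (kj in seq_len(wd[2])) for (ki in seq_len(wd[1])) {
        si <- (i - 1) * stride[1] - pad[1] + (ki - 1) * dil[1] + 1
        sj <- (j - 1) * stride[2] - pad[2] + (kj - 1) * dil[2] + 1
        if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2])
          y[i, j, o, n] <- y[i, j, o, n] + x[si, sj, cc, n] * w[ki, kj, cc, o]
      }
  y
}

# force a batch-norm layer to the exact identity in inference mode
bn_identity <- function(m) {
  for (lf in nn_modules(m)) {
    if (inherits(lf, "batch_norm")) {
      lf$run_mean[] <- 0
      lf$run_var[] <- 1 - lf$eps
      lf$params$gamma[] <- 1
      lf$params$beta[] <- 0
    }
  }
  invisible(m)
}

# set a 1x1 (or kernel-3 depthwise) convolution to the identity map
conv_identity <- function(conv) {
  W <- conv$params$W
  W[] <- 0
  wd <- dim(W)
  if (inherits(conv, "dwconv2d")) {
    W[(wd[1] + 1) %/% 2, (wd[2] + 1) %/% 2, ] <- 1
  } else {
    stopifnot(wd[3] == wd[4])
    for (cc in seq_len(wd[3])) W[(wd[1] + 1) %/% 2, (wd[2] + 1) %/% 2, cc, cc] <- 1
  }
  conv$params$W <- W
  invisible(conv)
}

expect_shape <- function(x, shape) expect_identical(dim(x), as.integer(shape))

rand_arr <- function(...) array(rnorm(prod(c(...))), c(...))
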