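# ---------------------------------------------------------------------------
# MobileNetV2 feature extractor.  The stage table reproduces the standard
# (t, c, n, s) layout: expansion factor, output channels, repeats, first-block
# stride.  Classification mode realizes the full network including the final
# 1280-channel 1x1 convolution, global average pooling and classifier;
# segmentation mode drops those and optionally converts the last stride-2
# stage to stride 1 with dilation 2, keeping the deepest features at 1/16 of
# the input resolution (the usual output-stride-16 dilation trick).
# ---------------------------------------------------------------------------

mobilenet_v2_stages <- function() {
  data.frame(t = c(1, 6, 6, 6, 6, 6, 6),
             c = c(16, 24, 32, 64, 96, 160, 320),
             n = c(1, 2, 3, 4, 3, 3, 1),
             s = c(1, 2, 2, 2, 1, 2, 1))
}

#' Build the MobileNetV2 backbone
#'
#' @param mode `"segmentation"` (feature extractor with multi-resolution
#'   taps) or `"classification"` (adds the 1280-channel head, average pool
#'   and classifier).
#' @param output_stride 16 or 32; 16 replaces the stride of the 160-channel
#'   stage by 1 and dilates subsequent depthwise kernels by 2
#'   (segmentation mode only).
#' @param num_classes classifier width in classification mode.
#' @return a backbone module; see [backbone_features()].
#' @export
mobilenet_v2 <- function(mode = c("segmentation", "classification"),
                         output_stride = 16, num_classes = 1000) {
  mode <- match.arg(mode)
  if (!output_stride %in% c(16, 32))
    stop("configuration error: output_stride must be 16 or 32")
  stages <- mobilenet_v2_stages()
  ch <- list(
    stem = nn_sequential(conv = conv2d(3, 32, kernel = 3, stride = 2),
                         bn = batch_norm(32), act = act_module("relu6"))
  )
  in_ch <- 32
  stride_so_far <- 2
  dilation <- 1
  for (si in seq_len(nrow(stages))) {
    row <- stages[si, ]
    blocks <- list()
    for (bi in seq_len(row$n)) {
      s <- if (bi == 1) row$s else 1
      if (mode == "segmentation" && output_stride == 16 &&
          s == 2 && stride_so_far >= 16) {
        s <- 1
        dilation <- 2
      }
      if (bi == 1) stride_so_far <- stride_so_far * s
      blocks[[sprintf("b%d", bi)]] <-
        inverted_residual_block(in_ch, row$c, stride = s,
                                expansion = row$t, dilation = dilation)
      in_ch <- row$c
    }
    ch[[sprintf("stage%d", si)]] <- do.call(nn_sequential, blocks)
  }
  if (mode == "classification") {
    ch$head <- nn_sequential(conv = conv2d(320, 1280, kernel = 1),
                             bn = batch_norm(1280), act = act_module("relu6"))
    ch$classifier <- linear_layer(1280, num_classes)
  }
  new_module("mobilenet_v2", children = ch, mode = mode,
             output_stride = output_stride)
}

# taps: stage2 output (24 ch, 1/4), stage3 (32 ch, 1/8),
#       stage5 (96 ch, 1/16), stage7 (320 ch, 1/16)
#' @export
nn_fwd.mobilenet_v2 <- function(m, x, training = FALSE, grad = FALSE) {
  vjps <- list()
  taps <- list()
  run <- function(name, z) {
    pr_push(name)
    r <- nn_fwd(m$children[[name]], z, training = training, grad = grad)
    pr_pop()
    if (grad) vjps[[name]] <<- r$vjp
    r$y
  }
  z <- run("stem", x)
  for (si in 1:7) {
    z <- run(sprintf("stage%d", si), z)
    if (si == 2) taps$os4 <- z
    if (si == 3) taps$os8 <- z
    if (si == 5) taps$os16_mid <- z
  }
  taps$os16_deep <- z
  if (m$mode == "classification") {
    z <- run("head", z)
    d <- dim(z)
    gp <- array(.colMeans(z, d[1] * d[2], d[3] * d[4]), c(d[3], d[4]))
    rl <- nn_fwd(m$children$classifier, gp, training = training, grad = grad)
    if (grad) vjps$classifier_full <- function(dy) {
      dgp <- rl$vjp(dy)
      array(rep(as.vector(dgp) / (d[1] * d[2]), each = d[1] * d[2]), d)
    }
    return(list(y = rl$y, taps = taps, vjp = if (grad) function(dy) {
      dz <- vjps$classifier_full(dy)
      dz <- vjps$head(dz)
      for (si in 7:1) dz <- vjps[[sprintf("stage%d", si)]](dz)
      vjps$stem(dz)
    }))
  }
  # segmentation: primary output is the deep tap; vjp accepts gradients for
  # all four taps as a named list
  vjp <- if (grad) function(dtaps) {
    dz <- dtaps$os16_deep
    for (si in 7:1) {
      if (si == 5 && !is.null(dtaps$os16_mid)) dz <- dz + dtaps$os16_mid
      if (si == 3 && !is.null(dtaps$os8)) dz <- dz + dtaps$os8
      if (si == 2 && !is.null(dtaps$os4)) dz <- dz + dtaps$os4
      dz <- vjps[[sprintf("stage%d", si)]](dz)
    }
    vjps$stem(dz)
  }
  list(y = taps$os16_deep, taps = taps, vjp = vjp)
}

#' Extract multi-resolution backbone features
#'
#' Runs the segmentation-mode backbone and returns the four taps: `os4`
#' (24 channels, 1/4 resolution), `os8` (32 ch, 1/8), `os16_mid` (96 ch,
#' 1/16) and `os16_deep` (320 ch, 1/16).
#'
#' @param backbone module from [mobilenet_v2()].
#' @param x input array `(H, W, 3, N)`; H and W must be divisible by 16.
#' @param training logical.
#' @return named list of the four feature arrays.
#' @export
backbone_features <- function(backbone, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("input error: height and width must be divisible by 16")
  nn_fwd(backbone, x, training = training, grad = FALSE)$taps
}
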