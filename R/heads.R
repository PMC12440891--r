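# ---------------------------------------------------------------------------
# Encoder head (S-ASPP), decoder fusion (C-CFF) and full-model assembly with
# ablation toggles.
# ---------------------------------------------------------------------------

#' Model configuration
#'
#' All architectural knobs of the segmentation network.  Defaults give the
#' full model: MobileNetV2 backbone at output stride 16, six-branch S-ASPP
#' with CBAM, C-CFF fusion of the 1/8 and 1/16 taps, and a depthwise
#' separable decoder.
#'
#' @param num_classes number of output classes (>= 2).
#' @param aspp_rates three strictly increasing dilation rates.
#' @param aspp_width ASPP branch width (channels).
#' @param cff_width C-CFF output width.
#' @param lowlevel_width width of the reduced 1/4-resolution decoder tap.
#' @param use_s_aspp strip-pooling sixth branch on/off (off = plain 5-branch
#'   ASPP with DSDConv branches).
#' @param use_c_cff C-CFF fusion branch on/off.
#' @param use_cbam_after_aspp CBAM refinement after the ASPP projection.
#' @param cff_attention recalibration inside C-CFF: "none", "cam", "sam" or
#'   "cbam".
#' @param decoder_convs number of 3x3 DSDConv stages in the decoder (1 or 2).
#' @param output_stride backbone output stride (16 or 32).
#' @export
model_config <- function(num_classes = 3, aspp_rates = c(6, 12, 18),
                         aspp_width = 256, cff_width = 48, lowlevel_width = 48,
                         use_s_aspp = TRUE, use_c_cff = TRUE,
                         use_cbam_after_aspp = TRUE,
                         cff_attention = c("cbam", "none", "cam", "sam"),
                         decoder_convs = 2, output_stride = 16) {
  if (num_classes < 2) stop("configuration error: num_classes must be >= 2")
  if (length(aspp_rates) != 3 || any(diff(aspp_rates) <= 0))
    stop("configuration error: aspp_rates must be three strictly increasing values")
  if (!decoder_convs %in% c(1, 2))
    stop("configuration error: decoder_convs must be 1 or 2")
  cff_attention <- match.arg(cff_attention)
  structure(list(num_classes = num_classes, aspp_rates = aspp_rates,
                 aspp_width = aspp_width, cff_width = cff_width,
                 lowlevel_width = lowlevel_width, use_s_aspp = use_s_aspp,
                 use_c_cff = use_c_cff,
                 use_cbam_after_aspp = use_cbam_after_aspp,
                 cff_attention = cff_attention, decoder_convs = decoder_convs,
                 output_stride = output_stride),
            class = "model_config")
}

conv_bn_relu <- function(in_ch, out_ch, kernel = 1, dilation = 1) {
  nn_sequential(conv = conv2d(in_ch, out_ch, kernel = kernel, dilation = dilation),
                bn = batch_norm(out_ch), act = act_module("relu"))
}

#' Atrous spatial pyramid pooling head (S-ASPP)
#'
#' Parallel branches on the deepest backbone tap: (1) a 1 x 1 convolution,
#' (2-4) 3 x 3 DSDConv at the three dilation rates, (5) global average
#' pooling -> 1 x 1 convolution -> bilinear broadcast, and, when
#' `use_s_aspp`, (6) strip pooling -> 1 x 1 convolution.  Branches are
#' concatenated and projected to `aspp_width` channels; when
#' `use_cbam_after_aspp` a CBAM refines the projection.  Spatial size is
#' preserved.
#'
#' @param in_ch input channels (the 320-channel 1/16 tap).
#' @param cfg a [model_config()].
#' @export
s_aspp_block <- function(in_ch = 320, cfg = model_config()) {
  w <- cfg$aspp_width
  r <- cfg$aspp_rates
  ch <- list(
    b1 = conv_bn_relu(in_ch, w, kernel = 1),
    b2 = dsd_conv_block(in_ch, w, kernel = 3, dilation = r[1]),
    b3 = dsd_conv_block(in_ch, w, kernel = 3, dilation = r[2]),
    b4 = dsd_conv_block(in_ch, w, kernel = 3, dilation = r[3]),
    pool_conv = conv_bn_relu(in_ch, w, kernel = 1)
  )
  n_branch <- 5
  if (cfg$use_s_aspp) {
    ch$strip <- strip_pool_block(in_ch)
    ch$strip_conv <- conv_bn_relu(in_ch, w, kernel = 1)
    n_branch <- 6
  }
  ch$project <- conv_bn_relu(n_branch * w, w, kernel = 1)
  ch$drop <- dropout_layer(0.1)
  if (cfg$use_cbam_after_aspp) ch$cbam <- cbam_block(w)
  new_module("s_aspp", children = ch, n_branch = n_branch, width = w)
}

#' @export
nn_fwd.s_aspp <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  ch <- m$children
  vjps <- list()
  run <- function(name, z) {
    pr_push(name)
    r <- nn_fwd(ch[[name]], z, training = training, grad = grad)
    pr_pop()
    if (grad) vjps[[name]] <<- r$vjp
    r$y
  }
  outs <- list(run("b1", x), run("b2", x), run("b3", x), run("b4", x))
  # image-level pooling branch: global mean, 1x1 conv, broadcast back
  gp <- array(.colMeans(x, d[1] * d[2], d[3] * d[4]), c(1, 1, d[3], d[4]))
  pc <- run("pool_conv", gp)
  outs[[5]] <- array(rep(as.vector(pc), each = d[1] * d[2]),
                     c(d[1], d[2], m$width, d[4]))
  if (m$n_branch == 6) {
    outs[[6]] <- run("strip_conv", run("strip", x))
  }
  cc <- cat_channels(outs)
  y <- run("drop", run("project", cc))
  if (!is.null(ch$cbam)) y <- run("cbam", y)
  vjp <- if (grad) function(dy) {
    if (!is.null(ch$cbam)) dy <- vjps$cbam(dy)
    dcc <- vjps$project(vjps$drop(dy))
    parts <- split_channels(dcc, rep(m$width, m$n_branch))
    dx <- vjps$b1(parts[[1]]) + vjps$b2(parts[[2]]) +
      vjps$b3(parts[[3]]) + vjps$b4(parts[[4]])
    dpc <- array(.colSums(parts[[5]], d[1] * d[2], m$width * d[4]),
                 c(1, 1, m$width, d[4]))
    dgp <- vjps$pool_conv(dpc)
    dx <- dx + array(rep(as.vector(dgp) / (d[1] * d[2]), each = d[1] * d[2]), d)
    if (m$n_branch == 6) dx <- dx + vjps$strip(vjps$strip_conv(parts[[6]]))
    dx
  }
  list(y = y, vjp = vjp)
}

#' Cascade feature fusion with attention recalibration (C-CFF)
#'
#' Fuses a shallow 1/8 tap `F1` with a deep 1/16 tap `F2`:
#' `F3 = BN(conv1x1(F1)) + BN(dilated_conv(upsample2x(F2)))`, recalibrates
#' `F3` with the configured attention (CBAM by default) and applies a final
#' ReLU.  Output is at `F1`'s spatial size with `cff_width` channels and is
#' element-wise non-negative.
#'
#' @param in1,in2 channel counts of F1 and F2.
#' @param cfg a [model_config()].
#' @export
c_cff_block <- function(in1 = 32, in2 = 96, cfg = model_config()) {
  w <- cfg$cff_width
  ch <- list(
    kappa = conv2d(in1, w, kernel = 1),
    kappa_bn = batch_norm(w),
    up2 = upsample_layer(2),
    phi = conv2d(in2, w, kernel = 3, dilation = 2),
    phi_bn = batch_norm(w)
  )
  ch <- c(ch, switch(cfg$cff_attention,
    cbam = list(att = cbam_block(w)),
    cam = list(att = channel_attention_block(w)),
    sam = list(att = spatial_attention_block()),
    none = NULL))
  ch$act <- act_module("relu")
  new_module("c_cff", children = ch, attention = cfg$cff_attention)
}

#' @export
nn_fwd.c_cff <- function(m, f1, training = FALSE, grad = FALSE, f2 = NULL) {
  if (any(dim(f1)[1:2] != 2 * dim(f2)[1:2]))
    stop("input error: F1 spatial size must be exactly twice F2's")
  ch <- m$children
  vjps <- list()
  run <- function(name, z) {
    r <- nn_fwd(ch[[name]], z, training = training, grad = grad)
    if (grad) vjps[[name]] <<- r$vjp
    r$y
  }
  a <- run("kappa_bn", run("kappa", f1))
  b <- run("phi_bn", run("phi", run("up2", f2)))
  f3 <- a + b
  gate <- NULL
  g <- switch(m$attention,
    cbam = run("att", f3),
    cam = { gate <- run("att", f3); mul_channel_gate(f3, gate) },
    sam = { gate <- run("att", f3); mul_spatial_gate(f3, gate) },
    none = f3)
  y <- run("act", g)
  vjp <- if (grad) function(dy) {
    dg <- vjps$act(dy)
    df3 <- switch(m$attention,
      cbam = vjps$att(dg),
      cam = mul_channel_gate(dg, gate) +
        vjps$att(sum_to_channel_gate(dg * f3)),
      sam = mul_spatial_gate(dg, gate) +
        vjps$att(sum_to_spatial_gate(dg * f3)),
      none = dg)
    df1 <- vjps$kappa(vjps$kappa_bn(df3))
    df2 <- vjps$up2(vjps$phi(vjps$phi_bn(df3)))
    list(df1 = df1, df2 = df2)
  }
  list(y = y, vjp = vjp, f3 = f3)
}

#' Apply a C-CFF block to a shallow/deep feature pair
#'
#' @param block module from [c_cff_block()].
#' @param f1 shallow tap `(2H, 2W, C1, N)`.
#' @param f2 deep tap `(H, W, C2, N)`.
#' @param training logical.
#' @export
c_cff_forward <- function(block, f1, f2, training = FALSE) {
  if (length(dim(f1)) == 3L) dim(f1) <- c(dim(f1), 1L)
  if (length(dim(f2)) == 3L) dim(f2) <- c(dim(f2), 1L)
  nn_fwd(block, f1, training = training, grad = FALSE, f2 = f2)$y
}

#' Assemble the full segmentation model
#'
#' Encoder: MobileNetV2 backbone plus the (S-)ASPP head on the 1/16 deep tap.
#' Decoder: the 1/4 tap reduced by a 1 x 1 convolution, concatenated with the
#' 4x-upsampled ASPP output and (when enabled) the 2x-upsampled C-CFF fusion
#' of the 1/8 and 1/16 taps, refined by 3 x 3 DSDConv stages at 256 channels,
#' classified by a 1 x 1 convolution and restored to the input resolution by
#' 4x bilinear upsampling.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer; when given, weight initialization is drawn
#'   under this seed without disturbing the caller's RNG stream.
#' @return a model module; run with [nn_forward()] to obtain per-class logits
#'   at the input resolution.
#' @export
assemble_model <- function(cfg = model_config(), seed = NULL) {
  build <- function() {
    ch <- list(
      backbone = mobilenet_v2("segmentation", output_stride = cfg$output_stride),
      aspp = s_aspp_block(320, cfg),
      ll_reduce = conv_bn_relu(24, cfg$lowlevel_width, kernel = 1),
      up4 = upsample_layer(4)
    )
    dec_in <- cfg$lowlevel_width + cfg$aspp_width
    if (cfg$use_c_cff) {
      ch$ccff <- c_cff_block(32, 96, cfg)
      ch$up_cff <- upsample_layer(2)
      dec_in <- dec_in + cfg$cff_width
    }
    ch$dec1 <- dsd_conv_block(dec_in, 256, kernel = 3)
    if (cfg$decoder_convs == 2) ch$dec2 <- dsd_conv_block(256, 256, kernel = 3)
    ch$classifier <- conv2d(256, cfg$num_classes, kernel = 1, bias = TRUE)
    ch$up_final <- upsample_layer(4)
    new_module("dsc_model", children = ch, cfg = cfg)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' @export
nn_fwd.dsc_model <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("input error: height and width must be divisible by 16")
  ch <- m$children
  vjps <- list()
  run <- function(name, z) {
    pr_push(name)
    r <- nn_fwd(ch[[name]], z, training = training, grad = grad)
    pr_pop()
    if (grad) vjps[[name]] <<- r$vjp
    r$y
  }
  pr_push("backbone")
  rb <- nn_fwd(ch$backbone, x, training = training, grad = grad)
  pr_pop()
  taps <- rb$taps
  a <- run("aspp", taps$os16_deep)
  a4 <- run("up4", a)
  ll <- run("ll_reduce", taps$os4)
  parts <- list(ll, a4)
  if (!is.null(ch$ccff)) {
    pr_push("ccff")
    rc <- nn_fwd(ch$ccff, taps$os8, training = training, grad = grad,
                 f2 = taps$os16_mid)
    pr_pop()
    parts[[3]] <- run("up_cff", rc$y)
  }
  z <- cat_channels(parts)
  z <- run("dec1", z)
  if (!is.null(ch$dec2)) z <- run("dec2", z)
  z <- run("classifier", z)
  logits <- run("up_final", z)
  vjp <- if (grad) function(dy) {
    dz <- vjps$up_final(dy)
    dz <- vjps$classifier(dz)
    if (!is.null(ch$dec2)) dz <- vjps$dec2(dz)
    dz <- vjps$dec1(dz)
    cs <- vapply(parts, function(p) dim(p)[3], numeric(1))
    dparts <- split_channels(dz, cs)
    dtaps <- list(os4 = vjps$ll_reduce(dparts[[1]]),
                  os16_deep = vjps$aspp(vjps$up4(dparts[[2]])))
    if (!is.null(ch$ccff)) {
      dcf <- rc$vjp(vjps$up_cff(dparts[[3]]))
      dtaps$os8 <- dcf$df1
      dtaps$os16_mid <- dcf$df2
    }
    rb$vjp(dtaps)
  }
  list(y = logits, vjp = vjp)
}

#' Ablation-study configurations
#'
#' `group1`: MobileNetV2 backbone with DSDConv substitution, plain 5-branch
#' ASPP, plain decoder.  `group2`: group1 plus the strip-pooling S-ASPP and
#' CBAM.  `group3`: group1 plus C-CFF.  `group4`: the full model.
#'
#' @param which one of `"group1"`, `"group2"`, `"group3"`, `"group4"`.
#' @param num_classes number of output classes.
#' @return a [model_config()].
#' @export
make_ablation_variant <- function(which = c("group4", "group1", "group2", "group3"),
                                  num_classes = 3) {
  which <- match.arg(which)
  switch(which,
    group1 = model_config(num_classes, use_s_aspp = FALSE,
                          use_cbam_after_aspp = FALSE, use_c_cff = FALSE),
    group2 = model_config(num_classes, use_s_aspp = TRUE,
                          use_cbam_after_aspp = TRUE, use_c_cff = FALSE),
    group3 = model_config(num_classes, use_s_aspp = FALSE,
                          use_cbam_after_aspp = FALSE, use_c_cff = TRUE),
    group4 = model_config(num_classes))
}
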