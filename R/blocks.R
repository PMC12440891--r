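# ---------------------------------------------------------------------------
# Neural building blocks: depthwise separable dilated convolution (DSDConv),
# the inverted residual bottleneck, strip pooling, channel / spatial
# attention and CBAM.  All blocks consume and emit (H, W, C, N) arrays and
# implement exact hand-derived backward passes.
# ---------------------------------------------------------------------------

#' Depthwise separable dilated convolution block
#'
#' Factorizes a k x k (optionally dilated) convolution into a per-channel
#' dilated depthwise stage followed by a 1 x 1 pointwise channel mixer, each
#' with batch normalization and ReLU.  For `k = 3`, parameters drop from
#' `9 * C_in * C_out` to `9 * C_in + C_in * C_out`.
#'
#' @param in_ch,out_ch channel counts.
#' @param kernel odd spatial kernel size of the depthwise stage.
#' @param stride 1 or 2.
#' @param dilation dilation rate of the depthwise kernel (>= 1).
#' @return a module; apply with [nn_forward()].
#' @export
dsd_conv_block <- function(in_ch, out_ch, kernel = 3, stride = 1, dilation = 1) {
  if (kernel %% 2 == 0) stop("configuration error: kernel must be odd")
  if (dilation < 1) stop("configuration error: dilation must be >= 1")
  if (!stride %in% c(1, 2)) stop("configuration error: stride must be 1 or 2")
  m <- nn_sequential(
    dw = dwconv2d(in_ch, kernel = kernel, stride = stride, dilation = dilation),
    dw_bn = batch_norm(in_ch),
    dw_act = act_module("relu"),
    pw = conv2d(in_ch, out_ch, kernel = 1),
    pw_bn = batch_norm(out_ch),
    pw_act = act_module("relu")
  )
  class(m) <- c("dsd_conv", class(m))
  m
}

#' Inverted residual bottleneck (expand - depthwise - linear project)
#'
#' The expansion stage widens channels by factor `expansion` (skipped when 1),
#' the depthwise 3 x 3 stage applies the stride/dilation, and a linear 1 x 1
#' projection narrows back with no nonlinearity.  A residual skip is applied
#' exactly when `stride == 1` and `in_ch == out_ch`.
#'
#' @param in_ch,out_ch channel counts.
#' @param stride 1 or 2.
#' @param expansion expansion factor t (>= 1).
#' @param dilation depthwise dilation (used by the output-stride-16 backbone).
#' @export
inverted_residual_block <- function(in_ch, out_ch, stride = 1, expansion = 6,
                                    dilation = 1) {
  if (!stride %in% c(1, 2)) stop("configuration error: stride must be 1 or 2")
  if (expansion < 1) stop("configuration error: expansion must be >= 1")
  hid <- in_ch * expansion
  layers <- list()
  if (expansion != 1) {
    layers$expand <- conv2d(in_ch, hid, kernel = 1)
    layers$expand_bn <- batch_norm(hid)
    layers$expand_act <- act_module("relu6")
  }
  layers$dw <- dwconv2d(hid, kernel = 3, stride = stride, dilation = dilation)
  layers$dw_bn <- batch_norm(hid)
  layers$dw_act <- act_module("relu6")
  layers$project <- conv2d(hid, out_ch, kernel = 1)
  layers$project_bn <- batch_norm(out_ch)
  path <- do.call(nn_sequential, layers)
  new_module("inverted_residual", children = list(path = path),
             use_res = (stride == 1 && in_ch == out_ch))
}

#' @export
nn_fwd.inverted_residual <- function(m, x, training = FALSE, grad = FALSE) {
  r <- nn_fwd(m$children$path, x, training = training, grad = grad)
  y <- if (m$use_res) r$y + x else r$y
  vjp <- if (grad) {
    function(dy) {
      dx <- r$vjp(dy)
      if (m$use_res) dx + dy else dx
    }
  }
  list(y = y, vjp = vjp)
}

# --- strip pooling ---------------------------------------------------------

# row means y^h (length H) and column means y^v (length W) per channel
strip_means <- function(u) {
  d <- dim(u)
  yh <- .colMeans(aperm(u, c(2, 1, 3, 4)), d[2], d[1] * d[3] * d[4])
  yv <- .colMeans(u, d[1], d[2] * d[3] * d[4])
  list(yh = array(yh, c(d[1], 1, d[3], d[4])),
       yv = array(yv, c(1, d[2], d[3], d[4])))
}

# broadcast an (H, 1, C, N) profile over width W
bcast_h <- function(h, W) {
  d <- dim(h)
  aperm(array(rep(as.vector(h), W), c(d[1], d[3], d[4], W)), c(1, 4, 2, 3))
}

# broadcast a (1, W, C, N) profile over height H
bcast_v <- function(v, H) {
  d <- dim(v)
  aperm(array(rep(as.vector(v), H), c(d[2], d[3], d[4], H)), c(4, 1, 2, 3))
}

# reduce an (H, W, C, N) gradient onto the H profile (sum over columns)
reduce_h <- function(g) {
  d <- dim(g)
  array(.colSums(aperm(g, c(2, 1, 3, 4)), d[2], d[1] * d[3] * d[4]),
        c(d[1], 1, d[3], d[4]))
}

reduce_v <- function(g) {
  d <- dim(g)
  array(.colSums(g, d[1], d[2] * d[3] * d[4]), c(1, d[2], d[3], d[4]))
}

#' Strip pooling block
#'
#' Pools each channel over whole rows and whole columns (weighted averaging
#' across the width and the height), passes each directional profile through
#' a kernel-3 one-dimensional convolution, broadcasts the two transformed
#' profiles back to H x W and sums them, then gates the input:
#' `z = x * sigmoid(f(y))` with `f` a 1 x 1 fusion convolution.  Output shape
#' equals input shape.
#'
#' @param channels input channel count.
#' @param internal channel width used for the directional profiles; `NULL`
#'   keeps the full channel count.  The default quarter-width reduction
#'   follows the original strip-pooling design.
#' @param dense_1d logical: dense (channel-mixing) 1-d convolutions on the
#'   profiles (`FALSE` gives per-channel depthwise 1-d convolutions).
#' @export
strip_pool_block <- function(channels, internal = max(1L, channels %/% 4L),
                             dense_1d = FALSE) {
  ci <- if (is.null(internal)) channels else internal
  ch <- list()
  if (!is.null(internal)) {
    ch$reduce <- conv2d(channels, ci, kernel = 1)
    ch$reduce_bn <- batch_norm(ci)
    ch$reduce_act <- act_module("relu")
  }
  ch$hconv <- if (dense_1d) conv2d(ci, ci, kernel = c(3, 1)) else dwconv2d(ci, kernel = c(3, 1))
  ch$hbn <- batch_norm(ci)
  ch$vconv <- if (dense_1d) conv2d(ci, ci, kernel = c(1, 3)) else dwconv2d(ci, kernel = c(1, 3))
  ch$vbn <- batch_norm(ci)
  ch$fuse <- conv2d(ci, channels, kernel = 1)
  ch$gate <- act_module("sigmoid")
  new_module("strip_pool", children = ch, reduced = !is.null(internal))
}

#' @export
nn_fwd.strip_pool <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  if (d[1] < 1 || d[2] < 1) stop("input error: empty spatial dimensions")
  ch <- m$children
  vjps <- list()
  run <- function(name, z) {
    r <- nn_fwd(ch[[name]], z, training = training, grad = grad)
    if (grad) vjps[[name]] <<- r$vjp
    r$y
  }
  u <- x
  if (m$reduced) {
    u <- run("reduce", u); u <- run("reduce_bn", u); u <- run("reduce_act", u)
  }
  du_dim <- dim(u)
  sm <- strip_means(u)
  h2 <- run("hbn", run("hconv", sm$yh))
  v2 <- run("vbn", run("vconv", sm$yv))
  fused <- bcast_h(h2, d[2]) + bcast_v(v2, d[1])
  g <- run("gate", run("fuse", fused))
  y <- x * g
  vjp <- if (grad) function(dy) {
    dx <- dy * g
    dg <- dy * x
    dfused <- vjps$fuse(vjps$gate(dg))
    dyh <- vjps$hconv(vjps$hbn(reduce_h(dfused)))
    dyv <- vjps$vconv(vjps$vbn(reduce_v(dfused)))
    du <- bcast_h(dyh, du_dim[2]) / du_dim[2] + bcast_v(dyv, du_dim[1]) / du_dim[1]
    if (m$reduced) {
      dx + vjps$reduce(vjps$reduce_bn(vjps$reduce_act(du)))
    } else {
      dx + du
    }
  }
  list(y = y, vjp = vjp)
}

# --- attention -------------------------------------------------------------

#' Channel attention block
#'
#' Global max- and average-pooled channel vectors pass through one shared
#' two-layer perceptron (hidden width `C / ratio`, ReLU between layers, no
#' biases); the two outputs are summed and squashed by a sigmoid, yielding a
#' per-channel gate `M_c` of shape `(1, 1, C, N)` with values strictly in
#' (0, 1).
#'
#' @param channels channel count C.
#' @param ratio reduction ratio r; if `C >= r`, C must be divisible by r,
#'   otherwise the hidden width is `max(1, C %/% r)`.
#' @export
channel_attention_block <- function(channels, ratio = 16) {
  if (channels >= ratio && channels %% ratio != 0)
    stop("configuration error: channels must be divisible by the reduction ratio")
  hidden <- max(1L, channels %/% ratio)
  new_module("channel_attention",
             params = list(W1 = kaiming(c(hidden, channels), fan_in = channels),
                           W2 = kaiming(c(channels, hidden), fan_in = hidden)),
             channels = channels, hidden = hidden)
}

#' @export
nn_fwd.channel_attention <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  npix <- d[1] * d[2]
  M <- matrix(x, npix, d[3] * d[4])
  avg <- matrix(.colMeans(M, npix, ncol(M)), d[3], d[4])
  idx <- max.col(t(M), ties.method = "first")
  mx <- matrix(M[cbind(idx, seq_along(idx))], d[3], d[4])
  mlp <- function(v) {
    h <- pmax(m$params$W1 %*% v, 0)
    list(h = h, s = m$params$W2 %*% h)
  }
  pa <- mlp(avg); pm <- mlp(mx)
  s <- pa$s + pm$s
  mc <- 1 / (1 + exp(-s))
  pr_record(m, "channel_attention",
            macs = 2 * 2 * m$channels * m$hidden, out_shape = c(1, 1, d[3], d[4]))
  y <- array(mc, c(1, 1, d[3], d[4]))
  vjp <- if (grad) function(dy) {
    ds <- matrix(as.vector(dy), d[3], d[4]) * mc * (1 - mc)
    back <- function(p, v) {
      dh <- (t(m$params$W2) %*% ds) * (p$h > 0)
      m$grads$W2 <- m$grads$W2 + ds %*% t(p$h)
      m$grads$W1 <- m$grads$W1 + dh %*% t(v)
      t(m$params$W1) %*% dh
    }
    davg <- back(pa, avg)
    dmax <- back(pm, mx)
    dM <- matrix(rep(as.vector(davg) / npix, each = npix), npix, ncol(M))
    dM[cbind(idx, seq_along(idx))] <- dM[cbind(idx, seq_along(idx))] + as.vector(dmax)
    array(dM, d)
  }
  list(y = y, vjp = vjp)
}

#' Spatial attention block
#'
#' Channel-wise mean and max maps are concatenated (2 x H x W) and convolved
#' with a single odd kernel (default 7 x 7, padding 3) followed by a sigmoid,
#' yielding a spatial gate `M_s` of shape `(H, W, 1, N)` in (0, 1).
#'
#' @param kernel odd convolution kernel size.
#' @export
spatial_attention_block <- function(kernel = 7) {
  new_module("spatial_attention",
             children = list(conv = conv2d(2, 1, kernel = kernel),
                             gate = act_module("sigmoid")))
}

# channel-wise mean / max maps as (H, W, 1, N) plus argmax bookkeeping
channel_stats <- function(x) {
  d <- dim(x)
  Xp <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  mean_v <- .rowMeans(Xp, nrow(Xp), d[3])
  mx <- Xp[, 1]
  arg <- rep(1L, nrow(Xp))
  if (d[3] > 1) for (c in 2:d[3]) {
    sel <- Xp[, c] > mx
    mx[sel] <- Xp[sel, c]
    arg[sel] <- c
  }
  reshape <- function(v) array(array(v, c(d[1], d[2], d[4])), c(d[1], d[2], 1, d[4]))
  list(mean = reshape(mean_v), max = reshape(mx), arg = arg, d = d)
}

#' @export
nn_fwd.spatial_attention <- function(m, x, training = FALSE, grad = FALSE) {
  st <- channel_stats(x)
  d <- st$d
  cm <- array(0, c(d[1], d[2], 2, d[4]))
  cm[, , 1, ] <- st$mean
  cm[, , 2, ] <- st$max
  rc <- nn_fwd(m$children$conv, cm, training = training, grad = grad)
  rg <- nn_fwd(m$children$gate, rc$y, training = training, grad = grad)
  vjp <- if (grad) function(dy) {
    dcm <- rc$vjp(rg$vjp(dy))
    dmean <- as.vector(dcm[, , 1, , drop = FALSE]) / d[3]
    dmax <- as.vector(dcm[, , 2, , drop = FALSE])
    dXp <- matrix(rep(dmean, d[3]), length(dmean), d[3])
    dXp[cbind(seq_along(st$arg), st$arg)] <- dXp[cbind(seq_along(st$arg), st$arg)] + dmax
    aperm(array(dXp, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  }
  list(y = rg$y, vjp = vjp)
}

# broadcast multiply helpers for attention gates
mul_channel_gate <- function(x, mc) {
  d <- dim(x)
  x * array(rep(as.vector(mc), each = d[1] * d[2]), d)
}

mul_spatial_gate <- function(x, ms) {
  d <- dim(x)
  x * aperm(array(rep(as.vector(ms), d[3]), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

sum_to_channel_gate <- function(g) {          # (H,W,C,N) -> (1,1,C,N)
  d <- dim(g)
  array(.colSums(g, d[1] * d[2], d[3] * d[4]), c(1, 1, d[3], d[4]))
}

sum_to_spatial_gate <- function(g) {          # (H,W,C,N) -> (H,W,1,N)
  d <- dim(g)
  v <- .rowSums(matrix(aperm(g, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]),
                d[1] * d[2] * d[4], d[3])
  array(array(v, c(d[1], d[2], d[4])), c(d[1], d[2], 1, d[4]))
}

#' Convolutional block attention module (CBAM)
#'
#' Sequential channel-then-spatial attention: `G = M_c(F) * F`, then
#' `out = M_s(G) * G`.  Both gates lie strictly in (0, 1), so the output is
#' element-wise bounded by the input; shape is preserved.
#'
#' @param channels channel count.
#' @param ratio channel-attention reduction ratio.
#' @param spatial_kernel spatial-attention kernel size.
#' @export
cbam_block <- function(channels, ratio = 16, spatial_kernel = 7) {
  new_module("cbam",
             children = list(ca = channel_attention_block(channels, ratio),
                             sa = spatial_attention_block(spatial_kernel)))
}

#' @export
nn_fwd.cbam <- function(m, x, training = FALSE, grad = FALSE) {
  rca <- nn_fwd(m$children$ca, x, training = training, grad = grad)
  g <- mul_channel_gate(x, rca$y)
  pr_record(m, "cbam_gate", macs = 2 * prod(dim(x)[1:3]), out_shape = dim(x))
  rsa <- nn_fwd(m$children$sa, g, training = training, grad = grad)
  y <- mul_spatial_gate(g, rsa$y)
  vjp <- if (grad) function(dy) {
    dg <- mul_spatial_gate(dy, rsa$y)
    dms <- sum_to_spatial_gate(dy * g)
    dg <- dg + rsa$vjp(dms)
    dx <- mul_channel_gate(dg, rca$y)
    dmc <- sum_to_channel_gate(dg * x)
    dx + rca$vjp(dmc)
  }
  list(y = y, vjp = vjp)
}
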