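# ---------------------------------------------------------------------------
# Primitive layers: convolutions, batch normalization, activations, pooling,
# bilinear resampling, dropout, linear.  Each `nn_fwd` method returns
# list(y, vjp); `vjp(dy)` accumulates parameter gradients and returns dx.
# A profiling collector (see profile.R) records multiply-accumulate counts
# when active.
# ---------------------------------------------------------------------------

as2 <- function(v) if (length(v) == 1L) c(v, v) else v

#' Dense 2-d convolution layer
#'
#' @param in_ch,out_ch channel counts.
#' @param kernel kernel size, scalar or `c(kh, kw)`.
#' @param stride,dilation scalar or length-2.
#' @param pad `"same"` (stride-1 size-preserving, requires odd kernel) or
#'   explicit `c(ph, pw)`.
#' @param bias include an additive per-channel bias (used only where no
#'   normalization follows, e.g. the classifier).
#' @export
conv2d <- function(in_ch, out_ch, kernel = 1, stride = 1, dilation = 1,
                   pad = "same", bias = FALSE) {
  k <- as2(kernel); s <- as2(stride); d <- as2(dilation)
  if (identical(pad, "same")) {
    if (any(k %% 2 == 0)) stop("configuration error: 'same' padding requires odd kernels")
    pad <- d * (k - 1) %/% 2
  }
  params <- list(W = kaiming(c(k[1], k[2], in_ch, out_ch), fan_in = k[1] * k[2] * in_ch))
  if (bias) params$b <- numeric(out_ch)
  new_module("conv2d", params = params, stride = as.integer(s),
             pad = as.integer(as2(pad)), dil = as.integer(d),
             in_ch = in_ch, out_ch = out_ch, k = k)
}

#' @export
nn_fwd.conv2d <- function(m, x, training = FALSE, grad = FALSE) {
  y <- .conv2d_fwd(x, m$params$W, m$stride, m$pad, m$dil)
  if (!is.null(m$params$b)) y <- y + ch_expand(m$params$b, dim(y))
  d <- dim(y)
  pr_record(m, "conv2d",
            macs = prod(m$k) * m$in_ch * m$out_ch * d[1] * d[2],
            out_shape = d)
  vjp <- if (grad) function(dy) {
    if (!is.null(m$params$b)) m$grads$b <- m$grads$b + ch_sum(dy)
    r <- .conv2d_bwd(x, m$params$W, dy, m$stride, m$pad, m$dil)
    m$grads$W <- m$grads$W + r$dw
    r$dx
  }
  list(y = y, vjp = vjp)
}

#' Depthwise 2-d convolution layer (one kernel per channel)
#' @inheritParams conv2d
#' @param channels number of channels (preserved).
#' @export
dwconv2d <- function(channels, kernel = 3, stride = 1, dilation = 1, pad = "same") {
  k <- as2(kernel); s <- as2(stride); d <- as2(dilation)
  if (identical(pad, "same")) {
    if (any(k %% 2 == 0)) stop("configuration error: 'same' padding requires odd kernels")
    pad <- d * (k - 1) %/% 2
  }
  new_module("dwconv2d",
             params = list(W = kaiming(c(k[1], k[2], channels), fan_in = k[1] * k[2])),
             stride = as.integer(s), pad = as.integer(as2(pad)),
             dil = as.integer(d), channels = channels, k = k)
}

#' @export
nn_fwd.dwconv2d <- function(m, x, training = FALSE, grad = FALSE) {
  y <- .dwconv2d_fwd(x, m$params$W, m$stride, m$pad, m$dil)
  d <- dim(y)
  pr_record(m, "dwconv2d", macs = prod(m$k) * m$channels * d[1] * d[2],
            out_shape = d)
  vjp <- if (grad) function(dy) {
    r <- .dwconv2d_bwd(x, m$params$W, dy, m$stride, m$pad, m$dil)
    m$grads$W <- m$grads$W + r$dw
    r$dx
  }
  list(y = y, vjp = vjp)
}

#' Batch normalization layer
#'
#' Per-channel normalization with learnable scale/shift; epsilon 1e-5,
#' running-statistic momentum 0.1.  In inference mode the running estimates
#' are used; a freshly initialized layer (mean 0, variance 1) is an
#' (epsilon-close) identity in inference mode.
#' @param channels channel count.
#' @export
batch_norm <- function(channels, eps = 1e-5, momentum = 0.1) {
  m <- new_module("batch_norm",
                  params = list(gamma = rep(1, channels), beta = numeric(channels)),
                  eps = eps, momentum = momentum, channels = channels)
  m$run_mean <- numeric(channels)
  m$run_var <- rep(1, channels)
  m$decay_exempt <- TRUE
  m
}

#' @export
nn_fwd.batch_norm <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  C <- d[3]; npix <- d[1] * d[2] * d[4]
  if (training) {
    mu <- ch_sum(x) / npix
    xc <- x - ch_expand(mu, d)
    v <- ch_sum(xc * xc) / npix
    if (!isTRUE(m$frozen)) {
      m$run_mean <- (1 - m$momentum) * m$run_mean + m$momentum * mu
      m$run_var <- (1 - m$momentum) * m$run_var + m$momentum * v * npix / max(npix - 1, 1)
    }
  } else {
    mu <- m$run_mean; v <- m$run_var
    xc <- x - ch_expand(mu, d)
  }
  istd <- 1 / sqrt(v + m$eps)
  xhat <- xc * ch_expand(istd, d)
  y <- xhat * ch_expand(m$params$gamma, d) + ch_expand(m$params$beta, d)
  pr_record(m, "batch_norm", macs = prod(d[1:3]), out_shape = d)
  vjp <- if (grad) function(dy) {
    dgamma <- ch_sum(dy * xhat)
    dbeta <- ch_sum(dy)
    m$grads$gamma <- m$grads$gamma + dgamma
    m$grads$beta <- m$grads$beta + dbeta
    if (training) {
      (ch_expand(m$params$gamma * istd / npix, d)) *
        (npix * dy - ch_expand(dbeta, d) - xhat * ch_expand(dgamma, d))
    } else {
      dy * ch_expand(m$params$gamma * istd, d)
    }
  }
  list(y = y, vjp = vjp)
}

# --- activations -----------------------------------------------------------

act_module <- function(kind) new_module(kind)

#' @export
nn_fwd.relu <- function(m, x, training = FALSE, grad = FALSE) {
  y <- pmax(x, 0); dim(y) <- dim(x)
  pr_record(m, "relu", macs = 0, out_shape = dim(x))
  vjp <- if (grad) function(dy) dy * (x > 0)
  list(y = y, vjp = vjp)
}

#' @export
nn_fwd.relu6 <- function(m, x, training = FALSE, grad = FALSE) {
  y <- pmin(pmax(x, 0), 6); dim(y) <- dim(x)
  pr_record(m, "relu6", macs = 0, out_shape = dim(x))
  vjp <- if (grad) function(dy) dy * (x > 0 & x < 6)
  list(y = y, vjp = vjp)
}

#' @export
nn_fwd.sigmoid <- function(m, x, training = FALSE, grad = FALSE) {
  y <- 1 / (1 + exp(-x)); dim(y) <- dim(x)
  pr_record(m, "sigmoid", macs = 0, out_shape = dim(x))
  vjp <- if (grad) function(dy) dy * y * (1 - y)
  list(y = y, vjp = vjp)
}

#' @export
nn_fwd.dropout <- function(m, x, training = FALSE, grad = FALSE) {
  if (!training || m$p <= 0) {
    pr_record(m, "dropout", macs = 0, out_shape = dim(x))
    return(list(y = x, vjp = if (grad) identity))
  }
  keep <- array(runif(length(x)) >= m$p, dim(x))
  y <- x * keep / (1 - m$p)
  vjp <- if (grad) function(dy) dy * keep / (1 - m$p)
  list(y = y, vjp = vjp)
}

dropout_layer <- function(p = 0.1) new_module("dropout", p = p)

# --- pooling ---------------------------------------------------------------

# global average pool to (1, 1, C, N)
#' @export
nn_fwd.gap <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  v <- .colSums(x, d[1] * d[2], d[3] * d[4]) / (d[1] * d[2])
  y <- array(v, c(1, 1, d[3], d[4]))
  pr_record(m, "gap", macs = 0, out_shape = dim(y))
  vjp <- if (grad) function(dy) {
    array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
  }
  list(y = y, vjp = vjp)
}

# global max pool to (1, 1, C, N)
#' @export
nn_fwd.gmp <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  M <- matrix(x, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(M), ties.method = "first")
  v <- M[cbind(idx, seq_along(idx))]
  y <- array(v, c(1, 1, d[3], d[4]))
  pr_record(m, "gmp", macs = 0, out_shape = dim(y))
  vjp <- if (grad) function(dy) {
    dM <- matrix(0, d[1] * d[2], d[3] * d[4])
    dM[cbind(idx, seq_along(idx))] <- as.vector(dy)
    array(dM, d)
  }
  list(y = y, vjp = vjp)
}

# --- bilinear resampling ---------------------------------------------------

# Interpolation matrix (out x in) for align_corners = FALSE sampling.
interp_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  src <- pmin(pmax((seq_len(n_out) - 0.5) * scale - 0.5, 0), n_in - 1)
  lo <- floor(src); hi <- pmin(lo + 1, n_in - 1); fr <- src - lo
  for (i in seq_len(n_out)) {
    A[i, lo[i] + 1] <- A[i, lo[i] + 1] + (1 - fr[i])
    A[i, hi[i] + 1] <- A[i, hi[i] + 1] + fr[i]
  }
  A
}

# y[(Ho,Wo,C,N)] = Ah %*% x %*% t(Aw) applied channel/sample-wise
apply_interp <- function(x, Ah, Aw) {
  d <- dim(x)
  t1 <- Ah %*% matrix(x, d[1], d[2] * d[3] * d[4])        # (Ho, W*C*N)
  Ho <- nrow(Ah)
  t1 <- array(t1, c(Ho, d[2], d[3] * d[4]))
  t1 <- aperm(t1, c(2, 1, 3))                              # (W, Ho, C*N)
  t2 <- Aw %*% matrix(t1, d[2], Ho * d[3] * d[4])          # (Wo, Ho*C*N)
  Wo <- nrow(Aw)
  t2 <- array(t2, c(Wo, Ho, d[3] * d[4]))
  array(aperm(t2, c(2, 1, 3)), c(Ho, Wo, d[3], d[4]))
}

bilinear_layer <- function() new_module("bilinear", cache_key = NULL)

#' @export
nn_fwd.bilinear <- function(m, x, training = FALSE, grad = FALSE) {
  d <- dim(x)
  ho <- m$out_hw[1]; wo <- m$out_hw[2]
  key <- paste(d[1], d[2], ho, wo)
  if (!identical(m$cache_key, key)) {
    m$Ah <- interp_matrix(ho, d[1]); m$Aw <- interp_matrix(wo, d[2])
    m$cache_key <- key
  }
  y <- apply_interp(x, m$Ah, m$Aw)
  pr_record(m, "bilinear", macs = 4 * prod(dim(y)[1:3]), out_shape = dim(y))
  vjp <- if (grad) function(dy) apply_interp(dy, t(m$Ah), t(m$Aw))
  list(y = y, vjp = vjp)
}

# fixed-factor upsampling: out = factor * in, resolved at forward time
upsample_layer <- function(factor) {
  m <- bilinear_layer()
  class(m) <- c("upsample", class(m))
  m$factor <- factor
  m
}

#' @export
nn_fwd.upsample <- function(m, x, training = FALSE, grad = FALSE) {
  m$out_hw <- dim(x)[1:2] * m$factor
  NextMethod()
}

# resize to an explicit size
resize_layer <- function(out_hw) {
  m <- bilinear_layer()
  m$out_hw <- out_hw
  m
}

# --- linear ----------------------------------------------------------------

#' Fully connected layer on (features, N) matrices
#' @param in_f,out_f feature counts.
#' @param bias include bias.
#' @export
linear_layer <- function(in_f, out_f, bias = TRUE) {
  params <- list(W = kaiming(c(out_f, in_f), fan_in = in_f))
  if (bias) params$b <- numeric(out_f)
  new_module("linear", params = params, in_f = in_f, out_f = out_f)
}

#' @export
nn_fwd.linear <- function(m, x, training = FALSE, grad = FALSE) {
  xm <- if (is.matrix(x)) x else matrix(as.vector(x), m$in_f)
  y <- m$params$W %*% xm
  if (!is.null(m$params$b)) y <- y + m$params$b
  pr_record(m, "linear", macs = m$in_f * m$out_f, out_shape = dim(y))
  vjp <- if (grad) function(dy) {
    dy <- if (is.matrix(dy)) dy else matrix(as.vector(dy), m$out_f)
    m$grads$W <- m$grads$W + dy %*% t(xm)
    if (!is.null(m$params$b)) m$grads$b <- m$grads$b + .rowSums(dy, nrow(dy), ncol(dy))
    t(m$params$W) %*% dy
  }
  list(y = y, vjp = vjp)
}

# --- composition helpers ---------------------------------------------------

#' Sequential container
#' @param ... child modules, optionally named.
#' @export
nn_sequential <- function(...) {
  ch <- list(...)
  if (is.null(names(ch)) || any(names(ch) == "")) {
    names(ch) <- sprintf("l%02d", seq_along(ch))
  }
  new_module("sequential", children = ch)
}

#' @export
nn_fwd.sequential <- function(m, x, training = FALSE, grad = FALSE) {
  vjps <- if (grad) vector("list", length(m$children))
  for (i in seq_along(m$children)) {
    r <- nn_fwd(m$children[[i]], x, training = training, grad = grad)
    x <- r$y
    if (grad) vjps[[i]] <- r$vjp
  }
  vjp <- if (grad) function(dy) {
    for (i in rev(seq_along(vjps))) dy <- vjps[[i]](dy)
    dy
  }
  list(y = x, vjp = vjp)
}

# channel-wise concatenation of a list of (H, W, Ci, N) arrays
cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0
  for (x in xs) {
    cc <- dim(x)[3]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  out
}

split_channels <- function(dy, cs) {
  out <- vector("list", length(cs))
  at <- 0
  for (i in seq_along(cs)) {
    out[[i]] <- dy[, , at + seq_len(cs[i]), , drop = FALSE]
    at <- at + cs[i]
  }
  out
}
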