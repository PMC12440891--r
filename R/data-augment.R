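# ---------------------------------------------------------------------------
# The six-variant augmentation suite: original, horizontal flip, rotation,
# Gaussian blur, random crop, HSV jitter.  Geometric transforms apply one
# spatial map to image and mask alike; masks always use nearest-neighbor
# resampling (no new labels) and regions rotated in from outside the frame
# take the ignore label.  Blur and HSV leave the mask untouched.
# ---------------------------------------------------------------------------

# gather with bilinear interpolation at fractional source coords (reflected
# at the border); ys/xs are H x W matrices of 1-based coordinates
sample_bilinear <- function(img, ys, xs) {
  d <- dim(img)
  reflect <- function(v, n) {
    v <- abs(v - 1)
    period <- 2 * (n - 1)
    v <- v %% period
    pmin(v, period - v) + 1
  }
  ys <- reflect(ys, d[1]); xs <- reflect(xs, d[2])
  y0 <- pmin(floor(ys), d[1] - 1); x0 <- pmin(floor(xs), d[2] - 1)
  fy <- ys - y0; fx <- xs - x0
  out <- array(0, c(dim(ys), d[3]))
  for (ch in seq_len(d[3])) {
    base <- (ch - 1) * d[1] * d[2]
    g <- function(yy, xx) img[base + yy + (xx - 1) * d[1]]
    out[, , ch] <- (1 - fy) * (1 - fx) * g(y0, x0) + (1 - fy) * fx * g(y0, x0 + 1) +
      fy * (1 - fx) * g(y0 + 1, x0) + fy * fx * g(y0 + 1, x0 + 1)
  }
  out
}

# nearest-neighbor gather; out-of-range coords yield `fill`
sample_nearest <- function(m, ys, xs, fill = 255L) {
  d <- dim(m)
  yi <- round(ys); xi <- round(xs)
  ok <- yi >= 1 & yi <= d[1] & xi >= 1 & xi <= d[2]
  out <- matrix(fill, nrow(ys), ncol(ys))
  out[ok] <- m[yi[ok] + (xi[ok] - 1) * d[1]]
  out
}

rotate_sample <- function(s, angle_deg) {
  d <- dim(s$image)
  th <- angle_deg * pi / 180
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  jj <- matrix(rep(seq_len(d[2]), each = d[1]), d[1])
  ii <- matrix(rep(seq_len(d[1]), d[2]), d[1])
  # inverse map: source = R(-theta) applied to centered output coords
  ys <- cy + cos(th) * (ii - cy) - sin(th) * (jj - cx)
  xs <- cx + sin(th) * (ii - cy) + cos(th) * (jj - cx)
  img <- sample_bilinear(s$image, ys, xs)
  img <- array(as.integer(pmin(pmax(round(img), 0), 255)), d)
  msk <- sample_nearest(s$mask, ys, xs, fill = 255L)
  seg_sample(img, msk, paste0(s$id, "_rot"))
}

gaussian_blur_sample <- function(s, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(s$image)
  # reflect-pad then separable depthwise convolution (valid region)
  padidx <- function(n) c(rev(seq_len(r) + 1), seq_len(n), n - seq_len(r))
  x <- s$image[padidx(d[1]), padidx(d[2]), , drop = FALSE] / 255
  x <- array(x, c(dim(x), 1))
  kh <- array(rep(k, 3), c(2 * r + 1, 1, 3))
  kv <- array(rep(k, 3), c(1, 2 * r + 1, 3))
  x <- .dwconv2d_fwd(x, kh, c(1L, 1L), c(0L, 0L), c(1L, 1L))
  x <- .dwconv2d_fwd(x, kv, c(1L, 1L), c(0L, 0L), c(1L, 1L))
  img <- array(as.integer(pmin(pmax(round(x * 255), 0), 255)), d)
  seg_sample(img, s$mask, paste0(s$id, "_blur"))
}

crop_resize_sample <- function(s, area = 0.8) {
  d <- dim(s$image)
  side <- sqrt(area)
  ch <- max(1, round(d[1] * side)); cw <- max(1, round(d[2] * side))
  oy <- sample.int(d[1] - ch + 1, 1); ox <- sample.int(d[2] - cw + 1, 1)
  img <- s$image[oy:(oy + ch - 1), ox:(ox + cw - 1), , drop = FALSE]
  msk <- s$mask[oy:(oy + ch - 1), ox:(ox + cw - 1)]
  # resize back: bilinear for the image, nearest for the mask
  Ah <- interp_matrix(d[1], ch); Aw <- interp_matrix(d[2], cw)
  x <- apply_interp(array(img / 255, c(ch, cw, 3, 1)), Ah, Aw)
  img2 <- array(as.integer(pmin(pmax(round(x * 255), 0), 255)), d)
  ys <- matrix(rep((seq_len(d[1]) - 0.5) * ch / d[1] + 0.5, d[2]), d[1])
  xs <- matrix(rep((seq_len(d[2]) - 0.5) * cw / d[2] + 0.5, each = d[1]), d[1])
  msk2 <- sample_nearest(msk, pmin(pmax(ys, 1), ch), pmin(pmax(xs, 1), cw))
  seg_sample(img2, msk2, paste0(s$id, "_crop"))
}

# numeric RGB<->HSV (h in [0,1))
rgb_to_hsv_num <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  dlt <- mx - mn
  h <- numeric(length(r))
  sel <- dlt > 0 & mx == r
  h[sel] <- ((g[sel] - b[sel]) / dlt[sel]) %% 6
  sel <- dlt > 0 & mx == g & mx != r
  h[sel] <- (b[sel] - r[sel]) / dlt[sel] + 2
  sel <- dlt > 0 & mx == b & mx != r & mx != g
  h[sel] <- (r[sel] - g[sel]) / dlt[sel] + 4
  list(h = h / 6, s = ifelse(mx > 0, dlt / mx, 0), v = mx)
}

hsv_to_rgb_num <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

hsv_jitter_sample <- function(s, dh, ds, dv) {
  d <- dim(s$image)
  r <- s$image[, , 1] / 255; g <- s$image[, , 2] / 255; b <- s$image[, , 3] / 255
  hsv <- rgb_to_hsv_num(r, g, b)
  rgb <- hsv_to_rgb_num(hsv$h + dh, pmin(pmax(hsv$s * ds, 0), 1),
                        pmin(pmax(hsv$v * dv, 0), 1))
  img <- array(as.integer(pmin(pmax(round(c(rgb$r, rgb$g, rgb$b) * 255), 0), 255)), d)
  seg_sample(img, s$mask, paste0(s$id, "_hsv"))
}

flip_sample <- function(s) {
  d <- dim(s$image)
  seg_sample(s$image[, d[2]:1, , drop = FALSE], s$mask[, d[2]:1],
             paste0(s$id, "_flip"))
}

#' Sixfold augmentation
#'
#' Emits, per input sample, the original plus exactly one variant per
#' operation — horizontal flip, rotation (uniform within +/-25 degrees),
#' Gaussian blur (sigma in \[1, 2\]), random crop to 80% area resized back,
#' and HSV jitter (hue +/-10 degrees, saturation/value +/-20%) — so 481
#' inputs become 2,886 outputs.  Deterministic given `seed`.
#'
#' @param samples list of [seg_sample()] objects.
#' @param seed integer seed.
#' @return list of `6 * length(samples)` samples.
#' @export
augment_sixfold <- function(samples, seed = 1) {
  with_seed(seed, {
    out <- vector("list", 6L * length(samples))
    k <- 0L
    for (s in samples) {
      out[[k + 1L]] <- s
      out[[k + 2L]] <- flip_sample(s)
      out[[k + 3L]] <- rotate_sample(s, runif(1, -25, 25))
      out[[k + 4L]] <- gaussian_blur_sample(s, runif(1, 1, 2))
      out[[k + 5L]] <- crop_resize_sample(s, area = 0.8)
      out[[k + 6L]] <- hsv_jitter_sample(s, runif(1, -10, 10) / 360,
                                         runif(1, 0.8, 1.2), runif(1, 0.8, 1.2))
      k <- k + 6L
    }
    out
  })
}
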