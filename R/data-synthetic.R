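# ---------------------------------------------------------------------------
# Seeded synthetic maize/weed field scenes.
#
# Each scene mimics the overhead field-imaging regime the package targets:
# a textured soil background, 1-3 maize plants rendered as 5-9 elongated
# leaves radiating from a stem center (label 1), 2-8 smaller weed rosettes
# (label 2), and multiplicative illumination plus color jitter.  Maize and
# weed foliage are both green but occupy different hue ranges (maize darker
# blue-green, weeds yellow-green), as the two canopies do in the field.
# Labels are exact by construction.  Leaves are rotated-ellipse polygons, a
# deliberately radial geometry.
# ---------------------------------------------------------------------------

# add a filled rotated ellipse to a label mask (in place value assignment)
ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  jj <- matrix(rep(seq_len(w), each = h), h)
  ii <- matrix(rep(seq_len(h), w), h)
  ct <- cos(theta); st <- sin(theta)
  u <- (ii - cy) * ct + (jj - cx) * st
  v <- -(ii - cy) * st + (jj - cx) * ct
  (u / a)^2 + (v / b)^2 <= 1
}

# smooth multiplicative field: coarse noise grid upsampled bilinearly
smooth_noise <- function(h, w, cells = 6, amp = 0.15) {
  g <- matrix(runif(cells * cells, -amp, amp), cells, cells)
  Ah <- interp_matrix(h, cells); Aw <- interp_matrix(w, cells)
  Ah %*% g %*% t(Aw)
}

draw_plant <- function(mask, cy, cx, n_leaves, leaf_len, leaf_width, label) {
  h <- nrow(mask); w <- ncol(mask)
  th0 <- runif(1, 0, 2 * pi)
  for (l in seq_len(n_leaves)) {
    th <- th0 + 2 * pi * (l - 1) / n_leaves + rnorm(1, 0, 0.15)
    len <- leaf_len * runif(1, 0.7, 1.15)
    wid <- leaf_width * runif(1, 0.75, 1.25)
    ecy <- cy + sin(th) * len / 2
    ecx <- cx + cos(th) * len / 2
    sel <- ellipse_mask(h, w, ecy, ecx, len / 2, wid, atan2(sin(th), cos(th)))
    mask[sel] <- label
  }
  mask
}

scene_once <- function(size, corn_scale) {
  h <- size; w <- size
  mask <- matrix(0L, h, w)
  # maize: 1-3 plants of radiating elongated leaves
  n_plants <- sample(1:3, 1)
  for (p in seq_len(n_plants)) {
    cy <- runif(1, 0.2 * h, 0.8 * h); cx <- runif(1, 0.2 * w, 0.8 * w)
    mask <- draw_plant(mask, cy, cx, n_leaves = sample(5:9, 1),
                       leaf_len = corn_scale * size * runif(1, 0.35, 0.5) / sqrt(n_plants),
                       leaf_width = corn_scale * size * runif(1, 0.03, 0.05),
                       label = 1L)
  }
  # weeds: small rosettes of 3-6 short leaves
  n_weeds <- sample(2:8, 1)
  for (p in seq_len(n_weeds)) {
    cy <- runif(1, 0.05 * h, 0.95 * h); cx <- runif(1, 0.05 * w, 0.95 * w)
    mask <- draw_plant(mask, cy, cx, n_leaves = sample(3:6, 1),
                       leaf_len = size * runif(1, 0.06, 0.12),
                       leaf_width = size * runif(1, 0.015, 0.03),
                       label = 2L)
  }
  mask
}

render_scene <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  npix <- h * w
  # soil: brown base with coarse and fine texture
  hch <- matrix(0.08 + 0.02 * runif(npix), h, w)     # hue
  sch <- matrix(runif(1, 0.45, 0.6), h, w)
  vch <- matrix(runif(1, 0.35, 0.5) + 0.06 * rnorm(npix), h, w)
  corn <- mask == 1L
  weed <- mask == 2L
  # maize: darker blue-green; weeds: lighter yellow-green
  hch[corn] <- runif(sum(corn), 0.33, 0.40)
  sch[corn] <- runif(sum(corn), 0.55, 0.75)
  vch[corn] <- runif(sum(corn), 0.35, 0.55)
  hch[weed] <- runif(sum(weed), 0.18, 0.26)
  sch[weed] <- runif(sum(weed), 0.5, 0.7)
  vch[weed] <- runif(sum(weed), 0.45, 0.65)
  # illumination gradient + smooth mottle
  grad <- outer(seq(-1, 1, length.out = h), seq(-1, 1, length.out = w),
                function(a, b) runif(1, -0.08, 0.08) * a + runif(1, -0.08, 0.08) * b)
  vch <- pmin(pmax(vch * (1 + grad + smooth_noise(h, w)), 0), 1)
  rgb <- hsv_to_rgb_num(hch, pmin(pmax(sch, 0), 1), vch)
  array(as.integer(pmin(pmax(round(c(rgb$r, rgb$g, rgb$b) * 255), 0), 255)),
        c(h, w, 3))
}

#' Generate synthetic maize/weed field scenes
#'
#' @param n number of scenes (>= 1).
#' @param size square scene side in pixels, divisible by 16.
#' @param seed integer seed; scenes are bit-reproducible given
#'   `(n, size, seed)`.
#' @param class_balance when `TRUE` every scene is redrawn until all three
#'   labels are present.
#' @param corn_frac_range admissible per-scene maize pixel fraction; scenes
#'   are rescaled/redrawn to land inside it.
#' @return list of [seg_sample()] objects.
#' @export
generate_synthetic_field <- function(n, size = 128, seed = 1,
                                     class_balance = TRUE,
                                     corn_frac_range = c(0.10, 0.40)) {
  if (n < 1) stop("n must be >= 1")
  if (size %% 16 != 0) stop("size must be divisible by 16")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      corn_scale <- 1
      for (try in 1:25) {
        mask <- scene_once(size, corn_scale)
        frac <- mean(mask == 1L)
        ok_frac <- frac >= corn_frac_range[1] && frac <= corn_frac_range[2]
        ok_bal <- !class_balance || all(c(0L, 1L, 2L) %in% mask)
        if (ok_frac && ok_bal) break
        target <- mean(corn_frac_range)
        corn_scale <- corn_scale * sqrt(target / max(frac, 1e-3))
        corn_scale <- min(max(corn_scale, 0.2), 4)
      }
      seg_sample(render_scene(mask), mask, sprintf("scene_%04d", i))
    })
  })
}
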