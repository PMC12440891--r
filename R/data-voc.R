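# ---------------------------------------------------------------------------
# Pascal-VOC-layout dataset I/O.
#
# Layout: <root>/JPEGImages/<id>.jpg, <root>/SegmentationClass/<id>.png,
# <root>/ImageSets/Segmentation/{train,val,trainval}.txt.
#
# Label masks are written as lossless 8-bit grayscale PNGs whose pixel value
# IS the label index (0 background, 1 corn, 2 weed, 255 ignore).  The reader
# also accepts RGB masks rendered with the 3-class color palette below
# (the rendering `cmd_predict` emits), mapping colors back to labels.
# ---------------------------------------------------------------------------

# class palette (RGB 0-255): background, corn, weed, ignore
voc_palette <- function() {
  rbind(background = c(0, 0, 0),
        corn = c(128, 0, 0),
        weed = c(0, 128, 0),
        ignore = c(224, 224, 192))
}

#' Construct a segmentation sample
#'
#' @param image integer array `(H, W, 3)` with values 0-255.
#' @param mask integer matrix `(H, W)` with labels 0 (background), 1 (corn),
#'   2 (weed) or 255 (ignore).
#' @param id sample name.
#' @export
seg_sample <- function(image, mask, id) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2]))
    stop("image and mask sizes differ for ", id)
  if (!all(mask %in% c(0L, 1L, 2L, 255L)))
    stop("mask labels outside {0, 1, 2, 255} for ", id)
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "seg_sample")
}

#' Write samples in Pascal VOC segmentation layout
#'
#' @param samples list of [seg_sample()] objects.
#' @param root output directory (created if needed).
#' @param split optional named list of id vectors (e.g.
#'   `list(train = ..., val = ...)`) written as ImageSets list files; a
#'   `trainval.txt` covering all samples is always written.
#' @export
write_voc_dataset <- function(samples, root, split = NULL) {
  jdir <- file.path(root, "JPEGImages")
  mdir <- file.path(root, "SegmentationClass")
  sdir <- file.path(root, "ImageSets", "Segmentation")
  for (d in c(jdir, mdir, sdir)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    jpeg::writeJPEG(s$image / 255, file.path(jdir, paste0(s$id, ".jpg")),
                    quality = 0.95)
    png::writePNG(s$mask / 255, file.path(mdir, paste0(s$id, ".png")))
  }
  ids <- vapply(samples, `[[`, character(1), "id")
  writeLines(ids, file.path(sdir, "trainval.txt"))
  for (nm in names(split)) {
    writeLines(split[[nm]], file.path(sdir, paste0(nm, ".txt")))
  }
  invisible(root)
}

read_mask_png <- function(path, id) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) {
    m <- round(px * 255)
  } else {
    pal <- voc_palette()
    code <- round(px[, , 1] * 255) * 65536 +
      round(px[, , 2] * 255) * 256 + round(px[, , 3] * 255)
    palcode <- pal[, 1] * 65536 + pal[, 2] * 256 + pal[, 3]
    m <- array(NA_integer_, dim(code))
    lab <- c(0L, 1L, 2L, 255L)
    for (k in seq_along(palcode)) m[code == palcode[k]] <- lab[k]
    if (anyNA(m))
      stop("format error: mask ", id, " contains colors outside the 3-class palette")
  }
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  if (!all(m %in% c(0L, 1L, 2L, 255L)))
    stop("format error: mask ", id, " is not a label-index mask")
  m
}

#' Read a Pascal-VOC-layout segmentation dataset
#'
#' @param root dataset directory (see [write_voc_dataset()]).
#' @param split name of an ImageSets list file to read (`"train"`, `"val"`,
#'   `"trainval"`); `NULL` reads every image present.
#' @return list of [seg_sample()] objects; pixels with palette index 255 map
#'   to the ignore label.
#' @export
read_voc_dataset <- function(root, split = NULL) {
  jdir <- file.path(root, "JPEGImages")
  mdir <- file.path(root, "SegmentationClass")
  ids <- if (is.null(split)) {
    sub("\\.jpg$", "", list.files(jdir, pattern = "\\.jpg$"))
  } else {
    f <- file.path(root, "ImageSets", "Segmentation", paste0(split, ".txt"))
    if (!file.exists(f)) stop("split list not found: ", f)
    readLines(f)
  }
  lapply(ids, function(id) {
    jp <- file.path(jdir, paste0(id, ".jpg"))
    mp <- file.path(mdir, paste0(id, ".png"))
    if (!file.exists(jp)) stop("missing image for basename '", id, "'")
    if (!file.exists(mp)) stop("missing mask for basename '", id, "'")
    img <- jpeg::readJPEG(jp)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    img <- array(as.integer(round(img * 255)), dim(img))
    seg_sample(img, read_mask_png(mp, id), id)
  })
}

#' Render a label mask with the 3-class color palette
#'
#' @param mask integer label matrix.
#' @return array `(H, W, 3)` in 0-1, suitable for `png::writePNG`.
#' @export
colorize_mask <- function(mask) {
  pal <- voc_palette() / 255
  lab <- c(0L, 1L, 2L, 255L)
  out <- array(0, c(dim(mask), 3))
  for (k in seq_along(lab)) {
    sel <- mask == lab[k]
    for (ch in 1:3) out[, , ch][sel] <- pal[k, ch]
  }
  out
}

#' Random train/validation split
#'
#' Disjoint cover of the input; the training share is
#' `floor(ratio * n + 0.5)` samples, membership drawn under `seed` without
#' disturbing the caller's RNG stream.
#'
#' @param samples list of samples (any list).
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return `list(train = ..., val = ...)`.
#' @export
split_dataset <- function(samples, ratio = 0.9, seed = 1) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  ntr <- floor(ratio * n + 0.5)
  idx <- with_seed(seed, sample.int(n))
  list(train = samples[sort(idx[seq_len(ntr)])],
       val = samples[sort(idx[-seq_len(ntr)])])
}
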