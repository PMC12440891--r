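make_tiny_samples <- function(n = 3, size = 32, seed = 5) {
  generate_synthetic_field(n, size = size, seed = seed)
}

test_that("VOC layout round-trips masks exactly", {
  root <- withr::local_tempdir()
  samples <- make_tiny_samples(3)
  write_voc_dataset(samples, root,
                    split = list(train = c("scene_0001", "scene_0002"),
                                 val = "scene_0003"))
  back <- read_voc_dataset(root)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, samples[[i]]$mask)
    expect_identical(dim(back[[i]]$image), dim(samples[[i]]$image))
  }
  tr <- read_voc_dataset(root, "train")
  expect_identical(vapply(tr, `[[`, "", "id"), c("scene_0001", "scene_0002"))

  # palette-rendered masks (the prediction format) read back to the same labels
  pm <- file.path(root, "SegmentationClass", "scene_0001.png")
  png::writePNG(colorize_mask(samples[[1]]$mask), pm)
  back2 <- read_voc_dataset(root, "train")
  expect_identical(back2[[1]]$mask, samples[[1]]$mask)

  # missing mask errors name the basename; off-palette colors are rejected
  file.remove(file.path(root, "SegmentationClass", "scene_0002.png"))
  expect_error(read_voc_dataset(root, "train"), "scene_0002")
  png::writePNG(array(runif(32 * 32 * 3), c(32, 32, 3)), pm)
  expect_error(read_voc_dataset(root, "train"), "format error")
})

test_that("ignore-labelled pixels are excluded from loss and mIoU", {
  mask <- matrix(c(0L, 1L, 255L, 1L), 2, 2)
  logits <- array(0, c(2, 2, 3, 1))
  logits[1, 1, 1, 1] <- 50; logits[2, 1, 2, 1] <- 50   # correct where scored
  logits[1, 2, 3, 1] <- 50                             # "wrong" on ignored pixel
  logits[2, 2, 1, 1] <- 50                             # wrong on a scored pixel
  # three scored pixels, one of them fully wrong with a 50-logit margin
  expect_equal(cross_entropy(logits, mask), 50 / 3, tolerance = 1e-3)
  cm <- accumulate_confusion(new_confusion(3),
                             dscseg:::logits_to_labels(logits), array(mask, c(2, 2, 1)))
  expect_identical(sum(cm), 3)                          # ignored pixel not scored
  expect_identical(cm[2, 1], 1)                         # the one true error
})

test_that("sixfold augmentation emits six aligned variants per input", {
  samples <- make_tiny_samples(2)
  aug <- augment_sixfold(samples, seed = 9)
  expect_length(aug, 12)
  aug481 <- augment_sixfold(samples[1], seed = 9)
  expect_length(aug481, 6)

  # determinism
  aug2 <- augment_sixfold(samples, seed = 9)
  expect_identical(aug, aug2)
  expect_false(identical(augment_sixfold(samples, seed = 10)[[3]]$image,
                         aug[[3]]$image))

  # flip commutes with the mask; photometric ops leave the mask untouched
  s <- samples[[1]]
  expect_identical(aug[[2]]$mask, s$mask[, ncol(s$mask):1])
  expect_identical(aug[[2]]$image[, dim(s$image)[2]:1, ], s$image)
  expect_identical(aug[[4]]$mask, s$mask)   # blur
  expect_identical(aug[[6]]$mask, s$mask)   # hsv
  # geometric ops preserve the label set (ignore allowed for rotation border)
  for (k in c(3, 5)) expect_true(all(aug[[k]]$mask %in% c(0L, 1L, 2L, 255L)))
  expect_true(all(aug[[5]]$mask %in% c(0L, 1L, 2L)))
})

test_that("train/validation split follows the rounding rule and seed", {
  sp <- split_dataset(as.list(1:2886), ratio = 0.9, seed = 4)
  expect_length(sp$train, 2597)
  expect_length(sp$val, 289)
  sp10 <- split_dataset(as.list(1:10), ratio = 0.9, seed = 4)
  expect_length(sp10$train, 9)
  expect_length(sp10$val, 1)
  expect_identical(split_dataset(as.list(1:50), seed = 7),
                   split_dataset(as.list(1:50), seed = 7))
  expect_length(intersect(unlist(sp10$train), unlist(sp10$val)), 0)
  expect_error(split_dataset(list(1), 0.9, 1), "at least 2")
})

test_that("synthetic scenes are reproducible, labelled and in the corn-fraction band", {
  a <- generate_synthetic_field(2, size = 64, seed = 3)
  b <- generate_synthetic_field(2, size = 64, seed = 3)
  expect_identical(a, b)                                 # bit-identical
  expect_false(identical(a[[1]]$image,
                         generate_synthetic_field(1, size = 64, seed = 8)[[1]]$image))
  expect_error(generate_synthetic_field(1, size = 100), "divisible")

  scenes <- generate_synthetic_field(50, size = 64, seed = 12)
  fracs <- vapply(scenes, function(s) mean(s$mask == 1L), numeric(1))
  expect_true(all(fracs >= 0.10 & fracs <= 0.40))
  for (s in scenes) expect_true(all(c(0L, 1L, 2L) %in% s$mask))
})
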