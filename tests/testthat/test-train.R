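test_that("learning-rate schedule hits the published endpoints", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 0.007)
  expect_equal(lr_at_epoch(cfg, 299), 7e-5)
  # monotone non-increasing over the run
  lrs <- vapply(0:299, lr_at_epoch, numeric(1), cfg = cfg)
  expect_true(all(diff(lrs) <= 1e-12))
  pcfg <- train_config(lr_schedule = "poly")
  expect_equal(lr_at_epoch(pcfg, 0), 0.007)
  expect_equal(lr_at_epoch(pcfg, 299), 7e-5)
  expect_error(train_config(epochs_frozen = 301), "epochs_frozen")
})

test_that("frozen phase leaves backbone weights untouched, unfreezing updates them", {
  set.seed(61)
  scenes <- generate_synthetic_field(2, size = 32, seed = 61)
  model <- assemble_model(model_config(), seed = 61)
  w0 <- nn_parameters(model$children$backbone)
  cfg <- train_config(epochs_total = 2, epochs_frozen = 1, batch_frozen = 2,
                      batch_unfrozen = 2, eval_interval_epochs = 10, seed = 61)
  res <- train_model(model, scenes, cfg = cfg)
  expect_identical(res$history$phase, c("frozen", "unfrozen"))
  expect_false(identical(nn_parameters(model$children$backbone), w0))

  # a fully frozen run: backbone identical before and after
  model2 <- assemble_model(model_config(), seed = 61)
  w2 <- nn_parameters(model2$children$backbone)
  cfg2 <- train_config(epochs_total = 1, epochs_frozen = 1, batch_frozen = 2,
                       batch_unfrozen = 2, eval_interval_epochs = 10, seed = 61)
  expect_error(train_model(model2, list(), cfg = cfg2), "empty")
  train_model(model2, scenes, cfg = cfg2)
  expect_identical(nn_parameters(model2$children$backbone), w2)
})

test_that("seeded runs are bitwise reproducible and logged", {
  scenes <- generate_synthetic_field(2, size = 32, seed = 62)
  run <- function() {
    model <- assemble_model(model_config(), seed = 62)
    train_model(model, scenes,
                cfg = train_config(epochs_total = 2, epochs_frozen = 0,
                                   batch_frozen = 2, batch_unfrozen = 2,
                                   eval_interval_epochs = 2, seed = 62))
  }
  h1 <- run()$history
  h2 <- run()$history
  expect_equal(h1$train_loss, h2$train_loss, tolerance = 1e-6)
  expect_equal(h1$val_miou, h2$val_miou, tolerance = 1e-6)
  expect_named(h1, c("epoch", "phase", "lr", "train_loss", "val_miou"))
  expect_false(is.na(h1$val_miou[2]))
})

test_that("resuming from a later start epoch continues the epoch numbering", {
  scenes <- generate_synthetic_field(2, size = 32, seed = 64)
  model <- assemble_model(model_config(), seed = 64)
  cfg <- train_config(epochs_total = 3, epochs_frozen = 0, batch_frozen = 2,
                      batch_unfrozen = 2, eval_interval_epochs = 5, seed = 64)
  r1 <- train_model(model, scenes, cfg = cfg)
  expect_identical(r1$history$epoch, 0:2)
  r2 <- train_model(model, scenes, cfg = cfg, start_epoch = 2L)
  expect_identical(r2$history$epoch, 2L)
  expect_equal(r2$history$lr, lr_at_epoch(cfg, 2))
})

test_that("history, checkpoints and resolved outputs land in the run directory", {
  root <- withr::local_tempdir()
  scenes <- generate_synthetic_field(2, size = 32, seed = 63)
  model <- assemble_model(model_config(), seed = 63)
  res <- train_model(model, scenes,
                     cfg = train_config(epochs_total = 2, epochs_frozen = 0,
                                        batch_frozen = 2, batch_unfrozen = 2,
                                        eval_interval_epochs = 1, seed = 63),
                     out_dir = root)
  expect_true(file.exists(file.path(root, "history.csv")))
  expect_true(file.exists(file.path(root, "best.rds")))
  expect_true(file.exists(file.path(root, "epoch_002.rds")))
  # state dictionaries restore bitwise into a differently initialized model
  expect_gte(res$best_miou, 0)
  model2 <- assemble_model(model_config(), seed = 99)
  nn_load_state(model2, nn_state_dict(model))
  x <- rand_arr(32, 32, 3, 1)
  expect_identical(nn_forward(model2, x), nn_forward(model, x))
})
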