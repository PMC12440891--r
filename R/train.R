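# ---------------------------------------------------------------------------
# Training loop: SGD with momentum and weight decay, cosine learning-rate
# decay between lr_max and lr_max * lr_min_fraction, a frozen-backbone phase
# with a larger batch followed by full fine-tuning with a smaller batch,
# periodic validation mIoU and checkpointing.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' Defaults reproduce the published schedule: initial learning rate 0.007
#' decaying to 1% of the maximum, weight decay 1e-4, SGD momentum 0.9,
#' 300 epochs with the backbone frozen for the first 100 (batch 8) and
#' unfrozen thereafter (batch 4), validation every 20 epochs.
#'
#' @param lr_max peak learning rate.
#' @param lr_min_fraction floor as a fraction of `lr_max`.
#' @param weight_decay L2 penalty (not applied to normalization parameters).
#' @param momentum SGD momentum.
#' @param epochs_total,epochs_frozen schedule lengths (frozen < total).
#' @param batch_frozen,batch_unfrozen batch sizes per phase.
#' @param eval_interval_epochs validation/checkpoint period.
#' @param lr_schedule `"cosine"` or `"poly"`.
#' @param seed integer seed controlling shuffling and dropout.
#' @export
train_config <- function(lr_max = 0.007, lr_min_fraction = 0.01,
                         weight_decay = 1e-4, momentum = 0.9,
                         epochs_total = 300, epochs_frozen = 100,
                         batch_frozen = 8, batch_unfrozen = 4,
                         eval_interval_epochs = 20,
                         lr_schedule = c("cosine", "poly"), seed = 1) {
  if (epochs_frozen > epochs_total)
    stop("configuration error: epochs_frozen must be <= epochs_total")
  if (batch_frozen < 1 || batch_unfrozen < 1)
    stop("configuration error: batch sizes must be >= 1")
  structure(list(lr_max = lr_max, lr_min_fraction = lr_min_fraction,
                 weight_decay = weight_decay, momentum = momentum,
                 epochs_total = epochs_total, epochs_frozen = epochs_frozen,
                 batch_frozen = batch_frozen, batch_unfrozen = batch_unfrozen,
                 eval_interval_epochs = eval_interval_epochs,
                 lr_schedule = match.arg(lr_schedule), seed = seed),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Cosine (default) or power-0.9 polynomial decay from `lr_max` at epoch 0
#' to `lr_max * lr_min_fraction` at the final epoch.
#'
#' @param cfg a [train_config()].
#' @param epoch 0-based epoch index.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  lr_min <- cfg$lr_max * cfg$lr_min_fraction
  if (cfg$epochs_total <= 1) return(cfg$lr_max)
  p <- epoch / (cfg$epochs_total - 1)
  if (cfg$lr_schedule == "cosine") {
    lr_min + (cfg$lr_max - lr_min) * 0.5 * (1 + cos(pi * p))
  } else {
    lr_min + (cfg$lr_max - lr_min) * (1 - p)^0.9
  }
}

# stack samples into a normalized input batch and a label array
samples_to_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(d[1], d[2], 3, n))
  msk <- array(0L, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    x[, , , i] <- (samples[[i]]$image / 255 - 0.5) / 0.5
    msk[, , i] <- samples[[i]]$mask
  }
  list(x = x, mask = msk)
}

# argmax over the class dimension of (H, W, M, N) logits -> (H, W, N) labels
logits_to_labels <- function(logits) {
  d <- dim(logits)
  L <- matrix(aperm(logits, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  array(max.col(L, ties.method = "first") - 1L, c(d[1], d[2], d[4]))
}

#' Evaluate a model on a set of samples
#'
#' @param model assembled model.
#' @param samples list of [seg_sample()] objects (uniform size).
#' @param batch_size evaluation batch size.
#' @param n_classes number of classes.
#' @return list with `confusion`, `class_iou` and `miou` (percent).
#' @export
evaluate_model <- function(model, samples, batch_size = 4, n_classes = 3) {
  cm <- new_confusion(n_classes)
  idx <- seq_along(samples)
  for (chunk in split(idx, ceiling(idx / batch_size))) {
    b <- samples_to_batch(samples[chunk])
    logits <- nn_fwd(model, b$x, training = FALSE, grad = FALSE)$y
    cm <- accumulate_confusion(cm, logits_to_labels(logits), b$mask)
  }
  list(confusion = cm, class_iou = class_iou(cm), miou = miou(cm))
}

#' Predict a label mask for one image
#'
#' @param model assembled model.
#' @param image integer array `(H, W, 3)` 0-255, sides divisible by 16.
#' @return integer label matrix `(H, W)`.
#' @export
predict_mask <- function(model, image) {
  x <- array((image / 255 - 0.5) / 0.5, c(dim(image), 1))
  logits <- nn_fwd(model, x, training = FALSE, grad = FALSE)$y
  logits_to_labels(logits)[, , 1]
}

#' Train a segmentation model
#'
#' SGD with momentum and weight decay under the freeze/unfreeze schedule of
#' `cfg`: the backbone receives no updates (and its normalization statistics
#' are held) for the first `epochs_frozen` epochs at `batch_frozen`, then is
#' unfrozen and training continues at `batch_unfrozen`.  The learning rate
#' follows `lr_at_epoch()`.  Validation mIoU and a checkpoint are produced
#' every `eval_interval_epochs` epochs and at the end.  Fully seeded and
#' reproducible.
#'
#' @param model assembled model (see [assemble_model()]).
#' @param train_set,val_set lists of [seg_sample()]; `val_set = NULL`
#'   evaluates on the training set.
#' @param cfg a [train_config()].
#' @param out_dir optional run directory for history CSV and checkpoints.
#' @param target_miou optional early-stop: training halts once a validation
#'   pass reaches this mIoU (percent).
#' @param start_epoch 0-based epoch to resume from (epoch numbering, learning
#'   rate and freeze phase continue as if the earlier epochs had just run;
#'   load the checkpoint state into `model` first).
#' @param verbose print per-epoch progress.
#' @return list with `history` (data frame), `best_miou`, `best_state`.
#' @export
train_model <- function(model, train_set, val_set = NULL, cfg = train_config(),
                        out_dir = NULL, target_miou = NULL, start_epoch = 0L,
                        verbose = FALSE) {
  if (length(train_set) == 0) stop("empty training set")
  eval_set <- if (is.null(val_set) || length(val_set) == 0) train_set else val_set
  n_classes <- model$cfg$num_classes %||% 3
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opt_state <- new.env(parent = emptyenv())
  history <- NULL
  best <- list(miou = -Inf, state = NULL)
  with_seed(cfg$seed, {
    frozen_now <- NA
    epochs <- seq.int(start_epoch, cfg$epochs_total - 1L)
    for (epoch in epochs) {
      frozen <- epoch < cfg$epochs_frozen
      if (!identical(frozen, frozen_now)) {
        if (!is.null(model$children$backbone))
          set_frozen(model$children$backbone, frozen)
        frozen_now <- frozen
      }
      lr <- lr_at_epoch(cfg, epoch)
      bs <- if (frozen) cfg$batch_frozen else cfg$batch_unfrozen
      ord <- sample.int(length(train_set))
      losses <- c()
      for (chunk in split(ord, ceiling(seq_along(ord) / bs))) {
        b <- samples_to_batch(train_set[chunk])
        nn_zero_grad(model)
        r <- nn_fwd(model, b$x, training = TRUE, grad = TRUE)
        l <- ce_loss(r$y, b$mask)
        r$vjp(l$grad)
        sgd_step(model, lr = lr, momentum = cfg$momentum,
                 weight_decay = cfg$weight_decay, state = opt_state)
        losses <- c(losses, l$loss)
      }
      val_miou <- NA_real_
      do_eval <- (epoch + 1) %% cfg$eval_interval_epochs == 0 ||
        epoch == cfg$epochs_total - 1
      if (do_eval) {
        ev <- evaluate_model(model, eval_set, batch_size = bs,
                             n_classes = n_classes)
        val_miou <- ev$miou
        if (val_miou > best$miou) {
          best <- list(miou = val_miou, state = nn_state_dict(model))
          if (!is.null(out_dir))
            saveRDS(best$state, file.path(out_dir, "best.rds"))
        }
        if (!is.null(out_dir))
          saveRDS(nn_state_dict(model),
                  file.path(out_dir, sprintf("epoch_%03d.rds", epoch + 1)))
      }
      history <- rbind(history, data.frame(
        epoch = epoch, phase = if (frozen) "frozen" else "unfrozen",
        lr = lr, train_loss = mean(losses), val_miou = val_miou))
      if (verbose)
        message(sprintf("epoch %3d [%s] lr %.5f loss %.4f miou %s",
                        epoch, if (frozen) "frozen" else "unfrozen", lr,
                        mean(losses),
                        if (is.na(val_miou)) "-" else sprintf("%.2f", val_miou)))
      if (!is.null(target_miou) && !is.na(val_miou) && val_miou >= target_miou)
        break
    }
  })
  if (!is.null(out_dir))
    utils::write.csv(history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  list(history = history, best_miou = best$miou, best_state = best$state)
}
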