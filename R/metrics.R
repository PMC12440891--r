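# ---------------------------------------------------------------------------
# Loss and evaluation metrics: pixel cross-entropy with an ignore label,
# confusion-matrix accumulation and mean intersection-over-union.
# ---------------------------------------------------------------------------

#' Pixel-wise softmax cross-entropy
#'
#' Mean over scored pixels of the negative log probability of the true
#' class; pixels carrying `ignore_label` are excluded from both the sum and
#' the pixel count.  Equals `log(M)` under a uniform M-class prediction.
#'
#' @param logits array `(H, W, M, N)` of unnormalized class scores (a 3-d
#'   array is treated as one sample).
#' @param mask integer array `(H, W, N)` (or matrix) of true labels in
#'   `0..M-1` or `ignore_label`.
#' @param ignore_label label excluded from scoring (default 255).
#' @return scalar loss; if every pixel is ignored, 0 with a warning.
#' @export
cross_entropy <- function(logits, mask, ignore_label = 255L) {
  ce_loss(logits, mask, ignore_label, grad = FALSE)$loss
}

ce_loss <- function(logits, mask, ignore_label = 255L, grad = TRUE) {
  if (length(dim(logits)) == 3L) dim(logits) <- c(dim(logits), 1L)
  d <- dim(logits)
  M <- d[3]
  lab <- as.integer(mask)
  if (length(lab) != d[1] * d[2] * d[4])
    stop("mask size does not match logits")
  bad <- lab != ignore_label & (lab < 0L | lab >= M)
  if (any(bad)) stop("mask contains labels outside 0..", M - 1)
  # (pixel, class) matrix in (H, W, N) pixel order
  L <- matrix(aperm(logits, c(1, 2, 4, 3)), d[1] * d[2] * d[4], M)
  mx <- L[, 1]
  if (M > 1) for (ci in 2:M) mx <- pmax(mx, L[, ci]) # stabilize
  Ls <- L - mx
  Z <- rowSums(exp(Ls))
  logp <- Ls - log(Z)
  scored <- which(lab != ignore_label)
  n <- length(scored)
  if (n == 0L) {
    warning("all pixels carry the ignore label; loss defined as 0")
    return(list(loss = 0, grad = array(0, d), n = 0L))
  }
  picked <- cbind(scored, lab[scored] + 1L)
  loss <- -sum(logp[picked]) / n
  g <- NULL
  if (grad) {
    P <- exp(logp)
    G <- matrix(0, nrow(L), M)
    G[scored, ] <- P[scored, ] / n
    G[picked] <- G[picked] - 1 / n
    g <- aperm(array(G, c(d[1], d[2], d[4], M)), c(1, 2, 4, 3))
  }
  list(loss = loss, grad = g, n = n)
}

#' Create an empty confusion matrix
#'
#' Rows index the true class, columns the predicted class.
#'
#' @param n_classes number of classes.
#' @export
new_confusion <- function(n_classes) {
  structure(matrix(0, n_classes, n_classes,
                   dimnames = list(truth = NULL, prediction = NULL)),
            class = c("confusion_matrix", "matrix"))
}

#' Accumulate (truth, prediction) pixel counts
#'
#' @param cm a [new_confusion()] matrix.
#' @param pred_mask,true_mask integer label arrays of identical shape.
#' @param ignore_label pixels with this true label are skipped.
#' @return the updated confusion matrix.
#' @export
accumulate_confusion <- function(cm, pred_mask, true_mask, ignore_label = 255L) {
  n <- nrow(cm)
  p <- as.integer(pred_mask)
  t <- as.integer(true_mask)
  if (length(p) != length(t)) stop("mask shapes differ")
  keep <- t != ignore_label
  p <- p[keep]; t <- t[keep]
  if (any(p < 0L | p >= n) || any(t < 0L | t >= n))
    stop("label outside 0..", n - 1)
  counts <- tabulate(t * n + p + 1L, nbins = n * n)
  cm + matrix(counts, n, n, byrow = TRUE)
}

#' Per-class intersection-over-union
#' @param cm confusion matrix (rows truth, columns prediction).
#' @return numeric vector of IoU values in \[0, 1\]; `NaN` for classes with
#'   an empty union.
#' @export
class_iou <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tp / (tp + fp + fn)
}

#' Mean intersection-over-union, as a percentage
#'
#' Mean over classes of `TP / (TP + FP + FN)`, times 100.  Classes absent
#' from both prediction and truth (empty union) are excluded from the mean
#' by default, or scored as IoU 1 with `empty = "one"`.
#'
#' @param cm confusion matrix.
#' @param empty handling of empty-union classes: `"exclude"` or `"one"`.
#' @export
miou <- function(cm, empty = c("exclude", "one")) {
  empty <- match.arg(empty)
  iou <- class_iou(cm)
  if (empty == "one") iou[is.nan(iou)] <- 1
  100 * mean(iou, na.rm = TRUE)
}
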