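# ---------------------------------------------------------------------------
# Parameter / multiply-accumulate profiler.
#
# Counting convention (documented in the methods vignette and in every
# report): MACs accumulate one multiply-accumulate per kernel tap of every
# convolution (dense: kh*kw*Cin*Cout*Ho*Wo; depthwise: kh*kw*C*Ho*Wo), per
# weight of every linear layer, one per output element of a normalization
# layer (scale-and-shift), four per output element of a bilinear resampler
# (four weighted taps), and the attention-gate products.  Activations and
# additions are not counted.  FLOPs are reported under both literature
# conventions, 1x and 2x MACs; `gflops` is the 2x value, which reproduces
# the standard published complexity of the reference MobileNetV2 backbone.
# ---------------------------------------------------------------------------

.pr <- new.env(parent = emptyenv())
.pr$active <- FALSE

pr_begin <- function() {
  .pr$active <- TRUE
  .pr$rows <- list()
  .pr$scope <- character()
}

pr_end <- function() {
  .pr$active <- FALSE
  rows <- .pr$rows
  .pr$rows <- list()
  rows
}

pr_push <- function(name) {
  if (.pr$active) .pr$scope <- c(.pr$scope, name)
  invisible(NULL)
}

pr_pop <- function() {
  if (.pr$active) .pr$scope <- .pr$scope[-length(.pr$scope)]
  invisible(NULL)
}

pr_record <- function(m, type, macs, out_shape) {
  if (!.pr$active) return(invisible(NULL))
  .pr$rows[[length(.pr$rows) + 1L]] <- list(
    scope = paste(.pr$scope, collapse = "."),
    type = type,
    macs = macs,
    params = sum(vapply(m$params, length, numeric(1))),
    out_shape = paste(out_shape[1:3], collapse = "x"))
  invisible(NULL)
}

#' Profile a model: trainable parameters and forward-pass cost
#'
#' Runs one inference-mode forward pass of `model` on a zero input of the
#' given size and accumulates multiply-accumulate counts layer by layer
#' under the convention described in the package vignette.  The parameter
#' count is exact and independent of the input size; MACs scale with the
#' input area.
#'
#' @param model a module (typically from [assemble_model()] or
#'   [mobilenet_v2()]).
#' @param input_hw input spatial size, default `c(512, 512)`.
#' @param in_ch input channels (3 for RGB).
#' @return a `profile_report`: list with `params`, `macs`, `flops`
#'   (`= 2 * macs`), `gmacs`, `gflops`, an informational `fps` (this host,
#'   this run — never asserted), `input_hw` and a per-layer data frame
#'   `layers`.
#' @export
profile_model <- function(model, input_hw = c(512, 512), in_ch = 3) {
  x <- array(0, c(input_hw[1], input_hw[2], in_ch, 1))
  pr_begin()
  on.exit(if (.pr$active) pr_end(), add = TRUE)
  t0 <- Sys.time()
  nn_fwd(model, x, training = FALSE, grad = FALSE)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  rows <- pr_end()
  layers <- data.frame(
    scope = vapply(rows, `[[`, character(1), "scope"),
    type = vapply(rows, `[[`, character(1), "type"),
    out_shape = vapply(rows, `[[`, character(1), "out_shape"),
    params = vapply(rows, `[[`, numeric(1), "params"),
    macs = vapply(rows, `[[`, numeric(1), "macs"),
    stringsAsFactors = FALSE)
  macs <- sum(layers$macs)
  structure(list(params = nn_param_count(model),
                 macs = macs, flops = 2 * macs,
                 gmacs = macs / 1e9, gflops = 2 * macs / 1e9,
                 fps = 1 / elapsed,   # informational only: this host, this run
                 input_hw = input_hw, layers = layers),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("profile at %dx%d input\n", x$input_hw[1], x$input_hw[2]))
  cat(sprintf("  trainable parameters: %s (%.3f M)\n",
              format(x$params, big.mark = ","), x$params / 1e6))
  cat(sprintf("  MACs:  %.3f G (FLOPs: %.3f G at 1x MACs, %.3f G at 2x MACs)\n",
              x$gmacs, x$gmacs, x$gflops))
  invisible(x)
}

#' Profile a named model variant
#'
#' Convenience wrapper assembling an ablation variant (or the full model)
#' and profiling it.
#'
#' @param variant `"full"` or one of the ablation groups
#'   (`"group1"`..`"group4"`).
#' @param input_hw input size.
#' @param num_classes output classes.
#' @param seed initialization seed (counts are weight-independent; the seed
#'   only fixes the assembled instance).
#' @export
profile_variant <- function(variant = "full", input_hw = c(512, 512),
                            num_classes = 3, seed = 1) {
  cfg <- if (identical(variant, "full")) {
    model_config(num_classes)
  } else {
    make_ablation_variant(variant, num_classes)
  }
  model <- assemble_model(cfg, seed = seed)
  profile_model(model, input_hw = input_hw)
}
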