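#' @useDynLib dscseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
#' @importFrom utils write.csv
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network module system.
#
# A module is an environment carrying `params` (trainable arrays), `grads`
# (same shapes), optional non-trainable state (e.g. batch-norm running
# statistics) and, for composites, a named `children` list.  `nn_fwd()` is the
# S3 workhorse: it returns `list(y, vjp)` where `vjp(dy)` is the
# vector-Jacobian product (the backward pass).  Calling `vjp` accumulates
# parameter gradients into `grads` and returns the input gradient, so shared
# submodules (e.g. the shared perceptron of channel attention) sum their
# contributions naturally.
# ---------------------------------------------------------------------------

new_module <- function(cls, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  if (is.null(e$children)) e$children <- list()
  e$grads <- lapply(e$params, function(p) p * 0)
  e$frozen <- FALSE
  class(e) <- c(cls, "nn_module")
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a module forward
#'
#' Applies a neural building block (or a whole assembled model) to an input
#' activation array of shape `(H, W, C, N)`.
#'
#' @param module a module created by one of the block constructors.
#' @param x numeric array `(H, W, C, N)`; a 3-d array `(H, W, C)` is treated
#'   as a single-sample batch.
#' @param training logical; `TRUE` uses batch statistics in normalization
#'   layers (and updates their running estimates) and activates dropout.
#' @return the output activation array.
#' @export
nn_forward <- function(module, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  nn_fwd(module, x, training = training, grad = FALSE)$y
}

nn_fwd <- function(m, x, training = FALSE, grad = FALSE, ...) UseMethod("nn_fwd")

# --- module traversal ------------------------------------------------------

#' Flatten a module tree into its leaf modules
#'
#' @param module a module.
#' @return named list of leaf modules; names are dot-separated paths.
#' @export
nn_modules <- function(module) {
  out <- list()
  rec <- function(m, prefix) {
    if (length(m$children) == 0L) {
      out[[prefix]] <<- m
    } else {
      for (nm in names(m$children)) rec(m$children[[nm]], paste0(prefix, ".", nm))
    }
  }
  rec(module, "root")
  out
}

#' Named list of trainable parameter arrays
#' @param module a module.
#' @export
nn_parameters <- function(module) {
  leaves <- nn_modules(module)
  out <- list()
  for (nm in names(leaves)) {
    p <- leaves[[nm]]$params
    for (pn in names(p)) out[[paste0(nm, ".", pn)]] <- p[[pn]]
  }
  out
}

#' Count trainable parameters
#' @param module a module.
#' @return integer count of trainable weights (normalization running
#'   statistics are state, not parameters, and are excluded).
#' @export
nn_param_count <- function(module) {
  sum(vapply(nn_parameters(module), length, numeric(1)))
}

#' Extract or restore all weights and normalization state
#' @param module a module.
#' @export
nn_state_dict <- function(module) {
  leaves <- nn_modules(module)
  lapply(leaves, function(m) {
    s <- list(params = m$params)
    if (!is.null(m$run_mean)) s$run_mean <- m$run_mean
    if (!is.null(m$run_var)) s$run_var <- m$run_var
    s
  })
}

#' @rdname nn_state_dict
#' @param state a list previously returned by `nn_state_dict()`.
#' @export
nn_load_state <- function(module, state) {
  leaves <- nn_modules(module)
  if (!identical(sort(names(leaves)), sort(names(state))))
    stop("state dictionary does not match module structure")
  for (nm in names(leaves)) {
    m <- leaves[[nm]]
    for (pn in names(state[[nm]]$params)) {
      if (!identical(dim(m$params[[pn]]), dim(state[[nm]]$params[[pn]])))
        stop("shape mismatch for ", nm, ".", pn)
      m$params[[pn]] <- state[[nm]]$params[[pn]]
    }
    if (!is.null(state[[nm]]$run_mean)) m$run_mean <- state[[nm]]$run_mean
    if (!is.null(state[[nm]]$run_var)) m$run_var <- state[[nm]]$run_var
  }
  invisible(module)
}

#' Freeze or unfreeze a module subtree
#'
#' Frozen modules receive no gradient updates from the optimizer and their
#' normalization layers stop updating running statistics (the transfer-
#' learning freeze phase of the training schedule).
#'
#' @param module a module.
#' @param frozen logical flag.
#' @export
set_frozen <- function(module, frozen = TRUE) {
  for (m in nn_modules(module)) m$frozen <- frozen
  module$frozen <- frozen
  invisible(module)
}

nn_zero_grad <- function(module) {
  for (m in nn_modules(module)) {
    m$grads <- lapply(m$params, function(p) p * 0)
  }
  invisible(module)
}

# --- initialization helpers ------------------------------------------------

kaiming <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# --- broadcasting helpers --------------------------------------------------

# expand per-channel vector v (length C) over an (H, W, C, N) array
ch_expand <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), d[4]), d)
}

# per-channel sums / means of an (H, W, C, N) array -> length C
ch_sum <- function(x) {
  d <- dim(x)
  m <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(matrix(m, d[3], d[4]), d[3], d[4])
}

# --- SGD with momentum -----------------------------------------------------

sgd_step <- function(module, lr, momentum = 0.9, weight_decay = 0, state = NULL) {
  leaves <- nn_modules(module)
  if (is.null(state)) state <- new.env(parent = emptyenv())
  for (nm in names(leaves)) {
    m <- leaves[[nm]]
    if (isTRUE(m$frozen)) next
    for (pn in names(m$params)) {
      key <- paste0(nm, ".", pn)
      g <- m$grads[[pn]]
      if (weight_decay > 0 && !identical(m$decay_exempt, TRUE)) {
        g <- g + weight_decay * m$params[[pn]]
      }
      v <- state[[key]] %||% 0
      v <- momentum * v - lr * g
      state[[key]] <- v
      m$params[[pn]] <- m$params[[pn]] + v
    }
  }
  state
}

# --- deterministic RNG scope ----------------------------------------------

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
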