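# Feature importance evaluators (FIEs). Every FIE maps
# (model, example, target) to a length-n position-level attribution:
# feature-level (n x |alphabet|) values are collapsed to positions,
# because grammar annotations live at the position level.

new_position_attribution <- function(values, method, target,
                                     example_ref = NULL) {
  stopifnot(all(is.finite(values)))
  structure(list(values = as.numeric(values), method = method,
                 target = target, example_ref = example_ref),
            class = "gb_position_attribution")
}

#' @export
print.gb_position_attribution <- function(x, ...) {
  cat(sprintf("Position attribution (%s, target %s): n = %d, mass = %.4g\n",
              x$method, as.character(x$target), length(x$values),
              sum(abs(x$values))))
  invisible(x)
}

#' @export
length.gb_position_attribution <- function(x) length(x$values)

#' Collapse feature-level attributions to position level
#'
#' @param feature_attr An `n x |alphabet|` matrix of per-feature
#'   attribution values.
#' @param method `"sum"` (signed sum over channels, the default),
#'   `"abs_sum"` (sum of absolute values, used by saliency) or
#'   `"max"`.
#' @return Numeric vector of length `n`.
#' @export
collapse_to_positions <- function(feature_attr,
                                  method = c("sum", "abs_sum", "max")) {
  method <- match.arg(method)
  stopifnot(is.matrix(feature_attr), all(is.finite(feature_attr)))
  switch(method,
    sum = rowSums(feature_attr),
    abs_sum = rowSums(abs(feature_attr)),
    max = apply(feature_attr, 1, max))
}

single_example_matrix <- function(model, example) {
  X <- as_input_array(model, example)
  if (dim(X)[1] != 1) stopf("FIEs take a single example")
  X
}

grad_matrix <- function(model, X, target, rule = "backprop") {
  g <- model_gradient(model, X, target, rule = rule)
  matrix(g[1, , ], dim(g)[2], dim(g)[3])
}

#' Raw gradient attribution
#'
#' The most basic gradient FIE: the gradient of the target output
#' with respect to the input, collapsed to positions by signed sum
#' over channels.
#'
#' @param model A `gb_model`.
#' @param example One example: character sequence, one-hot `n x A`
#'   matrix, or `(1, n, A)` array.
#' @param target 1-based class/label index.
#' @param collapse Collapse rule (see [collapse_to_positions()]).
#' @return A `gb_position_attribution`.
#' @export
raw_gradient <- function(model, example, target, collapse = "sum") {
  X <- single_example_matrix(model, example)
  z <- collapse_to_positions(grad_matrix(model, X, target), collapse)
  new_position_attribution(z, "raw_gradient", target)
}

#' Saliency (absolute gradient) attribution
#'
#' Element-wise absolute value of the input gradient, collapsed by
#' summing absolute values; attributions are therefore nonnegative.
#'
#' @inheritParams raw_gradient
#' @return A `gb_position_attribution` with values `>= 0`.
#' @export
saliency <- function(model, example, target) {
  X <- single_example_matrix(model, example)
  z <- collapse_to_positions(abs(grad_matrix(model, X, target)), "abs_sum")
  new_position_attribution(z, "saliency", target)
}

#' Gradient-x-input attribution
#'
#' Input times gradient: for one-hot inputs only the observed symbol's
#' channel contributes, and all-zero padding positions get 0.
#'
#' @inheritParams raw_gradient
#' @return A `gb_position_attribution`.
#' @export
gradient_x_input <- function(model, example, target, collapse = "sum") {
  X <- single_example_matrix(model, example)
  xm <- matrix(X[1, , ], dim(X)[2], dim(X)[3])
  z <- collapse_to_positions(xm * grad_matrix(model, X, target), collapse)
  new_position_attribution(z, "gradient_x_input", target)
}

#' Integrated gradients attribution
#'
#' Averages `K` gradients along the straight path from the zero
#' baseline to the input (right-endpoint Riemann sum, scales
#' `k/K, k = 1..K`). By default the mean gradient is multiplied by
#' the input (`multiply_by_input = TRUE`), the completeness-satisfying
#' form whose per-position attributions sum to approximately
#' `f_y(x) - f_y(0)`; set `multiply_by_input = FALSE` for the bare
#' mean-gradient variant.
#'
#' @inheritParams raw_gradient
#' @param K Number of path steps (default 100).
#' @param multiply_by_input Multiply the averaged gradient by the
#'   input before collapsing.
#' @return A `gb_position_attribution`.
#' @export
integrated_gradients <- function(model, example, target, K = 100,
                                 multiply_by_input = TRUE,
                                 collapse = "sum") {
  K <- as.integer(K)
  if (is.na(K) || K < 1) stopf("K must be >= 1")
  X <- single_example_matrix(model, example)
  n <- dim(X)[2]; A <- dim(X)[3]
  path <- array(0, c(K, n, A))
  for (k in seq_len(K)) path[k, , ] <- (k / K) * X[1, , ]
  g <- model_gradient(model, path, rep(target, K))
  avg <- matrix(colMeans(matrix(g, K, n * A)), n, A)
  xm <- matrix(X[1, , ], n, A)
  z <- collapse_to_positions(if (multiply_by_input) xm * avg else avg,
                             collapse)
  new_position_attribution(z, "integrated_gradients", target)
}

#' Modified-backpropagation attributions
#'
#' Attribution methods that alter the ReLU backward rule:
#' guided backpropagation (pass only where the forward activation and
#' the incoming backward signal are both positive), deconvolution
#' (pass only where the incoming signal is positive) and DeepLIFT
#' (rescale rule with zero-baseline reference activations; the
#' returned attribution is multiplier times input delta). Only ReLU
#' nonlinearities are supported for these methods.
#'
#' @inheritParams raw_gradient
#' @param method `"guided_backprop"`, `"deconvolution"` or
#'   `"deeplift"`.
#' @return A `gb_position_attribution`.
#' @export
modified_backprop <- function(model, example, target,
                              method = c("guided_backprop", "deconvolution",
                                         "deeplift"),
                              collapse = "sum") {
  method <- match.arg(method)
  X <- single_example_matrix(model, example)
  rule <- switch(method, guided_backprop = "guided",
                 deconvolution = "deconv", deeplift = "deeplift")
  g <- grad_matrix(model, X, target, rule = rule)
  if (method == "deeplift") {
    xm <- matrix(X[1, , ], dim(X)[2], dim(X)[3])
    g <- g * xm   # multipliers times (x - x0), x0 = 0
  }
  z <- collapse_to_positions(g, collapse)
  new_position_attribution(z, method, target)
}

# ---- sufficient input subsets --------------------------------------------

mask_eval <- function(model, X, target, masks) {
  # masks: list of logical vectors (TRUE = position kept); batch-evaluate
  n <- dim(X)[2]
  B <- length(masks)
  Xb <- array(0, c(B, n, dim(X)[3]))
  for (b in seq_len(B)) {
    keep <- masks[[b]]
    Xb[b, keep, ] <- X[1, keep, ]
  }
  predict.gb_model(model, Xb)[, target]
}

#' Sufficient input subsets (SIS)
#'
#' Model-agnostic FIE: finds disjoint subsets of positions, each
#' sufficient on its own (all other positions masked with the
#' all-zero vector) to keep the target output above the threshold
#' `tau`. Follows the backward-selection procedure: starting from all
#' available positions, greedily mask the position whose removal
#' decreases `f_y` the least until `f_y <= tau`; then re-grow the
#' minimal retained set from the most-recently-masked positions until
#' `f_y > tau` — that set is one SIS. The SIS is removed from the
#' available positions and the procedure repeats until the remaining
#' positions no longer suffice. If `f_y(x) <= tau` for the full
#' example, the result is empty.
#'
#' @inheritParams raw_gradient
#' @param tau Probability threshold in (0, 1).
#' @return An object of class `gb_sis_result`: list with `subsets`
#'   (list of logical masks over positions, mutually disjoint),
#'   `threshold`, `final_prediction_per_subset` (the value of `f_y`
#'   with only that subset unmasked) and `n`.
#' @export
sufficient_input_subsets <- function(model, example, target, tau = 0.5) {
  if (model$output_activation %in% c("softmax", "sigmoid") &&
      (tau <= 0 || tau >= 1))
    stopf("tau must lie in (0, 1) for probability outputs")
  X <- single_example_matrix(model, example)
  n <- dim(X)[2]
  pad <- apply(matrix(X[1, , ], n, dim(X)[3]), 1, function(r) all(r == 0))
  available <- which(!pad)
  subsets <- list(); preds <- numeric(0)
  full <- mask_eval(model, X, target, list(seq_len(n) %in% available))
  if (full <= tau)
    return(structure(list(subsets = list(), threshold = tau,
                          final_prediction_per_subset = numeric(0), n = n),
                     class = "gb_sis_result"))
  repeat {
    if (length(available) == 0) break
    cur <- mask_eval(model, X, target, list(seq_len(n) %in% available))
    if (cur <= tau) break
    # backward selection: order positions by reverse removal order
    remaining <- available
    stack <- integer(0)
    while (length(remaining) > 0) {
      masks <- lapply(remaining, function(p)
        seq_len(n) %in% setdiff(remaining, p))
      vals <- mask_eval(model, X, target, masks)
      best <- which.max(vals)
      stack <- c(stack, remaining[best])
      remaining <- remaining[-best]
    }
    # re-grow the minimal sufficient set from the last-removed positions
    S <- integer(0)
    val <- -Inf
    while (val <= tau && length(stack) > 0) {
      S <- c(S, stack[length(stack)])
      stack <- stack[-length(stack)]
      val <- mask_eval(model, X, target, list(seq_len(n) %in% S))
    }
    if (val <= tau) break
    subsets[[length(subsets) + 1]] <- seq_len(n) %in% S
    preds <- c(preds, val)
    available <- setdiff(available, S)
  }
  structure(list(subsets = subsets, threshold = tau,
                 final_prediction_per_subset = preds, n = n),
            class = "gb_sis_result")
}

#' @export
print.gb_sis_result <- function(x, ...) {
  cat(sprintf("SIS result: %d subset(s) over %d positions, tau = %g\n",
              length(x$subsets), x$n, x$threshold))
  for (i in seq_along(x$subsets))
    cat(sprintf("  SIS %d: positions {%s}, f_y = %.4f\n", i,
                paste(which(x$subsets[[i]]), collapse = ", "),
                x$final_prediction_per_subset[i]))
  invisible(x)
}

#' Run one or more FIEs over a set of examples
#'
#' Convenience wrapper used by the evaluation module and the CLI.
#'
#' @param model A `gb_model`.
#' @param sequences Character vector of sequences.
#' @param targets Integer target per example (1-based).
#' @param fie FIE name: one of `"raw_gradient"`, `"saliency"`,
#'   `"gradient_x_input"`, `"integrated_gradients"`,
#'   `"guided_backprop"`, `"deconvolution"`, `"deeplift"`.
#' @param ... Passed to the FIE (e.g. `K` for integrated gradients).
#' @return List of `gb_position_attribution`.
#' @export
attribute_examples <- function(model, sequences, targets, fie, ...) {
  fns <- list(
    raw_gradient = raw_gradient,
    saliency = saliency,
    gradient_x_input = gradient_x_input,
    integrated_gradients = integrated_gradients,
    guided_backprop = function(m, e, t, ...)
      modified_backprop(m, e, t, "guided_backprop", ...),
    deconvolution = function(m, e, t, ...)
      modified_backprop(m, e, t, "deconvolution", ...),
    deeplift = function(m, e, t, ...)
      modified_backprop(m, e, t, "deeplift", ...))
  if (!fie %in% names(fns)) stopf("unknown FIE '%s'", fie)
  targets <- rep(targets, length.out = length(sequences))
  lapply(seq_along(sequences), function(i) {
    att <- fns[[fie]](model, sequences[i], targets[i], ...)
    att$example_ref <- i
    att
  })
}
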