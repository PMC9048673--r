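# Model harness: one-hot encoding, model construction from a model
# definition, training with early stopping, prediction, and input
# gradients (the hook the attribution module builds on).

#' One-hot encode sequences
#'
#' Encodes a character vector of sequences into a
#' `(batch, length, |alphabet|)` array. Variable-length batches are
#' right-padded with all-zero channel vectors to the maximum length;
#' padding positions therefore receive zero attribution by
#' construction.
#'
#' @param sequences Character vector of sequences, or a dataset subset
#'   data frame with columns `x`/`y`.
#' @param alphabet Ordered symbol vector.
#' @param labels Optional label vector aligned with `sequences`
#'   (condition ids; `|`-joined for multilabel).
#' @param conditions Optional condition-id vector fixing the class
#'   order of the targets.
#' @param task `"multiclass"` or `"multilabel"`.
#' @return List of class `gb_batch` with `x` (3D array), `lengths`,
#'   and, when labels are given, `y` (integer class indices for
#'   multiclass; binary matrix for multilabel) plus `conditions`.
#' @export
encode_sequences <- function(sequences, alphabet, labels = NULL,
                             conditions = NULL, task = "multiclass") {
  if (is.data.frame(sequences)) {
    labels <- labels %||% sequences$y
    sequences <- sequences$x
  }
  B <- length(sequences)
  A <- length(alphabet)
  lens <- nchar(sequences)
  n <- if (B == 0) 0L else max(lens)
  X <- array(0, c(B, n, A))
  if (B > 0 && n > 0) {
    chars <- strsplit(sequences, "")
    flat <- unlist(chars)
    idx <- match(flat, alphabet)
    if (anyNA(idx)) {
      i <- which(is.na(idx))[1]
      bb <- rep(seq_len(B), lens)
      pos <- sequence(lens)
      stopf("unknown symbol '%s' at position %d of sequence %d",
            flat[i], pos[i], bb[i])
    }
    X[cbind(rep(seq_len(B), lens), sequence(lens), idx)] <- 1
  }
  out <- list(x = X, lengths = lens)
  if (!is.null(labels)) {
    if (task == "multiclass") {
      if (is.null(conditions)) conditions <- sort(unique(labels))
      y <- match(labels, conditions)
      if (anyNA(y)) stopf("label '%s' not among conditions",
                          labels[which(is.na(y))[1]])
    } else {
      if (is.null(conditions))
        conditions <- sort(unique(unlist(strsplit(labels, "|", fixed = TRUE))))
      y <- matrix(0, B, length(conditions))
      sets <- strsplit(labels, "|", fixed = TRUE)
      for (b in seq_len(B)) y[b, match(sets[[b]], conditions)] <- 1
    }
    out$y <- y
    out$conditions <- conditions
  }
  structure(out, class = "gb_batch")
}

activation_for_loss <- function(loss) {
  switch(loss,
    categorical_crossentropy = "softmax",
    binary_crossentropy = "sigmoid",
    none = "linear",
    stopf("unknown loss '%s'", loss))
}

#' Build an untrained model from a model definition
#'
#' Instantiates the declared architecture for a given input shape.
#' Parameter initialization (He-scaled Gaussian) is deterministic
#' under the model definition's seed. The final dense layer must have
#' as many units as there are conditions/labels.
#'
#' @param md A `gb_model_definition`.
#' @param input_shape `c(window_length, |alphabet|)`.
#' @param n_outputs Number of conditions (multiclass) or labels
#'   (multilabel).
#' @param alphabet Optional symbol vector stored with the model so
#'   prediction and attribution can encode raw sequences.
#' @return An object of class `gb_model` (untrained).
#' @export
build_model <- function(md, input_shape, n_outputs,
                        alphabet = NULL) {
  stopifnot(inherits(md, "gb_model_definition"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2)
    stopf("input_shape must be c(length, channels)")
  last <- md$architecture[[length(md$architecture)]]
  if (last$units != n_outputs)
    stopf("output layer has %d units but the task has %d conditions/labels",
          last$units, n_outputs)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(md$seed)
  built <- build_layers(md$architecture, input_shape)
  # zero-initialized output layer: stabilizes early training (hidden
  # layers receive no gradient until the head has learned meaningful
  # directions), preventing dying-ReLU collapse in narrow bottlenecks
  out_idx <- length(built$layers)
  built$layers[[out_idx]]$W <- built$layers[[out_idx]]$W * 0
  built$layers[[out_idx]]$b <- built$layers[[out_idx]]$b * 0
  structure(list(layers = built$layers, input_shape = input_shape,
                 n_outputs = as.integer(n_outputs),
                 output_activation = activation_for_loss(md$loss),
                 loss = md$loss, md = md, alphabet = alphabet,
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0)),
                 trained = FALSE),
            class = "gb_model")
}

#' @export
print.gb_model <- function(x, ...) {
  cat(sprintf("%s gb_model: input %sx%s -> %d outputs (%s), %d layer(s)\n",
              if (x$trained) "trained" else "untrained",
              x$input_shape[1], x$input_shape[2], x$n_outputs,
              x$output_activation, length(x$layers)))
  if (nrow(x$history) > 0)
    cat(sprintf("  trained %d epoch(s), final val loss %.4f\n",
                nrow(x$history), tail(x$history$val_loss, 1)))
  invisible(x)
}

apply_activation <- function(logits, activation) {
  switch(activation,
    softmax = {
      z <- logits - apply(logits, 1, max)
      e <- exp(z)
      e / rowSums(e)
    },
    sigmoid = 1 / (1 + exp(-logits)),
    linear = logits,
    stopf("unknown activation '%s'", activation))
}

as_input_array <- function(model, x) {
  if (is.character(x)) {
    if (is.null(model$alphabet))
      stopf("model carries no alphabet; encode sequences first")
    x <- encode_sequences(x, model$alphabet)$x
  }
  if (inherits(x, "gb_batch")) x <- x$x
  if (is.matrix(x)) x <- array(x, c(1, dim(x)))  # single example
  if (length(dim(x)) != 3) stopf("input must be a (batch, length, channels) array")
  if (!all(dim(x)[2:3] == model$input_shape))
    stopf("input shape %dx%d does not match model input %dx%d",
          dim(x)[2], dim(x)[3], model$input_shape[1], model$input_shape[2])
  x
}

#' Predict class/label probabilities
#'
#' @param object A `gb_model`.
#' @param x Input: `(batch, length, channels)` array, `gb_batch`,
#'   single-example one-hot matrix, or character sequences (if the
#'   model stores an alphabet).
#' @param type `"prob"` (activated output) or `"logit"`.
#' @param ... Unused.
#' @return Matrix `(batch, n_outputs)`; multiclass rows sum to 1,
#'   multilabel entries lie in `[0, 1]`.
#' @export
predict.gb_model <- function(object, x, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  if ((is.character(x) && length(x) == 0) ||
      (!is.null(dim(x)) && dim(x)[1] == 0 && !is.matrix(x)))
    return(matrix(0, 0, object$n_outputs))
  X <- as_input_array(object, x)
  if (dim(X)[1] == 0) return(matrix(0, 0, object$n_outputs))
  r <- layers_forward(object$layers, X, training = FALSE)
  if (type == "logit") r$out else apply_activation(r$out, object$output_activation)
}

loss_value <- function(model, P, y) {
  eps <- 1e-12
  if (model$loss == "categorical_crossentropy") {
    -mean(log(pmax(P[cbind(seq_len(nrow(P)), y)], eps)))
  } else {
    -mean(y * log(pmax(P, eps)) + (1 - y) * log(pmax(1 - P, eps)))
  }
}

#' Train a model on a simulated or external dataset
#'
#' Minimizes the declared loss with the declared optimizer on the
#' training subset, with early stopping on validation loss (declared
#' patience, best weights restored). Training reads only `x` and `y`;
#' annotations `a` are never accessed. The training RNG stream is
#' seeded from the model seed and independent of the simulation
#' stream, so a fixed (data seed, model seed) pair reproduces the
#' training trajectory exactly.
#'
#' @param model An untrained (or trained) `gb_model`.
#' @param dataset A `gb_dataset`, or a list with `gb_batch` entries
#'   `training` and `validation`.
#' @param md Model definition controlling training; defaults to the
#'   one the model was built from.
#' @param verbose Print per-epoch losses.
#' @return The trained `gb_model` with a filled `history` data frame
#'   (one row per epoch: `epoch`, `train_loss`, `val_loss`).
#' @export
train_model <- function(model, dataset, md = model$md, verbose = FALSE) {
  stopifnot(inherits(model, "gb_model"))
  if (inherits(dataset, "gb_dataset")) {
    dd <- dataset$data_definition
    conds <- dd$conditions$id
    enc_train <- encode_sequences(dataset$training$x, dd$alphabet,
                                  dataset$training$y, conds, dd$task_type)
    enc_val <- encode_sequences(dataset$validation$x, dd$alphabet,
                                dataset$validation$y, conds, dd$task_type)
    if (is.null(model$alphabet)) model$alphabet <- dd$alphabet
  } else {
    enc_train <- dataset$training
    enc_val <- dataset$validation
  }
  if (is.null(enc_train) || dim(enc_train$x)[1] == 0)
    stopf("training subset is empty")
  n <- dim(enc_train$x)[1]
  multiclass <- model$loss == "categorical_crossentropy"
  Ytr <- if (multiclass) {
    Y <- matrix(0, n, model$n_outputs)
    Y[cbind(seq_len(n), enc_train$y)] <- 1
    Y
  } else enc_train$y
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(md$seed + 1L)   # training stream, distinct from init stream
  layers <- model$layers
  state <- adam_init(layers)
  lr <- md$optimizer$learning_rate
  batch_size <- md$training$batch_size
  patience <- md$training$patience
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_layers <- layers; wait <- 0; t_step <- 0
  n_epochs <- md$training$epochs
  for (epoch in seq_len(n_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0; n_batches <- 0
    for (start in seq(1, n, by = batch_size)) {
      ids <- perm[start:min(start + batch_size - 1, n)]
      Xb <- enc_train$x[ids, , , drop = FALSE]
      Yb <- Ytr[ids, , drop = FALSE]
      fw <- layers_forward(layers, Xb, training = TRUE)
      layers <- fw$layers   # batch-norm running stats
      P <- apply_activation(fw$out, model$output_activation)
      B <- length(ids)
      loss <- if (multiclass)
        -mean(log(pmax(rowSums(P * Yb), 1e-12)))
      else
        -mean(Yb * log(pmax(P, 1e-12)) + (1 - Yb) * log(pmax(1 - P, 1e-12)))
      if (!is.finite(loss))
        stopf("training diverged (non-finite loss) at epoch %d", epoch)
      dLogits <- if (multiclass) (P - Yb) / B
                 else (P - Yb) / (B * model$n_outputs)
      bw <- layers_backward(layers, fw$caches, dLogits)
      t_step <- t_step + 1
      upd <- apply_updates(layers, bw$grads, state, lr, t_step,
                           md$optimizer$name)
      layers <- upd$layers; state <- upd$state
      epoch_loss <- epoch_loss + loss; n_batches <- n_batches + 1
    }
    model$layers <- layers
    Pval <- predict.gb_model(model, enc_val$x)
    val_loss <- loss_value(model, Pval, enc_val$y)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = epoch_loss / n_batches,
                                val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f, val %.4f", epoch,
                      epoch_loss / n_batches, val_loss))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss; best_layers <- layers; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience && patience > 0) break
    }
  }
  if (n_epochs > 0 && nrow(history) > 0) model$layers <- best_layers
  model$history <- history
  model$trained <- nrow(history) > 0
  model
}

#' Gradient of the target output with respect to the input
#'
#' Backpropagates from the model output `f_y` (the activated
#' probability by default) down to the one-hot input, optionally with
#' a modified ReLU backward rule.
#'
#' @param model A `gb_model`.
#' @param x Input batch (see [predict.gb_model()]).
#' @param target Integer class/label index (1-based), scalar or one
#'   per example.
#' @param rule ReLU backward rule: `"backprop"`, `"guided"`,
#'   `"deconv"` or `"deeplift"` (rescale, zero-baseline reference).
#' @param on Differentiate the activated `"output"` (default) or the
#'   pre-activation `"logit"`.
#' @return Array with the input's shape. For `rule = "deeplift"` the
#'   returned values are the DeepLIFT multipliers (contributions are
#'   `multipliers * (x - 0)`).
#' @export
model_gradient <- function(model, x, target, rule = "backprop",
                           on = c("output", "logit")) {
  on <- match.arg(on)
  X <- as_input_array(model, x)
  B <- dim(X)[1]
  target <- as.integer(rep(target, length.out = B))
  if (any(target < 1 | target > model$n_outputs))
    stopf("target index out of range 1..%d", model$n_outputs)
  fw <- layers_forward(model$layers, X, training = FALSE)
  ref_caches <- NULL
  fw0 <- NULL
  if (rule == "deeplift") {
    fw0 <- layers_forward(model$layers, array(0, dim(X)), training = FALSE)
    ref_caches <- fw0$caches
  }
  dLogits <- matrix(0, B, model$n_outputs)
  if (on == "logit") {
    dLogits[cbind(seq_len(B), target)] <- 1
  } else if (model$output_activation == "softmax") {
    P <- apply_activation(fw$out, "softmax")
    py <- P[cbind(seq_len(B), target)]
    dLogits <- -P * py
    dLogits[cbind(seq_len(B), target)] <-
      dLogits[cbind(seq_len(B), target)] + py
  } else if (model$output_activation == "sigmoid") {
    P <- apply_activation(fw$out, "sigmoid")
    py <- P[cbind(seq_len(B), target)]
    if (rule == "deeplift") {
      # rescale rule through the (single-input) output sigmoid, so the
      # completeness identity extends through the activation
      zy <- fw$out[cbind(seq_len(B), target)]
      zy0 <- fw0$out[cbind(seq_len(B), target)]
      py0 <- 1 / (1 + exp(-zy0))
      dz <- zy - zy0
      dLogits[cbind(seq_len(B), target)] <-
        ifelse(abs(dz) > 1e-7, (py - py0) / dz, py * (1 - py))
    } else {
      dLogits[cbind(seq_len(B), target)] <- py * (1 - py)
    }
  } else {
    dLogits[cbind(seq_len(B), target)] <- 1
  }
  bw <- layers_backward(model$layers, fw$caches, dLogits, rule, ref_caches)
  if (!all(is.finite(bw$dX))) stopf("non-finite gradient")
  bw$dX
}
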