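# Hand-coded oracle models with known ground truth, used to test
# FIEs and SIS against analytically known attributions.

#' Oracle model: detects one symbol at one position
#'
#' Builds a differentiable single-layer model whose sigmoid output is
#' approximately 1 iff symbol `symbol` occupies position `position`
#' and approximately 0 otherwise: a dense layer over the flattened
#' one-hot input with weight `scale` on the (position, symbol)
#' feature and bias `-scale/2`. Because the model is linear up to the
#' output sigmoid, gradient-based attributions have closed forms.
#'
#' @param position 1-based sequence position to detect.
#' @param symbol Symbol to detect.
#' @param n Sequence length the model accepts.
#' @param alphabet Symbol vector.
#' @param scale Logit scale (sharpness of the detector).
#' @return A `gb_model` with a single (1-unit, sigmoid) output.
#' @export
oracle_model <- function(position, symbol, n,
                         alphabet = alphabet_symbols("DNA"), scale = 20) {
  position <- as.integer(position)
  A <- length(alphabet)
  s_idx <- match(symbol, alphabet)
  if (is.na(s_idx)) stopf("symbol '%s' not in alphabet", symbol)
  if (position < 1 || position > n) stopf("position out of range 1..%d", n)
  W <- matrix(0, n * A, 1)
  # flatten order of array (B, n, A): feature = position + (channel-1)*n
  W[position + (s_idx - 1) * n, 1] <- scale
  layers <- list(list(type = "flatten"),
                 list(type = "dense", units = 1L, W = W, b = -scale / 2))
  md <- model_definition(list(list(type = "dense", units = 1)),
                         loss = "binary_crossentropy",
                         training = list(epochs = 0))
  structure(list(layers = layers, input_shape = c(as.integer(n), A),
                 n_outputs = 1L, output_activation = "sigmoid",
                 loss = "binary_crossentropy", md = md,
                 alphabet = alphabet,
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0)),
                 trained = TRUE),
            class = "gb_model")
}

#' Linear oracle model with explicit weights
#'
#' A model computing `f(x) = w . x + b` with identity output
#' activation, for closed-form gradient checks: the input gradient of
#' a linear model is `w` for every `x`.
#'
#' @param W Weight matrix `(n * |alphabet|) x n_outputs`, feature
#'   order position-major within channel (matching the flatten
#'   layer).
#' @param b Bias vector.
#' @param n Sequence length.
#' @param alphabet Symbol vector.
#' @return A `gb_model` with linear output.
#' @export
linear_model <- function(W, b, n, alphabet = alphabet_symbols("DNA")) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == n * length(alphabet))
  layers <- list(list(type = "flatten"),
                 list(type = "dense", units = ncol(W), W = W, b = b))
  md <- model_definition(list(list(type = "dense", units = ncol(W))),
                         loss = "categorical_crossentropy",
                         training = list(epochs = 0))
  structure(list(layers = layers,
                 input_shape = c(as.integer(n), length(alphabet)),
                 n_outputs = ncol(W), output_activation = "linear",
                 loss = "none", md = md, alphabet = alphabet,
                 history = data.frame(epoch = integer(0),
                                      train_loss = numeric(0),
                                      val_loss = numeric(0)),
                 trained = TRUE),
            class = "gb_model")
}
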