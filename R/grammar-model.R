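# Data model for grammars (data definitions) and model definitions.

#' Position weight matrix sequence element
#'
#' A PWM describes a sequence element (e.g. a transcription factor
#' binding motif) as independent per-position symbol probabilities.
#' The matrix is stored with one row per position ("PWM column" in
#' motif terminology) and one column per alphabet symbol; each row must
#' sum to 1 within 1e-9.
#'
#' @param element_id Identifier, unique within a data definition.
#' @param matrix Numeric matrix, width x |alphabet|.
#' @param alphabet Symbol vector the columns refer to.
#' @return An object of class `gb_pwm`.
#' @export
pwm_element <- function(element_id, matrix, alphabet = alphabet_symbols("DNA")) {
  m <- as.matrix(matrix)
  if (nrow(m) < 1) stopf("PWM '%s': width must be >= 1", element_id)
  if (ncol(m) != length(alphabet))
    stopf("PWM '%s': %d columns but alphabet has %d symbols",
          element_id, ncol(m), length(alphabet))
  if (any(m < 0)) stopf("PWM '%s': negative probabilities", element_id)
  sums <- rowSums(m)
  if (any(abs(sums - 1) > 1e-9))
    stopf("PWM '%s': position %d probabilities sum to %.12f, expected 1",
          element_id, which(abs(sums - 1) > 1e-9)[1],
          sums[which(abs(sums - 1) > 1e-9)[1]])
  colnames(m) <- alphabet
  rownames(m) <- NULL
  structure(list(element_id = element_id, matrix = m, alphabet = alphabet),
            class = "gb_pwm")
}

#' k-mer set sequence element
#'
#' A sequence element defined as a list of k-mers with associated
#' probabilities; sampling an instance draws one k-mer.
#'
#' @param element_id Identifier.
#' @param kmers Named numeric vector: names are the k-mer strings,
#'   values their probabilities (must sum to 1 within 1e-9).
#' @param alphabet Symbol vector the k-mers are written in.
#' @return An object of class `gb_kmer_set`.
#' @export
kmer_element <- function(element_id, kmers, alphabet = alphabet_symbols("DNA")) {
  if (length(kmers) == 0) stopf("k-mer set '%s': empty", element_id)
  if (is.null(names(kmers)) || any(!nzchar(names(kmers))))
    stopf("k-mer set '%s': kmers must be a named vector", element_id)
  if (any(kmers < 0) || any(kmers > 1))
    stopf("k-mer set '%s': probabilities must lie in [0, 1]", element_id)
  if (abs(sum(kmers) - 1) > 1e-9)
    stopf("k-mer set '%s': probabilities sum to %.12f, expected 1",
          element_id, sum(kmers))
  bad <- vapply(strsplit(names(kmers), ""),
                function(ch) any(!ch %in% alphabet), logical(1))
  if (any(bad))
    stopf("k-mer set '%s': k-mer '%s' uses symbols outside the alphabet",
          element_id, names(kmers)[which(bad)[1]])
  structure(list(element_id = element_id, kmers = kmers, alphabet = alphabet),
            class = "gb_kmer_set")
}

#' Width of a sequence element
#'
#' For PWMs the number of positions; for k-mer sets the maximum k-mer
#' length (used for feasibility checks).
#'
#' @param element A `gb_pwm` or `gb_kmer_set`.
#' @return Integer width.
#' @export
element_width <- function(element) {
  if (inherits(element, "gb_pwm")) return(nrow(element$matrix))
  if (inherits(element, "gb_kmer_set")) return(max(nchar(names(element$kmers))))
  stopf("not a sequence element")
}

#' Spacing/order constraint between two sequence elements
#'
#' Constrains the gap (in bp, symbols between the end of the first and
#' the start of the second element) between two elements of a rule, and
#' optionally their order.
#'
#' @param element_id_a,element_id_b Ids of the constrained elements.
#' @param min_gap,max_gap Integer gap bounds, `0 <= min_gap <= max_gap`.
#' @param order_fixed If `TRUE`, `element_id_a` must precede
#'   `element_id_b`; otherwise the order is randomized per example.
#' @return An object of class `gb_spacing`.
#' @export
spacing_constraint <- function(element_id_a, element_id_b, min_gap, max_gap,
                               order_fixed = TRUE) {
  min_gap <- as.integer(min_gap); max_gap <- as.integer(max_gap)
  if (min_gap < 0 || max_gap < min_gap)
    stopf("spacing constraint %s-%s: need 0 <= min_gap <= max_gap",
          element_id_a, element_id_b)
  structure(list(element_id_a = element_id_a, element_id_b = element_id_b,
                 min_gap = min_gap, max_gap = max_gap,
                 order_fixed = isTRUE(order_fixed)),
            class = "gb_spacing")
}

#' Probabilistic grammar rule
#'
#' A rule places an ordered list of sequence elements into the window
#' of an example of its condition, with a given firing probability and
#' position specification.
#'
#' @param condition_id Condition the rule belongs to.
#' @param probability Chance in `[0, 1]` that the rule fires for an
#'   example of its condition. Probabilities below 1 yield pure
#'   background examples that still carry the condition's label
#'   (label-noise-like examples).
#' @param position Either the string `"center"`, the string `"random"`
#'   (uniform over feasible starts), or a 0-based fixed start index.
#' @param element_ids Ordered, nonempty character vector of element ids.
#' @param spacing_constraints List of [spacing_constraint()] objects
#'   applying to consecutive element pairs.
#' @return An object of class `gb_rule`.
#' @export
grammar_rule <- function(condition_id, probability = 1, position = "random",
                         element_ids, spacing_constraints = list()) {
  if (probability < 0 || probability > 1)
    stopf("rule for '%s': probability must lie in [0, 1]", condition_id)
  if (length(element_ids) == 0)
    stopf("rule for '%s': element_ids must be nonempty", condition_id)
  if (is.character(position)) {
    if (!position %in% c("center", "random"))
      stopf("rule for '%s': position must be 'center', 'random' or a 0-based index",
            condition_id)
  } else {
    position <- as.integer(position)
    if (position < 0) stopf("rule for '%s': fixed position must be >= 0", condition_id)
  }
  stopifnot(all(vapply(spacing_constraints, inherits, logical(1), "gb_spacing")))
  structure(list(condition_id = condition_id, probability = probability,
                 position = position, element_ids = as.character(element_ids),
                 spacing_constraints = spacing_constraints),
            class = "gb_rule")
}

# minimal span of a rule: element widths plus the min gap of every
# consecutive pair (0 where unconstrained)
rule_min_span <- function(rule, elements) {
  widths <- vapply(rule$element_ids,
                   function(id) element_width(elements[[id]]), numeric(1))
  gaps <- 0
  if (length(rule$element_ids) > 1) {
    gaps <- vapply(seq_len(length(rule$element_ids) - 1), function(i) {
      sc <- find_spacing(rule, rule$element_ids[i], rule$element_ids[i + 1])
      if (is.null(sc)) 0L else sc$min_gap
    }, integer(1))
  }
  sum(widths) + sum(gaps)
}

find_spacing <- function(rule, id_a, id_b) {
  for (sc in rule$spacing_constraints) {
    if ((sc$element_id_a == id_a && sc$element_id_b == id_b) ||
        (sc$element_id_a == id_b && sc$element_id_b == id_a))
      return(sc)
  }
  NULL
}

#' Complete generative specification of a synthetic dataset
#'
#' A data definition bundles everything the simulator needs: the task
#' type, alphabet, window length, background distribution(s),
#' conditions, sequence elements and the probabilistic rules (the
#' grammar) that encode condition information into sequence windows.
#'
#' @param task_type `"multiclass"` (mutually exclusive classes) or
#'   `"multilabel"` (independent labels).
#' @param alphabet_kind `"DNA"`, `"RNA"` or `"protein"`.
#' @param window_length A single integer (fixed length) or a length-2
#'   vector `(min, max)`; variable lengths are sampled uniformly.
#' @param background List of [alphabet_distribution()]s: exactly one
#'   with `condition_id = NULL` (the default) plus optional
#'   per-condition backgrounds.
#' @param conditions Data frame with columns `id` and `label`.
#' @param elements List of [pwm_element()] / [kmer_element()] objects.
#' @param rules List of [grammar_rule()] objects.
#' @param set_sizes Named integer vector with entries `training`,
#'   `validation`, `test`: examples per condition in each subset.
#' @param seed Integer simulation seed; the dataset is a pure function
#'   of the data definition including this seed.
#' @return An object of class `gb_data_definition`.
#' @export
data_definition <- function(task_type, alphabet_kind, window_length,
                            background, conditions, elements, rules,
                            set_sizes, seed = 1L) {
  if (!task_type %in% c("multiclass", "multilabel"))
    stopf("task_type must be 'multiclass' or 'multilabel'")
  alpha <- alphabet_symbols(alphabet_kind)
  window_length <- as.integer(window_length)
  if (!length(window_length) %in% c(1, 2) || any(window_length < 1))
    stopf("window_length must be a positive integer or (min, max) pair")
  if (length(window_length) == 2 && window_length[1] > window_length[2])
    stopf("window_length range must satisfy min <= max")
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(conditions)))
    stopf("conditions must have columns 'id' and 'label'")
  if (anyDuplicated(conditions$id))
    stopf("condition ids must be unique")
  if (inherits(background, "gb_alphabet_dist")) background <- list(background)
  ok <- vapply(background, inherits, logical(1), "gb_alphabet_dist")
  if (!all(ok)) stopf("background must be alphabet_distribution objects")
  bg_cond <- vapply(background,
                    function(b) if (is.null(b$condition_id)) "" else b$condition_id,
                    character(1))
  if (sum(bg_cond == "") != 1)
    stopf("exactly one default (condition-free) background is required")
  dangling_bg <- setdiff(bg_cond[bg_cond != ""], conditions$id)
  if (length(dangling_bg) > 0)
    stopf("background refers to unknown condition(s): %s",
          paste(dangling_bg, collapse = ", "))
  el_ids <- vapply(elements, function(e) e$element_id, character(1))
  if (anyDuplicated(el_ids)) stopf("element ids must be unique")
  names(elements) <- el_ids
  for (r in rules) {
    if (!r$condition_id %in% conditions$id)
      stopf("rule refers to unknown condition '%s'", r$condition_id)
    missing_el <- setdiff(r$element_ids, el_ids)
    if (length(missing_el) > 0)
      stopf("rule for '%s' refers to unknown element(s): %s",
            r$condition_id, paste(missing_el, collapse = ", "))
    for (sc in r$spacing_constraints) {
      if (!all(c(sc$element_id_a, sc$element_id_b) %in% r$element_ids))
        stopf("spacing constraint %s-%s names elements not in the rule",
              sc$element_id_a, sc$element_id_b)
    }
    span <- rule_min_span(r, elements)
    lmin <- window_length[1]
    if (span > lmin)
      stopf("rule for '%s' is infeasible: minimal span %d exceeds window length %d",
            r$condition_id, span, lmin)
    if (is.numeric(r$position) && r$position + span > lmin)
      stopf("rule for '%s' is infeasible: fixed position %d + span %d exceeds window length %d",
            r$condition_id, r$position, span, lmin)
  }
  set_sizes <- vapply(c("training", "validation", "test"),
                      function(k) as.integer(set_sizes[[k]]), integer(1))
  if (any(is.na(set_sizes)) || any(set_sizes < 1))
    stopf("set_sizes must provide strictly positive training/validation/test counts")
  structure(list(task_type = task_type, alphabet_kind = alphabet_kind,
                 alphabet = alpha, window_length = window_length,
                 background = background, conditions = conditions,
                 elements = elements, rules = rules,
                 set_sizes = set_sizes, seed = as.integer(seed)),
            class = "gb_data_definition")
}

#' @export
print.gb_data_definition <- function(x, ...) {
  cat(sprintf("Data definition: %s task over %s alphabet\n",
              x$task_type, x$alphabet_kind))
  cat(sprintf("  window length : %s\n",
              paste(x$window_length, collapse = "-")))
  cat(sprintf("  conditions    : %s\n", paste(x$conditions$id, collapse = ", ")))
  cat(sprintf("  elements      : %s\n", paste(names(x$elements), collapse = ", ")))
  cat(sprintf("  rules         : %d\n", length(x$rules)))
  cat(sprintf("  set sizes     : %s (per condition)\n",
              paste(sprintf("%s=%d", names(x$set_sizes), x$set_sizes),
                    collapse = ", ")))
  cat(sprintf("  seed          : %d\n", x$seed))
  invisible(x)
}

known_layer_types <- c("conv", "dense", "max_pool", "global_max_pool",
                       "batch_norm", "dropout", "relu", "flatten", "skip")

validate_layer_spec <- function(layer) {
  if (is.null(layer$type) || !layer$type %in% known_layer_types)
    stopf("unknown layer type '%s'", if (is.null(layer$type)) "<missing>" else layer$type)
  switch(layer$type,
    conv = {
      if (is.null(layer$filters) || layer$filters < 1 ||
          is.null(layer$width) || layer$width < 1)
        stopf("conv layer needs filters >= 1 and width >= 1")
    },
    dense = {
      if (is.null(layer$units) || layer$units < 1)
        stopf("dense layer needs units >= 1")
    },
    max_pool = {
      if (is.null(layer$width) || layer$width < 2)
        stopf("max_pool layer needs width >= 2")
    },
    dropout = {
      if (is.null(layer$rate) || layer$rate < 0 || layer$rate >= 1)
        stopf("dropout rate must lie in [0, 1)")
    },
    skip = {
      if (is.null(layer$layers) || length(layer$layers) == 0)
        stopf("skip layer needs a nonempty 'layers' block")
      for (sub in layer$layers) validate_layer_spec(sub)
    }
  )
  invisible(layer)
}

#' Declarative model definition
#'
#' Describes a neural network architecture together with its loss,
#' optimizer, training process and seed — everything needed to create
#' and train the model reproducibly. The architecture is an ordered
#' list of layer specifications; the final layer must be a `dense`
#' layer whose unit count equals the number of conditions/labels
#' (checked when the model is built).
#'
#' Supported layer types: `conv` (1D, fields `filters`, `width`),
#' `dense` (`units`), `max_pool` (`width`), `global_max_pool`,
#' `batch_norm`, `dropout` (`rate` in `[0,1)`), `relu`, `flatten`
#' (inserted automatically where needed) and `skip` (a residual block
#' with field `layers`, output = input + block(input)).
#'
#' @param architecture List of layer specification lists, each with a
#'   `type` field.
#' @param loss `"categorical_crossentropy"` (multiclass, softmax
#'   output) or `"binary_crossentropy"` (multilabel, sigmoid output).
#' @param optimizer List with `name` (`"adam"` or `"sgd"`) and
#'   `learning_rate`.
#' @param training List with `batch_size`, `epochs` and early-stopping
#'   `patience` (epochs without validation-loss improvement).
#' @param seed Integer seed for parameter initialization and the
#'   training RNG stream (independent of the simulation stream).
#' @return An object of class `gb_model_definition`.
#' @export
model_definition <- function(architecture,
                             loss = "categorical_crossentropy",
                             optimizer = list(name = "adam", learning_rate = 1e-3),
                             training = list(batch_size = 64, epochs = 30,
                                             patience = 10),
                             seed = 1L) {
  if (length(architecture) == 0) stopf("architecture must be nonempty")
  for (layer in architecture) validate_layer_spec(layer)
  if (!loss %in% c("categorical_crossentropy", "binary_crossentropy"))
    stopf("loss must be categorical_crossentropy or binary_crossentropy")
  if (is.null(optimizer$name)) optimizer$name <- "adam"
  if (!optimizer$name %in% c("adam", "sgd"))
    stopf("optimizer must be 'adam' or 'sgd'")
  if (is.null(optimizer$learning_rate)) optimizer$learning_rate <- 1e-3
  defaults <- list(batch_size = 64, epochs = 30, patience = 10)
  for (k in names(defaults)) if (is.null(training[[k]])) training[[k]] <- defaults[[k]]
  if (training$batch_size < 1 || training$epochs < 0 || training$patience < 0)
    stopf("training: batch_size >= 1, epochs >= 0, patience >= 0 required")
  last <- architecture[[length(architecture)]]
  if (last$type != "dense")
    stopf("the final architecture layer must be a dense output layer")
  structure(list(architecture = architecture, loss = loss,
                 optimizer = optimizer, training = training,
                 seed = as.integer(seed)),
            class = "gb_model_definition")
}

#' @export
print.gb_model_definition <- function(x, ...) {
  fmt <- function(l) {
    extras <- setdiff(names(l), c("type", "layers"))
    inner <- if (l$type == "skip")
      paste0("[", paste(vapply(l$layers, fmt, character(1)), collapse = ", "), "]")
    else paste(sprintf("%s=%s", extras, unlist(l[extras])), collapse = ", ")
    if (nzchar(inner)) sprintf("%s(%s)", l$type, inner) else l$type
  }
  cat("Model definition\n")
  cat("  architecture :", paste(vapply(x$architecture, fmt, character(1)),
                                collapse = " -> "), "\n")
  cat(sprintf("  loss         : %s\n", x$loss))
  cat(sprintf("  optimizer    : %s (lr=%g)\n", x$optimizer$name,
              x$optimizer$learning_rate))
  cat(sprintf("  training     : batch=%d, epochs=%d, patience=%d, seed=%d\n",
              x$training$batch_size, x$training$epochs, x$training$patience,
              x$seed))
  invisible(x)
}
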