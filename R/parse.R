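# YAML parsing and serialization of data and model definitions.
# YAML is the canonical config dialect; the schema (field names below)
# is normative, the dialect is not.

read_yaml_doc <- function(document) {
  is_file <- length(document) == 1 && !grepl("\n", document) &&
    file.exists(document)
  tryCatch(
    if (is_file) yaml::read_yaml(document) else yaml::yaml.load(document),
    error = function(e) stopf("malformed YAML document: %s", conditionMessage(e))
  )
}

parse_element_spec <- function(spec, alphabet) {
  if (is.null(spec$id)) stopf("element without 'id' field")
  type <- spec$type
  if (identical(type, "pwm")) {
    rows <- spec$matrix
    if (is.null(rows) || length(rows) == 0)
      stopf("element '%s': pwm requires a 'matrix' block", spec$id)
    m <- do.call(rbind, lapply(rows, as.numeric))
    pwm_element(spec$id, m, alphabet)
  } else if (identical(type, "kmer")) {
    km <- unlist(spec$kmers)
    kmer_element(spec$id, km, alphabet)
  } else {
    stopf("element '%s': unknown type '%s' (expected 'pwm' or 'kmer')",
          spec$id, if (is.null(type)) "<missing>" else type)
  }
}

parse_rule_spec <- function(spec) {
  pos <- spec$position
  if (is.null(pos)) pos <- "random"
  if (is.numeric(pos)) pos <- as.integer(pos)
  scs <- lapply(spec$spacing, function(s)
    spacing_constraint(s$a, s$b, s$min_gap, s$max_gap,
                       isTRUE(s$order_fixed)))
  grammar_rule(condition_id = spec$condition,
               probability = if (is.null(spec$probability)) 1 else spec$probability,
               position = pos,
               element_ids = unlist(spec$elements),
               spacing_constraints = scs)
}

#' Parse a data definition document
#'
#' Reads a YAML data definition (file path or literal text), validates
#' every field and cross-reference, and returns a
#' [data_definition()] object. Violating inputs are rejected, never
#' silently corrected.
#'
#' @param document Path to a YAML file, or YAML text.
#' @return A `gb_data_definition`.
#' @seealso [serialize_data_definition()] for the inverse;
#'   `parse_data_definition(serialize_data_definition(dd))` round-trips.
#' @export
parse_data_definition <- function(document) {
  doc <- read_yaml_doc(document)
  for (f in c("task_type", "alphabet", "window_length", "background",
              "conditions", "elements", "rules", "set_sizes"))
    if (is.null(doc[[f]])) stopf("data definition: missing field '%s'", f)
  alpha <- alphabet_symbols(doc$alphabet)
  bg <- lapply(names(doc$background), function(key) {
    cond <- if (identical(key, "default")) NULL else sub("^condition_", "", key)
    alphabet_distribution(alpha, unlist(doc$background[[key]]), cond)
  })
  conditions <- data.frame(
    id = vapply(doc$conditions, function(cc) cc$id, character(1)),
    label = vapply(doc$conditions, function(cc)
      if (is.null(cc$label)) cc$id else cc$label, character(1)),
    stringsAsFactors = FALSE)
  elements <- lapply(doc$elements, parse_element_spec, alphabet = alpha)
  rules <- lapply(doc$rules, parse_rule_spec)
  data_definition(task_type = doc$task_type, alphabet_kind = doc$alphabet,
                  window_length = unlist(doc$window_length),
                  background = bg, conditions = conditions,
                  elements = elements, rules = rules,
                  set_sizes = unlist(doc$set_sizes),
                  seed = if (is.null(doc$seed)) 1L else doc$seed)
}

#' Serialize a data definition to YAML
#'
#' @param dd A `gb_data_definition`.
#' @param file Optional path; if given the YAML is written there.
#' @return YAML text (invisibly if `file` is given).
#' @export
serialize_data_definition <- function(dd, file = NULL) {
  bg <- list()
  for (b in dd$background) {
    key <- if (is.null(b$condition_id)) "default"
           else paste0("condition_", b$condition_id)
    bg[[key]] <- as.list(b$probabilities)
  }
  doc <- list(
    task_type = dd$task_type,
    alphabet = dd$alphabet_kind,
    window_length = if (length(dd$window_length) == 1) dd$window_length
                    else as.list(dd$window_length),
    seed = dd$seed,
    set_sizes = as.list(dd$set_sizes),
    background = bg,
    conditions = lapply(seq_len(nrow(dd$conditions)), function(i)
      list(id = dd$conditions$id[i], label = dd$conditions$label[i])),
    elements = lapply(dd$elements, function(e) {
      if (inherits(e, "gb_pwm"))
        list(id = e$element_id, type = "pwm",
             matrix = lapply(seq_len(nrow(e$matrix)),
                             function(i) as.list(unname(e$matrix[i, ]))))
      else
        list(id = e$element_id, type = "kmer", kmers = as.list(e$kmers))
    }),
    rules = lapply(dd$rules, function(r) {
      out <- list(condition = r$condition_id, probability = r$probability,
                  position = r$position, elements = as.list(r$element_ids))
      if (length(r$spacing_constraints) > 0)
        out$spacing <- lapply(r$spacing_constraints, function(sc)
          list(a = sc$element_id_a, b = sc$element_id_b,
               min_gap = sc$min_gap, max_gap = sc$max_gap,
               order_fixed = sc$order_fixed))
      out
    })
  )
  names(doc$elements) <- NULL
  txt <- yaml::as.yaml(doc, precision = 15L)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Parse a model definition document
#'
#' Reads a YAML model definition (file path or literal text) into a
#' validated [model_definition()].
#'
#' @param document Path to a YAML file, or YAML text.
#' @return A `gb_model_definition`.
#' @export
parse_model_definition <- function(document) {
  doc <- read_yaml_doc(document)
  if (is.null(doc$architecture)) stopf("model definition: missing 'architecture'")
  model_definition(
    architecture = doc$architecture,
    loss = if (is.null(doc$loss)) "categorical_crossentropy" else doc$loss,
    optimizer = if (is.null(doc$optimizer))
      list(name = "adam", learning_rate = 1e-3) else doc$optimizer,
    training = if (is.null(doc$training)) list() else doc$training,
    seed = if (is.null(doc$seed)) 1L else doc$seed)
}

#' Serialize a model definition to YAML
#'
#' @param md A `gb_model_definition`.
#' @param file Optional output path.
#' @return YAML text (invisibly if `file` is given).
#' @export
serialize_model_definition <- function(md, file = NULL) {
  doc <- list(seed = md$seed, loss = md$loss, optimizer = md$optimizer,
              training = md$training, architecture = md$architecture)
  txt <- yaml::as.yaml(doc, precision = 15L)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Import a HOMER-format motif as a PWM element
#'
#' Parses one HOMER motif record: a `>` header line (consensus, name,
#' threshold, ...) followed by one whitespace-separated probability row
#' per motif position (A, C, G, T order). Rows whose sum deviates from
#' 1 by at most 1e-3 are renormalized; larger deviations or negative
#' entries are errors.
#'
#' @param motif_text Path to a motif file or the motif text itself.
#' @param element_id Optional id; defaults to the name field of the
#'   header.
#' @return A `gb_pwm` over the DNA alphabet.
#' @export
import_homer_motif <- function(motif_text, element_id = NULL) {
  is_file <- length(motif_text) == 1 && !grepl("\n", motif_text) &&
    file.exists(motif_text)
  lines <- if (is_file) readLines(motif_text)
           else strsplit(paste(motif_text, collapse = "\n"), "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2 || !startsWith(lines[1], ">"))
    stopf("not a HOMER motif: expected a '>' header line followed by probability rows")
  header <- strsplit(sub("^>", "", lines[1]), "[ \t]+")[[1]]
  if (is.null(element_id))
    element_id <- if (length(header) >= 2) header[2] else header[1]
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(l, "[ \t]+")[[1]]))
  if (any(vapply(rows, function(r) length(r) != 4 || anyNA(r), logical(1))))
    stopf("HOMER motif '%s': each row must contain 4 numeric probabilities",
          element_id)
  m <- do.call(rbind, rows)
  if (any(m < 0))
    stopf("HOMER motif '%s': negative probability in row %d",
          element_id, which(apply(m, 1, function(r) any(r < 0)))[1])
  sums <- rowSums(m)
  off <- abs(sums - 1)
  if (any(off > 1e-3))
    stopf("HOMER motif '%s': row %d sums to %.6f (deviates from 1 by more than 1e-3)",
          element_id, which(off > 1e-3)[1], sums[which(off > 1e-3)[1]])
  m <- m / sums
  pwm_element(element_id, m, alphabet_symbols("DNA"))
}
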