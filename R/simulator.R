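# Simulator: generates (x, y, a) example triplets and full datasets
# from a data definition. All sampling uses R's global RNG;
# simulate_dataset() seeds it from the data definition, making the
# dataset a pure function of the definition.

#' Sample a background sequence
#'
#' Draws `length` i.i.d. symbols from a background distribution.
#'
#' @param length Non-negative integer.
#' @param dist A [alphabet_distribution()].
#' @return A character string of `length` symbols (`""` for length 0).
#' @export
sample_background <- function(length, dist) {
  stopifnot(inherits(dist, "gb_alphabet_dist"))
  length <- as.integer(length)
  if (is.na(length) || length < 0) stopf("length must be >= 0")
  if (length == 0) return("")
  paste(sample(dist$alphabet, length, replace = TRUE,
               prob = dist$probabilities), collapse = "")
}

#' Sample one instance of a sequence element
#'
#' For a PWM, each position is drawn independently from its
#' probability row; for a k-mer set, one k-mer is drawn according to
#' the set's probabilities.
#'
#' @param element A `gb_pwm` or `gb_kmer_set`.
#' @return A character string.
#' @export
sample_element_instance <- function(element) {
  if (inherits(element, "gb_pwm")) {
    m <- element$matrix
    idx <- vapply(seq_len(nrow(m)),
                  function(i) sample.int(ncol(m), 1L, prob = m[i, ]),
                  integer(1))
    paste(element$alphabet[idx], collapse = "")
  } else if (inherits(element, "gb_kmer_set")) {
    names(element$kmers)[sample.int(length(element$kmers), 1L,
                                    prob = element$kmers)]
  } else {
    stopf("not a sequence element")
  }
}

# Decide element order for one firing of a rule: consecutive pairs
# with an order_fixed = FALSE constraint are swapped with prob 0.5.
resolve_order <- function(rule) {
  ids <- rule$element_ids
  if (length(ids) < 2) return(ids)
  for (i in seq_len(length(ids) - 1)) {
    sc <- find_spacing(rule, ids[i], ids[i + 1])
    if (!is.null(sc) && !sc$order_fixed && runif(1) < 0.5)
      ids[c(i, i + 1)] <- ids[c(i + 1, i)]
    if (!is.null(sc) && sc$order_fixed &&
        sc$element_id_a == ids[i + 1] && sc$element_id_b == ids[i])
      ids[c(i, i + 1)] <- ids[c(i + 1, i)]
  }
  ids
}

place_chain <- function(rule, window_chars, ann_chars, elements, instances,
                        order_ids) {
  L <- length(window_chars)
  widths <- vapply(order_ids, function(id) nchar(instances[[id]]), integer(1))
  n_el <- length(order_ids)
  gaps <- integer(0)
  if (n_el > 1) {
    gaps <- vapply(seq_len(n_el - 1), function(i) {
      sc <- find_spacing(rule, order_ids[i], order_ids[i + 1])
      if (is.null(sc)) 0L
      else sc$min_gap + sample.int(sc$max_gap - sc$min_gap + 1L, 1L) - 1L
    }, integer(1))
  }
  total <- sum(widths) + sum(gaps)
  if (total > L) return(NULL)
  start <- if (identical(rule$position, "center")) {
    (L - total) %/% 2L               # 0-based
  } else if (identical(rule$position, "random")) {
    sample.int(L - total + 1L, 1L) - 1L
  } else {
    if (rule$position + total > L) return(NULL)
    rule$position
  }
  starts <- start + cumsum(c(0L, head(widths, -1) + gaps))
  placements <- data.frame(element_id = order_ids, start = starts,
                           end = starts + widths, stringsAsFactors = FALSE)
  idx <- unlist(lapply(seq_len(n_el),
                       function(i) (starts[i] + 1L):(starts[i] + widths[i])))
  if (any(ann_chars[idx] == "G")) return(NULL)  # overlap with earlier rule
  for (i in seq_len(n_el)) {
    pos <- (starts[i] + 1L):(starts[i] + widths[i])
    window_chars[pos] <- strsplit(instances[[order_ids[i]]], "")[[1]]
    ann_chars[pos] <- "G"
  }
  list(window = window_chars, annotation = ann_chars, placements = placements)
}

place_independent <- function(rule, window_chars, ann_chars, elements,
                              instances) {
  L <- length(window_chars)
  placements <- NULL
  for (id in rule$element_ids) {
    w <- nchar(instances[[id]])
    if (w > L) return(NULL)
    ok <- FALSE
    for (try in 1:50) {
      start <- sample.int(L - w + 1L, 1L) - 1L
      pos <- (start + 1L):(start + w)
      if (!any(ann_chars[pos] == "G")) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    window_chars[pos] <- strsplit(instances[[id]], "")[[1]]
    ann_chars[pos] <- "G"
    placements <- rbind(placements,
                        data.frame(element_id = id, start = start,
                                   end = start + w, stringsAsFactors = FALSE))
  }
  list(window = window_chars, annotation = ann_chars, placements = placements)
}

#' Place the elements of a rule into a window
#'
#' Writes freshly sampled element instances into a background window
#' and marks the written positions as grammar (`G`) in the annotation.
#' Elements connected by spacing constraints are placed as a chain
#' whose inter-element gaps are drawn uniformly from
#' `[min_gap, max_gap]`; the chain start obeys the rule's position
#' spec (0-based fixed index, `"center"` with start
#' `floor((L - span)/2)`, or uniform over feasible starts). Rules with
#' several elements and no spacing constraints place each element
#' independently at uniform random non-overlapping positions when the
#' position spec is `"random"`, and as a gap-0 chain otherwise.
#' Placements never overlap previously placed grammar positions;
#' placement is rejection-sampled up to `max_retries` times, then
#' errors.
#'
#' @param rule A [grammar_rule()].
#' @param window Character string, the current window.
#' @param annotation Character string of `G`/`_`, same length.
#' @param elements Named element list from the data definition.
#' @param max_retries Rejection-sampling budget.
#' @return List with `window`, `annotation` (strings) and `placements`
#'   (data frame of element_id, 0-based half-open `start`/`end`).
#' @export
place_rule <- function(rule, window, annotation, elements,
                       max_retries = 1000L) {
  wc <- strsplit(window, "")[[1]]
  ac <- strsplit(annotation, "")[[1]]
  if (length(wc) != length(ac))
    stopf("window and annotation lengths differ")
  independent <- length(rule$element_ids) > 1 &&
    length(rule$spacing_constraints) == 0 &&
    identical(rule$position, "random")
  for (try in seq_len(max_retries)) {
    instances <- lapply(elements[rule$element_ids], sample_element_instance)
    names(instances) <- rule$element_ids
    res <- if (independent) {
      place_independent(rule, wc, ac, elements, instances)
    } else {
      place_chain(rule, wc, ac, elements, instances, resolve_order(rule))
    }
    if (!is.null(res)) {
      return(list(window = paste(res$window, collapse = ""),
                  annotation = paste(res$annotation, collapse = ""),
                  placements = res$placements))
    }
  }
  stopf("no feasible placement for rule of condition '%s' after %d retries",
        rule$condition_id, max_retries)
}

condition_background <- function(dd, condition_id) {
  for (b in dd$background)
    if (!is.null(b$condition_id) && b$condition_id == condition_id) return(b)
  for (b in dd$background) if (is.null(b$condition_id)) return(b)
  stopf("no background distribution found")
}

#' Simulate one (x, y, a) example
#'
#' Samples a window from the condition's background distribution (or
#' the default), fires each applicable rule with its probability, and
#' returns the sequence, label and per-position annotation
#' (`G` = grammar position, `_` = background position).
#'
#' For multiclass tasks only the named condition's rules apply and `y`
#' is its id (even when no rule fired, yielding a label-noise-like
#' background example). For multilabel tasks every condition's rules
#' fire independently and `y` is the `|`-joined set of conditions with
#' at least one fired rule.
#'
#' @param condition_id Condition to simulate.
#' @param dd A `gb_data_definition`.
#' @return List with `x`, `y`, `a` (strings).
#' @export
simulate_example <- function(condition_id, dd) {
  if (!condition_id %in% dd$conditions$id)
    stopf("unknown condition '%s'", condition_id)
  L <- if (length(dd$window_length) == 1) dd$window_length
       else sample(dd$window_length[1]:dd$window_length[2], 1L)
  x <- sample_background(L, condition_background(dd, condition_id))
  a <- paste(rep("_", L), collapse = "")
  placements <- NULL
  if (dd$task_type == "multiclass") {
    y <- condition_id
    for (r in dd$rules) {
      if (r$condition_id != condition_id) next
      if (r$probability > 0 && runif(1) <= r$probability) {
        placed <- place_rule(r, x, a, dd$elements)
        x <- placed$window; a <- placed$annotation
        placements <- rbind(placements, placed$placements)
      }
    }
  } else {
    fired <- character(0)
    for (r in dd$rules) {
      if (r$probability > 0 && runif(1) <= r$probability) {
        placed <- place_rule(r, x, a, dd$elements)
        x <- placed$window; a <- placed$annotation
        placements <- rbind(placements, placed$placements)
        fired <- union(fired, r$condition_id)
      }
    }
    y <- paste(dd$conditions$id[dd$conditions$id %in% fired], collapse = "|")
  }
  list(x = x, y = y, a = a, placements = placements)
}

#' Simulate a full dataset
#'
#' Generates training, validation and test subsets with the
#' per-condition counts declared in the data definition. The result is
#' deterministic given the definition (including its seed); the
#' simulation RNG stream is independent of any training stream.
#'
#' @param dd A `gb_data_definition`.
#' @return An object of class `gb_dataset`: list with `training`,
#'   `validation`, `test` (data frames with columns `x`, `y`, `a`),
#'   `data_definition` and `seed`.
#' @export
simulate_dataset <- function(dd) {
  stopifnot(inherits(dd, "gb_data_definition"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(dd$seed)
  subsets <- lapply(names(dd$set_sizes), function(subset) {
    n_per <- dd$set_sizes[[subset]]
    rows <- lapply(dd$conditions$id, function(cid) {
      ex <- replicate(n_per, simulate_example(cid, dd), simplify = FALSE)
      data.frame(x = vapply(ex, `[[`, character(1), "x"),
                 y = vapply(ex, `[[`, character(1), "y"),
                 a = vapply(ex, `[[`, character(1), "a"),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(subsets) <- names(dd$set_sizes)
  structure(c(subsets, list(data_definition = dd, seed = dd$seed)),
            class = "gb_dataset")
}

#' @export
print.gb_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset (seed %d): %d training, %d validation, %d test examples\n",
              x$seed, nrow(x$training), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Per-example gap between two placed elements
#'
#' Utility for inspecting spacing-constrained grammars: given an
#' annotation string with exactly two runs of `G`, returns the number
#' of background positions between them (`NA` otherwise).
#'
#' @param annotation Annotation string (`G`/`_`).
#' @return Integer gap or `NA`.
#' @export
annotation_gap <- function(annotation) {
  r <- rle(strsplit(annotation, "")[[1]])
  g_runs <- which(r$values == "G")
  if (length(g_runs) != 2 || diff(g_runs) != 2) return(NA_integer_)
  r$lengths[g_runs[1] + 1L]
}
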