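# Programmatic fixtures: information-content-targeted random PWMs and
# ready-made grammars, so tests and examples need no external motif
# database. Fixture motifs make no claim of biological fidelity.

column_ic <- function(p) {
  nz <- p[p > 0]
  log2(length(p)) + sum(nz * log2(nz))
}

# Temper a base probability vector p^t / sum(p^t) so its information
# content hits `ic` (bits); bisection on t. t = 0 gives the uniform
# column (ic 0); t -> Inf approaches one-hot (ic log2 |alphabet|).
temper_to_ic <- function(p, ic, tol = 1e-3) {
  a <- length(p)
  max_ic <- log2(a)
  if (ic <= tol) return(rep(1 / a, a))
  if (ic >= max_ic - tol) {
    out <- rep(0, a); out[which.max(p)] <- 1
    return(out)
  }
  lp <- log(p)
  f <- function(t) {
    w <- t * lp
    q <- exp(w - max(w))    # log-space tempering avoids underflow
    q <- q / sum(q)
    column_ic(q) - ic
  }
  lo <- 0; hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (f(hi) < 0) stopf("cannot reach information content %.3f bits", ic)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  w <- ((lo + hi) / 2) * lp
  q <- exp(w - max(w))
  q / sum(q)
}

#' Random PWM with a target per-column information content
#'
#' Draws each column from a symmetric Dirichlet and tempers it so the
#' information content (in bits; `log2 |alphabet| - H`, at most 2 for
#' DNA) matches `ic_per_column` within 0.1 bits. `ic = 0` yields
#' uniform columns, the maximum yields one-hot columns.
#'
#' @param width Motif width (>= 1).
#' @param ic_per_column Target bits per column, in
#'   `[0, log2 |alphabet|]`.
#' @param element_id Id for the resulting element.
#' @param alphabet Symbol vector.
#' @return A `gb_pwm`.
#' @export
random_pwm <- function(width, ic_per_column, element_id = "pwm",
                       alphabet = alphabet_symbols("DNA")) {
  width <- as.integer(width)
  if (width < 1) stopf("width must be >= 1")
  a <- length(alphabet)
  if (ic_per_column < 0 || ic_per_column > log2(a))
    stopf("information content %.3f bits is unreachable for a %d-symbol alphabet",
          ic_per_column, a)
  m <- t(vapply(seq_len(width), function(i) {
    g <- stats::rgamma(a, shape = 1)
    temper_to_ic(g / sum(g), ic_per_column)
  }, numeric(a)))
  pwm_element(element_id, m, alphabet)
}

random_kmer <- function(k, alphabet = alphabet_symbols("DNA")) {
  paste(sample(alphabet, k, replace = TRUE), collapse = "")
}

#' Six toy grammar archetypes
#'
#' Builds a ready-made multiclass data definition implementing one of
#' six archetypal grammars of increasing complexity:
#' 1. class-specific k-mer at a fixed (center) position;
#' 2. class-specific PWM at a fixed (center) position;
#' 3. class-specific PWM at a uniform-random position;
#' 4. class-specific *combination* of PWMs drawn from a shared pool
#'    (no single PWM is class-specific), placed independently at
#'    random;
#' 5. two shared PWMs whose *order* is class-specific;
#' 6. two shared PWMs whose *spacing* is class-specific.
#'
#' The builder is a pure function of its arguments: motifs/k-mers are
#' derived from `seed`, which is also the simulation seed of the
#' returned definition.
#'
#' @param n Archetype number, 1..6.
#' @param n_classes Number of conditions (archetypes 5 and 6 require 2).
#' @param window_length Window length (integer or `(min, max)`).
#' @param k k-mer length (archetype 1).
#' @param motif_width PWM width (archetypes 2-6).
#' @param ic_per_column PWM information content, bits per column.
#' @param combo_size Elements per combination (archetype 4).
#' @param pool_size Shared PWM pool size (archetype 4); defaults to
#'   `n_classes + combo_size - 1` so combinations overlap between
#'   classes but no element is unique to a class.
#' @param gap_ranges List of two `(min, max)` gap ranges (archetype 6).
#' @param order_gap_range Gap range for the order archetype 5.
#' @param set_sizes Per-condition subset sizes.
#' @param rule_probability Firing probability of every rule.
#' @param seed Simulation seed.
#' @return A `gb_data_definition`.
#' @export
grammar_archetype <- function(n, n_classes = 4, window_length = 150,
                              k = 8, motif_width = 8, ic_per_column = 1.4,
                              combo_size = 2, pool_size = NULL,
                              gap_ranges = list(c(0, 3), c(10, 13)),
                              order_gap_range = c(0, 20),
                              set_sizes = c(training = 1000, validation = 200,
                                            test = 200),
                              rule_probability = 1, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1 || n > 6) stopf("archetype number must be in 1..6")
  if (n %in% c(5, 6) && n_classes != 2)
    stopf("archetypes 5 and 6 are binary grammars (n_classes = 2)")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  conds <- data.frame(id = paste0("c", seq_len(n_classes)),
                      label = paste("condition", seq_len(n_classes)),
                      stringsAsFactors = FALSE)
  alpha <- alphabet_symbols("DNA")
  bg <- human_genome_background()
  if (n == 1) {
    kmers <- character(0)
    while (length(kmers) < n_classes)
      kmers <- unique(c(kmers, random_kmer(k, alpha)))
    elements <- lapply(seq_len(n_classes), function(i)
      kmer_element(paste0("kmer_c", i), setNames(1, kmers[i]), alpha))
    rules <- lapply(seq_len(n_classes), function(i)
      grammar_rule(conds$id[i], rule_probability, "center",
                   paste0("kmer_c", i)))
  } else if (n %in% c(2, 3)) {
    elements <- lapply(seq_len(n_classes), function(i)
      random_pwm(motif_width, ic_per_column, paste0("pwm_c", i), alpha))
    pos <- if (n == 2) "center" else "random"
    rules <- lapply(seq_len(n_classes), function(i)
      grammar_rule(conds$id[i], rule_probability, pos, paste0("pwm_c", i)))
  } else if (n == 4) {
    if (is.null(pool_size)) pool_size <- n_classes + combo_size - 1
    if (choose(pool_size, combo_size) < n_classes)
      stopf("pool of %d elements has fewer than %d distinct %d-combinations",
            pool_size, n_classes, combo_size)
    elements <- lapply(seq_len(pool_size), function(i)
      random_pwm(motif_width, ic_per_column, paste0("pwm_", i), alpha))
    combos <- utils::combn(pool_size, combo_size, simplify = FALSE)
    combos <- combos[sample.int(length(combos), n_classes)]
    rules <- lapply(seq_len(n_classes), function(i)
      grammar_rule(conds$id[i], rule_probability, "random",
                   paste0("pwm_", combos[[i]])))
  } else if (n == 5) {
    elements <- list(random_pwm(motif_width, ic_per_column, "pwm_a", alpha),
                     random_pwm(motif_width, ic_per_column, "pwm_b", alpha))
    rules <- list(
      grammar_rule("c1", rule_probability, "random", c("pwm_a", "pwm_b"),
                   list(spacing_constraint("pwm_a", "pwm_b",
                                           order_gap_range[1],
                                           order_gap_range[2], TRUE))),
      grammar_rule("c2", rule_probability, "random", c("pwm_b", "pwm_a"),
                   list(spacing_constraint("pwm_b", "pwm_a",
                                           order_gap_range[1],
                                           order_gap_range[2], TRUE))))
  } else {
    elements <- list(random_pwm(motif_width, ic_per_column, "pwm_a", alpha),
                     random_pwm(motif_width, ic_per_column, "pwm_b", alpha))
    rules <- lapply(1:2, function(i)
      grammar_rule(conds$id[i], rule_probability, "random",
                   c("pwm_a", "pwm_b"),
                   list(spacing_constraint("pwm_a", "pwm_b",
                                           gap_ranges[[i]][1],
                                           gap_ranges[[i]][2], TRUE))))
  }
  data_definition("multiclass", "DNA", window_length, list(bg), conds,
                  elements, rules, set_sizes, seed = seed)
}

#' Spacing-constrained two-motif grammar
#'
#' A binary classification grammar modeling a hetero-dimeric
#' transcription-factor pair: the positive condition places two
#' fixture PWMs with a tight spacing constraint (default gap 0-3 bp,
#' fixed order); the negative condition is pure background (or, with
#' `negative = "shuffled"`, carries the same two motifs without any
#' spacing constraint).
#'
#' @param gap_range `(min, max)` gap in bp between the two motifs.
#' @param window_length Window length.
#' @param motif_width Width of each fixture PWM.
#' @param ic_per_column PWM information content, bits per column.
#' @param negative `"background"` or `"shuffled"`.
#' @param set_sizes Per-condition subset sizes.
#' @param seed Simulation seed.
#' @return A `gb_data_definition`.
#' @export
sox2_pou5f1_like_grammar <- function(gap_range = c(0, 3), window_length = 150,
                                     motif_width = 9, ic_per_column = 1.5,
                                     negative = c("background", "shuffled"),
                                     set_sizes = c(training = 1000,
                                                   validation = 200,
                                                   test = 200),
                                     seed = 1L) {
  negative <- match.arg(negative)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  alpha <- alphabet_symbols("DNA")
  elements <- list(
    random_pwm(motif_width, ic_per_column, "motif_a", alpha),
    random_pwm(motif_width, ic_per_column, "motif_b", alpha))
  conds <- data.frame(id = c("pos", "neg"),
                      label = c("dimer present", "no dimer"),
                      stringsAsFactors = FALSE)
  rules <- list(grammar_rule("pos", 1, "random", c("motif_a", "motif_b"),
                             list(spacing_constraint("motif_a", "motif_b",
                                                     gap_range[1], gap_range[2],
                                                     TRUE))))
  if (negative == "shuffled")
    rules <- c(rules, list(grammar_rule("neg", 1, "random",
                                        c("motif_a", "motif_b"))))
  data_definition("multiclass", "DNA", window_length,
                  list(human_genome_background()), conds, elements, rules,
                  set_sizes, seed = seed)
}
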