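#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames median quantile pchisq
#' @importFrom utils read.delim write.table head tail
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Symbol set for a sequence alphabet
#'
#' Returns the ordered symbol vector for one of the three supported
#' biological alphabets. Order is fixed and used everywhere a symbol
#' index matters (PWM columns, one-hot channels).
#'
#' @param kind One of `"DNA"`, `"RNA"` or `"protein"`.
#' @return Character vector of symbols (4 nucleotides or 20 amino acids).
#' @export
#' @examples
#' alphabet_symbols("DNA")
alphabet_symbols <- function(kind) {
  switch(kind,
    DNA = c("A", "C", "G", "T"),
    RNA = c("A", "C", "G", "U"),
    protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    stopf("unknown alphabet kind '%s' (expected DNA, RNA or protein)", kind)
  )
}

#' Background symbol distribution
#'
#' A categorical distribution over an alphabet, used to draw background
#' (non-grammar) positions. Distributions may be condition-specific,
#' allowing class-dependent backgrounds.
#'
#' @param alphabet Ordered character vector of symbols (see
#'   [alphabet_symbols()]).
#' @param probabilities Named numeric vector, one probability per symbol.
#'   Must sum to 1 (tolerance 1e-9) with every entry in `[0, 1]`.
#' @param condition_id Optional condition this background applies to;
#'   `NULL` marks the default background.
#' @return An object of class `gb_alphabet_dist`.
#' @export
alphabet_distribution <- function(alphabet, probabilities, condition_id = NULL) {
  if (is.null(names(probabilities))) {
    if (length(probabilities) != length(alphabet))
      stopf("unnamed probabilities must have one entry per symbol")
    names(probabilities) <- alphabet
  }
  unknown <- setdiff(names(probabilities), alphabet)
  if (length(unknown) > 0)
    stopf("probability given for symbol(s) not in alphabet: %s",
          paste(unknown, collapse = ", "))
  p <- setNames(rep(0, length(alphabet)), alphabet)
  p[names(probabilities)] <- probabilities
  if (any(p < 0) || any(p > 1))
    stopf("background probabilities must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stopf("background probabilities sum to %.12f, expected 1", sum(p))
  structure(list(alphabet = alphabet, probabilities = p,
                 condition_id = condition_id),
            class = "gb_alphabet_dist")
}

#' Natural nucleotide distribution of the human genome
#'
#' The default DNA background: 29.565% A, 20.435% C, 20.435% G,
#' 29.565% T.
#'
#' @param condition_id Optional condition id (default background if `NULL`).
#' @return A `gb_alphabet_dist`.
#' @export
human_genome_background <- function(condition_id = NULL) {
  alphabet_distribution(alphabet_symbols("DNA"),
                        c(A = 0.29565, C = 0.20435, G = 0.20435, T = 0.29565),
                        condition_id = condition_id)
}
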