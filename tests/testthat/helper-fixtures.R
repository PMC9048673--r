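# Shared fixtures built in code. Heavier objects (a small trained
# conv net) are memoized so the suite pays for them once.

.fixture_env <- new.env(parent = emptyenv())

# archetype-1-style binary grammar, 30-nt windows, 6-mers
tiny_dd <- function(seed = 11L, train = 200L) {
  grammar_archetype(1, n_classes = 2, window_length = 30, k = 6,
                    set_sizes = c(training = train, validation = 50,
                                  test = 50),
                    seed = seed)
}

tiny_md <- function(seed = 21L, epochs = 45) {
  model_definition(
    list(list(type = "conv", filters = 8, width = 7),
         list(type = "relu"),
         list(type = "global_max_pool"),
         list(type = "dense", units = 2)),
    training = list(batch_size = 32, epochs = epochs, patience = epochs),
    seed = seed)
}

# memoized: a small conv net trained to high accuracy on tiny_dd
trained_toy_conv <- function() {
  if (is.null(.fixture_env$toy)) {
    ds <- simulate_dataset(tiny_dd())
    model <- build_model(tiny_md(), c(30, 4), 2,
                         alphabet = alphabet_symbols("DNA"))
    model <- train_model(model, ds)
    .fixture_env$toy <- list(model = model, ds = ds)
  }
  .fixture_env$toy
}

# one-hot a single sequence into a (n, A) matrix
onehot1 <- function(seq, alphabet = alphabet_symbols("DNA")) {
  enc <- encode_sequences(seq, alphabet)
  matrix(enc$x[1, , ], nchar(seq), length(alphabet))
}

expect_rel_equal <- function(actual, expected, tol) {
  denom <- max(abs(expected), 1e-12)
  expect_lt(abs(actual - expected) / denom, tol)
}
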