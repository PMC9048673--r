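# Model harness: encoding, construction, training, prediction,
# gradients.

test_that("one-hot encoding is exact, padded, and strict about symbols", {
  enc <- encode_sequences("ACGT", alphabet_symbols("DNA"))
  expect_equal(matrix(enc$x[1, , ], 4, 4), diag(4))
  # variable lengths: right-padded with all-zero channel vectors
  enc2 <- encode_sequences(c("ACGTACGT", "ACGTACGTAC"),
                           alphabet_symbols("DNA"))
  expect_equal(dim(enc2$x), c(2, 10, 4))
  expect_equal(sum(enc2$x[1, 9:10, ]), 0)
  expect_equal(rowSums(matrix(enc2$x[2, , ], 10, 4)), rep(1, 10))
  # a 150-nt sequence is a 150 x 4 matrix: 600 features, width 150
  enc3 <- encode_sequences(strrep("A", 150), alphabet_symbols("DNA"))
  expect_equal(dim(enc3$x)[2:3], c(150, 4))
  expect_equal(prod(dim(enc3$x)[2:3]), 600)
  expect_error(encode_sequences(c("ACGT", "ACXT"), alphabet_symbols("DNA")),
               "unknown symbol 'X' at position 3 of sequence 2")
})

test_that("build_model is seed-deterministic and type-checks shapes", {
  md <- tiny_md(seed = 5)
  m1 <- build_model(md, c(30, 4), 2)
  m2 <- build_model(md, c(30, 4), 2)
  expect_identical(m1$layers, m2$layers)
  # output width must equal the number of conditions
  expect_error(build_model(md, c(30, 4), 3), "output layer")
  # conv wider than the input
  bad <- model_definition(list(list(type = "conv", filters = 2, width = 50),
                               list(type = "dense", units = 2)))
  expect_error(build_model(bad, c(30, 4), 2), "exceeds input length")
  # forward pass on zeros returns finite probabilities
  p <- predict(m1, array(0, c(1, 30, 4)))
  expect_true(all(is.finite(p)))
  expect_equal(rowSums(p), 1)
})

test_that("the full layer vocabulary builds and differentiates", {
  md <- model_definition(
    list(list(type = "conv", filters = 6, width = 5),
         list(type = "batch_norm"),
         list(type = "relu"),
         list(type = "max_pool", width = 2),
         list(type = "skip",
              layers = list(list(type = "conv", filters = 6, width = 1),
                            list(type = "relu"))),
         list(type = "global_max_pool"),
         list(type = "dense", units = 8),
         list(type = "relu"),
         list(type = "dropout", rate = 0.3),
         list(type = "dense", units = 3)),
    seed = 13)
  m <- build_model(md, c(24, 4), 3)
  set.seed(2)
  X <- array(runif(3 * 24 * 4), c(3, 24, 4))
  P <- predict(m, X)
  expect_equal(dim(P), c(3, 3))
  expect_equal(rowSums(P), rep(1, 3))
  g <- model_gradient(m, X, target = 2)
  expect_equal(dim(g), dim(X))
  expect_true(all(is.finite(g)))
  # skip blocks must preserve shape
  bad <- model_definition(
    list(list(type = "skip",
              layers = list(list(type = "conv", filters = 3, width = 2))),
         list(type = "dense", units = 2)))
  expect_error(build_model(bad, c(10, 4), 2), "shape")
})

test_that("gradients agree with central finite differences", {
  toy <- trained_toy_conv()
  m <- toy$model
  x <- toy$ds$test$x[1]
  X <- array(onehot1(x), c(1, 30, 4))
  # perturb a mix of active and inactive coordinates
  g <- model_gradient(m, X, target = 1)
  set.seed(42)
  h <- 1e-5
  for (i in 1:10) {
    p <- sample(30, 1); a <- sample(4, 1)
    Xp <- X; Xp[1, p, a] <- Xp[1, p, a] + h
    Xm <- X; Xm[1, p, a] <- Xm[1, p, a] - h
    fd <- (predict(m, Xp)[1, 1] - predict(m, Xm)[1, 1]) / (2 * h)
    if (abs(fd) > 1e-7)
      expect_rel_equal(g[1, p, a], fd, 1e-4)
    else
      expect_lt(abs(g[1, p, a] - fd), 1e-7)
  }
})

test_that("training contract: zero epochs, determinism, divergence guard", {
  ds <- simulate_dataset(tiny_dd(seed = 41, train = 60L))
  md0 <- tiny_md(epochs = 0)
  m0 <- train_model(build_model(md0, c(30, 4), 2), ds)
  expect_equal(nrow(m0$history), 0)
  expect_false(m0$trained)
  md <- tiny_md(seed = 8, epochs = 3)
  mA <- train_model(build_model(md, c(30, 4), 2), ds)
  mB <- train_model(build_model(md, c(30, 4), 2), ds)
  expect_identical(mA$history, mB$history)
  expect_identical(mA$layers, mB$layers)
  # training only sees x and y: a gb_dataset with corrupted annotations
  # trains identically
  ds2 <- ds
  ds2$training$a <- strrep("G", 30)
  mC <- train_model(build_model(md, c(30, 4), 2), ds2)
  expect_identical(mA$history, mC$history)
})

test_that("a trained toy conv net separates archetype-1 classes", {
  toy <- trained_toy_conv()
  dd <- toy$ds$data_definition
  enc <- encode_sequences(toy$ds$test$x, dd$alphabet, toy$ds$test$y,
                          dd$conditions$id)
  P <- predict(toy$model, enc$x)
  expect_equal(mean(max.col(P) == enc$y), 1.0)
  cv <- roc_pr_curves(P, enc$y, "micro")
  expect_equal(cv$roc_auc, 1.0)
})

test_that("the naive dense-only architecture builds and trains", {
  md <- model_definition(list(list(type = "dense", units = 16),
                              list(type = "relu"),
                              list(type = "dense", units = 2)),
                         training = list(batch_size = 32, epochs = 5,
                                         patience = 5), seed = 2)
  ds <- simulate_dataset(tiny_dd(seed = 43, train = 100L))
  m <- train_model(build_model(md, c(30, 4), 2), ds)
  expect_equal(nrow(m$history), 5)
  expect_lt(tail(m$history$val_loss, 1), log(2))  # better than chance
})

test_that("multilabel models train with binary cross-entropy", {
  dd <- grammar_archetype(3, n_classes = 2, window_length = 30,
                          motif_width = 6,
                          set_sizes = c(training = 80, validation = 20,
                                        test = 20), seed = 29)
  dd$task_type <- "multilabel"
  ds <- simulate_dataset(dd)
  md <- model_definition(list(list(type = "conv", filters = 4, width = 7),
                              list(type = "relu"),
                              list(type = "global_max_pool"),
                              list(type = "dense", units = 2)),
                         loss = "binary_crossentropy",
                         training = list(batch_size = 32, epochs = 3,
                                         patience = 3), seed = 6)
  m <- train_model(build_model(md, c(30, 4), 2), ds)
  enc <- encode_sequences(ds$test$x, dd$alphabet, ds$test$y,
                          dd$conditions$id, "multilabel")
  P <- predict(m, enc$x)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(dim(P), c(nrow(ds$test), 2))
})

test_that("prediction handles empty batches and single examples", {
  toy <- trained_toy_conv()
  expect_equal(dim(predict(toy$model, character(0))), c(0, 2))
  p <- predict(toy$model, onehot1(toy$ds$test$x[1]))
  expect_equal(dim(p), c(1, 2))
})
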