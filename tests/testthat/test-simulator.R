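# Simulator: background sampling, element instances, placement,
# examples and datasets.

test_that("sample_background matches its distribution and handles edges", {
  bg <- human_genome_background()
  set.seed(101)
  n <- 1e5
  s <- sample_background(n, bg)
  freq <- table(factor(strsplit(s, "")[[1]], levels = bg$alphabet)) / n
  for (sym in c("A", "G")) {
    p <- bg$probabilities[[sym]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(freq[[sym]] - p), 3 * se)
  }
  expect_identical(sample_background(0, bg), "")
  det <- alphabet_distribution(bg$alphabet, c(A = 1, C = 0, G = 0, T = 0))
  expect_identical(sample_background(5, det), "AAAAA")
  expect_error(sample_background(-1, bg), ">= 0")
})

test_that("sample_element_instance draws from PWM columns and k-mer sets", {
  det <- pwm_element("det", diag(4))
  expect_identical(sample_element_instance(det), "ACGT")
  km <- kmer_element("k", c(AAA = 1))
  expect_identical(sample_element_instance(km), "AAA")
  unif <- pwm_element("u", matrix(0.25, 1, 4))
  set.seed(7)
  draws <- replicate(1e5, sample_element_instance(unif))
  freq <- table(factor(draws, levels = alphabet_symbols("DNA"))) / 1e5
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) < 3 * se))
})

test_that("place_rule honors the center convention and order constraints", {
  el <- list(w4 = pwm_element("w4", diag(4)))
  rule <- grammar_rule("c1", 1, "center", "w4")
  res <- place_rule(rule, strrep("A", 10), strrep("_", 10), el)
  # width 4 in window 10: 0-based start floor((10-4)/2) = 3, i.e. 4..7 1-based
  expect_identical(res$annotation, "___GGGG___")
  expect_equal(res$placements$start, 3)
  expect_equal(res$placements$end, 7)
  # 0-based fixed position
  rule0 <- grammar_rule("c1", 1, 0, "w4")
  expect_identical(place_rule(rule0, strrep("A", 10), strrep("_", 10),
                              el)$annotation, "GGGG______")
  # fixed order: a always precedes b
  el2 <- list(a = pwm_element("a", diag(4)), b = pwm_element("b", diag(4)))
  rule_ab <- grammar_rule("c1", 1, "random", c("a", "b"),
                          list(spacing_constraint("a", "b", 1, 5, TRUE)))
  set.seed(5)
  ok <- replicate(1000, {
    pl <- place_rule(rule_ab, strrep("A", 40), strrep("_", 40), el2)$placements
    pl$start[pl$element_id == "a"] < pl$start[pl$element_id == "b"]
  })
  expect_true(all(ok))
})

test_that("spacing constraints bound the simulated gaps", {
  el2 <- list(a = pwm_element("a", diag(4)), b = pwm_element("b", diag(4)))
  rule <- grammar_rule("c1", 1, "random", c("a", "b"),
                       list(spacing_constraint("a", "b", 0, 3, TRUE)))
  set.seed(9)
  gaps <- replicate(2000, {
    pl <- place_rule(rule, strrep("A", 60), strrep("_", 60), el2)$placements
    pl$start[2] - pl$end[1]
  })
  expect_true(all(gaps %in% 0:3))
  expect_equal(max(gaps), 3)
  # gap histogram uniform within 3 SE per bin
  p <- 1 / 4
  se <- sqrt(p * (1 - p) / 2000)
  expect_true(all(abs(table(factor(gaps, levels = 0:3)) / 2000 - p) < 3 * se))
})

test_that("placement errors when no feasible arrangement exists", {
  el <- list(w8 = pwm_element("w8", matrix(0.25, 8, 4)))
  rule <- grammar_rule("c1", 1, "random", "w8")
  # window almost full of earlier grammar positions
  ann <- paste(c(rep("G", 9), "_"), collapse = "")
  expect_error(place_rule(rule, strrep("A", 10), ann, el, max_retries = 50),
               "no feasible placement")
})

test_that("simulate_example produces consistent (x, y, a) triplets", {
  dd <- tiny_dd(seed = 3)
  set.seed(1)
  ex <- simulate_example("c1", dd)
  expect_equal(nchar(ex$x), 30)
  expect_equal(nchar(ex$a), 30)
  expect_equal(ex$y, "c1")
  # archetype 1: exactly one G-run of width k at the window center
  r <- rle(strsplit(ex$a, "")[[1]])
  expect_equal(sum(r$values == "G"), 1)
  expect_equal(r$lengths[r$values == "G"], 6)
  expect_equal(r$lengths[1], (30 - 6) %/% 2)   # center convention
  # condition with no rules -> all background
  dd_bg <- dd
  dd_bg$rules <- list()
  ex2 <- simulate_example("c1", dd_bg)
  expect_identical(ex2$a, strrep("_", 30))
  # rule probability 0 never fires
  dd0 <- dd
  dd0$rules <- lapply(dd0$rules, function(r) { r$probability <- 0; r })
  for (i in 1:20)
    expect_identical(simulate_example("c1", dd0)$a, strrep("_", 30))
})

test_that("conservation: G count equals total placed element width", {
  for (arch in c(1, 3, 4, 6)) {
    dd <- grammar_archetype(arch,
                            n_classes = if (arch %in% c(5, 6)) 2 else 3,
                            window_length = 60, k = 5, motif_width = 5,
                            set_sizes = c(training = 5, validation = 2,
                                          test = 2),
                            seed = arch)
    set.seed(arch * 100)
    for (cid in dd$conditions$id) {
      ex <- simulate_example(cid, dd)
      g_count <- sum(strsplit(ex$a, "")[[1]] == "G")
      placed <- if (is.null(ex$placements)) 0
                else sum(ex$placements$end - ex$placements$start)
      expect_equal(g_count, placed)
      # every G run lies inside the union of placement intervals
      if (!is.null(ex$placements)) {
        mask <- rep(FALSE, nchar(ex$a))
        for (i in seq_len(nrow(ex$placements)))
          mask[(ex$placements$start[i] + 1):ex$placements$end[i]] <- TRUE
        expect_identical(strsplit(ex$a, "")[[1]] == "G", mask)
      }
    }
  }
})

test_that("simulate_dataset honors set sizes, determinism, and seed diversity", {
  dd <- grammar_archetype(1, n_classes = 2, window_length = 30, k = 6,
                          set_sizes = c(training = 1000, validation = 200,
                                        test = 200), seed = 17)
  ds <- simulate_dataset(dd)
  expect_equal(nrow(ds$training), 2000)
  expect_equal(nrow(ds$validation), 400)
  expect_equal(nrow(ds$test), 400)
  expect_equal(as.vector(table(ds$training$y)), c(1000, 1000))
  # byte-identical reruns
  expect_identical(ds$training, simulate_dataset(dd)$training)
  # different seeds: distinct sequences, matching composition
  small <- function(seed) {
    d <- tiny_dd(seed = seed, train = 20L)
    simulate_dataset(d)
  }
  sets <- lapply(1:5, small)
  for (i in 2:5) {
    expect_false(identical(sets[[1]]$training$x, sets[[i]]$training$x))
    expect_equal(table(sets[[i]]$training$y), table(sets[[1]]$training$y))
  }
})

test_that("background positions follow the background distribution", {
  # chi-square goodness of fit on "_" positions, 10 simulation seeds
  bg <- human_genome_background()
  passes <- vapply(1:10, function(seed) {
    dd <- grammar_archetype(3, n_classes = 2, window_length = 150,
                            motif_width = 8,
                            set_sizes = c(training = 350, validation = 2,
                                          test = 2), seed = seed)
    ds <- simulate_dataset(dd)
    xs <- strsplit(paste(ds$training$x, collapse = ""), "")[[1]]
    as_ <- strsplit(paste(ds$training$a, collapse = ""), "")[[1]]
    sym <- xs[as_ == "_"][1:1e5]
    obs <- table(factor(sym, levels = bg$alphabet))
    expected <- bg$probabilities * length(sym)
    stat <- sum((obs - expected)^2 / expected)
    pchisq(stat, df = 3, lower.tail = FALSE) > 0.01
  }, logical(1))
  expect_gte(sum(passes), 9)
})

test_that("variable-length windows and multilabel firing semantics", {
  dd <- grammar_archetype(3, n_classes = 2, window_length = c(40, 60),
                          motif_width = 6,
                          set_sizes = c(training = 30, validation = 5,
                                        test = 5), seed = 23)
  ds <- simulate_dataset(dd)
  lens <- nchar(ds$training$x)
  expect_true(all(lens >= 40 & lens <= 60))
  expect_gt(length(unique(lens)), 1)
  expect_identical(nchar(ds$training$a), lens)
  # multilabel: y is the set of fired conditions
  ddm <- dd
  ddm$task_type <- "multilabel"
  ddm$rules <- lapply(ddm$rules, function(r) { r$probability <- 0.5; r })
  set.seed(31)
  ys <- replicate(60, simulate_example("c1", ddm)$y)
  labs <- sort(unique(unlist(strsplit(ys, "|", fixed = TRUE))))
  expect_true(all(labs %in% c("", "c1", "c2")))
  expect_true(any(ys == ""))                 # no rule fired
  expect_true(any(grepl("c1", ys) & grepl("c2", ys)))  # both fired
})
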