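# Evaluation: conventional test-set metrics (ROC / PR curves),
# grammar- and vocabulary-recovery scores against ground-truth
# annotations, grammar agreement plots, and dataset-size sweeps.

binary_curve_points <- function(scores, targets) {
  stopifnot(length(scores) == length(targets))
  targets <- as.integer(targets)
  P <- sum(targets == 1); N <- sum(targets == 0)
  if (P == 0 || N == 0)
    stopf("need at least one positive and one negative target")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- targets[ord]
  # group tied scores: curve points only at unique-threshold boundaries
  boundary <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(t)[boundary]
  fp <- cumsum(1 - t)[boundary]
  list(threshold = s[boundary], tp = tp, fp = fp, P = P, N = N)
}

#' ROC curve with trapezoidal AUC
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param targets Binary targets (0/1 or logical).
#' @return A `gb_metric_curve`: list with `kind = "ROC"`, `points`
#'   (data frame threshold/x = FPR/y = TPR) and `auc`.
#' @export
roc_curve <- function(scores, targets) {
  cp <- binary_curve_points(scores, targets)
  fpr <- c(0, cp$fp / cp$N)
  tpr <- c(0, cp$tp / cp$P)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(kind = "ROC",
                 points = data.frame(threshold = c(Inf, cp$threshold),
                                     x = fpr, y = tpr),
                 auc = auc),
            class = "gb_metric_curve")
}

#' Precision-recall curve with step-wise AUC
#'
#' Uses step-wise summation (average-precision style), not linear
#' interpolation, which is optimistic for PR curves.
#'
#' @inheritParams roc_curve
#' @return A `gb_metric_curve` with `kind = "PR"`, `points`
#'   (threshold/x = recall/y = precision) and `auc`.
#' @export
pr_curve <- function(scores, targets) {
  cp <- binary_curve_points(scores, targets)
  recall <- cp$tp / cp$P
  precision <- cp$tp / (cp$tp + cp$fp)
  auc <- sum(diff(c(0, recall)) * precision)
  structure(list(kind = "PR",
                 points = data.frame(threshold = cp$threshold,
                                     x = recall, y = precision),
                 auc = auc),
            class = "gb_metric_curve")
}

#' @export
print.gb_metric_curve <- function(x, ...) {
  cat(sprintf("%s curve: AUC = %.4f (%d points)\n", x$kind, x$auc,
              nrow(x$points)))
  invisible(x)
}

#' ROC and PR curves for multiclass/multilabel scores
#'
#' One-vs-rest curves per class plus an aggregate: micro-averaging
#' pools all (class, example) score-target pairs before thresholding;
#' `"per-class"` (macro) averages the per-class AUCs.
#'
#' @param scores Matrix `(examples, classes)` of scores, or a vector
#'   for binary problems.
#' @param targets Integer class indices (multiclass), a binary matrix
#'   (multilabel), or a binary vector matching a score vector.
#' @param averaging `"micro"` or `"per-class"`.
#' @return List with `roc`, `pr` (per-class lists of
#'   `gb_metric_curve`), `roc_auc`, `pr_auc` (aggregate under the
#'   chosen averaging).
#' @export
roc_pr_curves <- function(scores, targets, averaging = c("micro", "per-class")) {
  averaging <- match.arg(averaging)
  if (is.null(dim(scores))) {
    roc <- roc_curve(scores, targets)
    pr <- pr_curve(scores, targets)
    return(list(roc = list(roc), pr = list(pr),
                roc_auc = roc$auc, pr_auc = pr$auc))
  }
  C <- ncol(scores)
  Y <- if (is.matrix(targets)) targets else {
    m <- matrix(0, nrow(scores), C)
    m[cbind(seq_len(nrow(scores)), as.integer(targets))] <- 1
    m
  }
  roc <- lapply(seq_len(C), function(ci) roc_curve(scores[, ci], Y[, ci]))
  pr <- lapply(seq_len(C), function(ci) pr_curve(scores[, ci], Y[, ci]))
  if (averaging == "micro") {
    roc_auc <- roc_curve(as.vector(scores), as.vector(Y))$auc
    pr_auc <- pr_curve(as.vector(scores), as.vector(Y))$auc
  } else {
    roc_auc <- mean(vapply(roc, `[[`, numeric(1), "auc"))
    pr_auc <- mean(vapply(pr, `[[`, numeric(1), "auc"))
  }
  list(roc = roc, pr = pr, roc_auc = roc_auc, pr_auc = pr_auc)
}

annotation_mask <- function(annotation) {
  ch <- strsplit(annotation, "")[[1]]
  if (any(!ch %in% c("G", "_")))
    stopf("annotation may only contain 'G' and '_'")
  ch == "G"
}

#' Grammar-agreement score of an attribution
#'
#' Fraction of absolute attribution mass that falls on grammar
#' positions: `sum |z| over G positions / sum |z| over all
#' (non-padding) positions`, with 0/0 defined as 0. Invariant under
#' positive rescaling of the attribution. This mass-fraction statistic
#' is this package's definition of grammar/vocabulary recovery.
#'
#' @param attr A `gb_position_attribution` or numeric vector.
#' @param annotation Annotation string (`G`/`_`), same length.
#' @param exclude Optional logical vector marking positions (e.g.
#'   padding) to drop from both numerator and denominator.
#' @return Score in `[0, 1]`.
#' @export
grammar_agreement_score <- function(attr, annotation, exclude = NULL) {
  z <- if (inherits(attr, "gb_position_attribution")) attr$values else attr
  g <- annotation_mask(annotation)
  if (length(z) != length(g))
    stopf("attribution length %d does not match annotation length %d",
          length(z), length(g))
  keep <- if (is.null(exclude)) rep(TRUE, length(z)) else !exclude
  total <- sum(abs(z[keep]))
  if (total == 0) return(0)
  sum(abs(z[g & keep])) / total
}

#' SIS grammar-agreement score
#'
#' Precision of the union of all SIS masks against the grammar
#' positions: `|SIS-positions in G| / |SIS-positions|`, 0/0 = 0.
#'
#' @param sis A `gb_sis_result`.
#' @param annotation Annotation string, length matching the example.
#' @return Score in `[0, 1]`.
#' @export
sis_agreement_score <- function(sis, annotation) {
  g <- annotation_mask(annotation)
  if (sis$n != length(g))
    stopf("SIS length %d does not match annotation length %d",
          sis$n, length(g))
  if (length(sis$subsets) == 0) return(0)
  u <- Reduce(`|`, sis$subsets)
  if (sum(u) == 0) return(0)
  sum(u & g) / sum(u)
}

#' Aggregate grammar-recovery summary over examples
#'
#' @param attrs List of `gb_position_attribution`.
#' @param annotations Character vector of annotation strings.
#' @return A `gb_agreement_summary`: per-example scores, mean, median,
#'   FIE name and example count.
#' @export
agreement_summary <- function(attrs, annotations) {
  stopifnot(length(attrs) == length(annotations))
  scores <- vapply(seq_along(attrs), function(i)
    grammar_agreement_score(attrs[[i]], annotations[i]), numeric(1))
  structure(list(per_example_scores = scores,
                 aggregate = c(mean = mean(scores), median = median(scores)),
                 method = if (length(attrs) > 0) attrs[[1]]$method else NA,
                 n_examples = length(attrs)),
            class = "gb_agreement_summary")
}

#' @export
print.gb_agreement_summary <- function(x, ...) {
  cat(sprintf("Grammar agreement (%s, n = %d): mean %.3f, median %.3f\n",
              x$method, x$n_examples, x$aggregate["mean"],
              x$aggregate["median"]))
  invisible(x)
}

#' Grammar agreement plot data (and optional heatmap rendering)
#'
#' Builds the example x position grid behind a grammar agreement
#' plot: attribution magnitude as luminosity (min-max normalized per
#' example to [0, 1], darker = more important) and the ground-truth
#' annotation as hue (grammar green, background red). Examples are
#' ordered by descending agreement score.
#'
#' @param annotations Character vector of annotation strings.
#' @param attrs List of `gb_position_attribution`, aligned.
#' @param file Optional PNG path; if given a heatmap is rendered.
#' @return A `gb_agreement_plot`: list with `luminosity` (matrix,
#'   examples x positions, NA beyond an example's length), `hue`
#'   (character matrix `"G"`/`"_"`), `order` (row order applied) and
#'   `scores`.
#' @export
agreement_plot <- function(annotations, attrs, file = NULL) {
  stopifnot(length(attrs) == length(annotations))
  nex <- length(attrs)
  lens <- nchar(annotations)
  width <- max(lens)
  lum <- matrix(NA_real_, nex, width)
  hue <- matrix(NA_character_, nex, width)
  scores <- numeric(nex)
  for (i in seq_len(nex)) {
    z <- abs(attrs[[i]]$values)
    rng <- range(z)
    lum[i, seq_len(lens[i])] <- if (diff(rng) == 0) rep(0, lens[i])
                                else (z - rng[1]) / diff(rng)
    hue[i, seq_len(lens[i])] <- strsplit(annotations[i], "")[[1]]
    scores[i] <- grammar_agreement_score(attrs[[i]], annotations[i])
  }
  ord <- order(scores, decreasing = TRUE)
  res <- structure(list(luminosity = lum[ord, , drop = FALSE],
                        hue = hue[ord, , drop = FALSE],
                        order = ord, scores = scores[ord]),
                   class = "gb_agreement_plot")
  if (!is.null(file)) render_agreement_plot(res, file)
  res
}

render_agreement_plot <- function(plot_data, file) {
  lum <- plot_data$luminosity
  hue <- plot_data$hue
  col <- matrix("white", nrow(lum), ncol(lum))
  ok <- !is.na(lum)
  col[ok & hue == "G"] <- grDevices::rgb(1 - lum[ok & hue == "G"], 1,
                                         1 - lum[ok & hue == "G"])
  col[ok & hue == "_"] <- grDevices::rgb(1, 1 - lum[ok & hue == "_"],
                                         1 - lum[ok & hue == "_"])
  grDevices::png(file, width = 900, height = 60 + 12 * nrow(lum))
  op <- graphics::par(mar = c(2, 2, 1, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(NA, xlim = c(0, ncol(lum)), ylim = c(0, nrow(lum)),
                 xlab = "position", ylab = "example", xaxs = "i",
                 yaxs = "i", axes = FALSE)
  graphics::axis(1); graphics::axis(2)
  graphics::rect(rep(seq_len(ncol(lum)) - 1, each = nrow(lum)),
                 rep(nrow(lum) - seq_len(nrow(lum)), ncol(lum)),
                 rep(seq_len(ncol(lum)), each = nrow(lum)),
                 rep(nrow(lum) - seq_len(nrow(lum)) + 1, ncol(lum)),
                 col = as.vector(col), border = NA)
  invisible(file)
}

#' Dataset-size sweep
#'
#' For every (grammar, architecture, training size, simulation seed)
#' cell: simulate a dataset with the given training size per
#' condition, train the architecture, and record test-set micro ROC
#' and PR AUCs (plus, optionally, mean integrated-gradients grammar
#' agreement over a test subsample). Results accumulate in a
#' tab-separated file when `out` is given, making the sweep
#' resumable: completed cells are skipped on re-run; failed cells are
#' recorded with metric `"error"` and the sweep continues.
#'
#' @param dd_list Named list of data definitions (grammars).
#' @param md_list Named list of model definitions (architectures).
#' @param sizes Strictly increasing integer vector of training sizes
#'   (examples per condition).
#' @param seeds Integer vector of simulation seeds.
#' @param out Optional TSV path for resumable accumulation.
#' @param agreement_n If > 0, also record mean IG agreement over this
#'   many test examples.
#' @return Data frame with columns grammar, architecture, size, seed,
#'   metric, value.
#' @export
run_sweep <- function(dd_list, md_list, sizes, seeds = 1L, out = NULL,
                      agreement_n = 0) {
  if (is.null(names(dd_list)))
    names(dd_list) <- paste0("grammar", seq_along(dd_list))
  if (is.null(names(md_list)))
    names(md_list) <- paste0("model", seq_along(md_list))
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) stopf("sizes must be strictly increasing")
  done <- NULL
  if (!is.null(out) && file.exists(out))
    done <- read.delim(out, stringsAsFactors = FALSE)
  rows <- list()
  for (gname in names(dd_list)) for (mname in names(md_list))
    for (size in sizes) for (seed in seeds) {
      if (!is.null(done) &&
          any(done$grammar == gname & done$architecture == mname &
              done$size == size & done$seed == seed)) next
      cell <- tryCatch({
        dd <- dd_list[[gname]]
        dd$set_sizes["training"] <- size
        dd$seed <- as.integer(seed)
        ds <- simulate_dataset(dd)
        n_out <- nrow(dd$conditions)
        model <- build_model(md_list[[mname]],
                             c(max(dd$window_length), length(dd$alphabet)),
                             n_out)
        model <- train_model(model, ds)
        enc <- encode_sequences(ds$test$x, dd$alphabet, ds$test$y,
                                dd$conditions$id, dd$task_type)
        P <- predict.gb_model(model, enc$x)
        curves <- roc_pr_curves(P, enc$y, "micro")
        metrics <- data.frame(metric = c("roc_auc", "pr_auc"),
                              value = c(curves$roc_auc, curves$pr_auc))
        if (agreement_n > 0) {
          idx <- seq_len(min(agreement_n, nrow(ds$test)))
          attrs <- attribute_examples(model, ds$test$x[idx],
                                      enc$y[idx], "integrated_gradients",
                                      K = 20)
          ag <- agreement_summary(attrs, ds$test$a[idx])
          metrics <- rbind(metrics,
                           data.frame(metric = "agreement_ig_mean",
                                      value = ag$aggregate[["mean"]]))
        }
        metrics
      }, error = function(e)
        data.frame(metric = "error", value = NA_real_,
                   stringsAsFactors = FALSE))
      cell <- data.frame(grammar = gname, architecture = mname,
                         size = size, seed = seed, cell,
                         stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- cell
      if (!is.null(out)) {
        write.table(rbind(done, do.call(rbind, rows)), out, sep = "\t",
                    row.names = FALSE, quote = FALSE)
      }
    }
  res <- do.call(rbind, c(list(done), rows))
  rownames(res) <- NULL
  res
}
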