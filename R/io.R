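# On-disk formats: plain-text datasets (tab-separated sequence/label
# plus aligned annotation files), FASTA export, and plain-text model
# checkpoints (YAML definition + JSON parameters + TSV history).

#' Write a dataset to a directory
#'
#' Per subset, two aligned plain-text files: `<subset>.txt` with
#' header `x<TAB>y` (sequence, `|`-joined labels) and
#' `<subset>-annotation.txt` with header `annotation<TAB>y`. The
#' generating data definition is saved as `data-definition.yaml`.
#'
#' @param dataset A `gb_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gb_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (subset in c("training", "validation", "test")) {
    df <- dataset[[subset]]
    write.table(df[, c("x", "y")], file.path(dir, paste0(subset, ".txt")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    ann <- data.frame(annotation = df$a, y = df$y)
    write.table(ann, file.path(dir, paste0(subset, "-annotation.txt")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  serialize_data_definition(dataset$data_definition,
                            file.path(dir, "data-definition.yaml"))
  invisible(dir)
}

#' Read a dataset from a directory
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `gb_dataset`.
#' @export
read_dataset <- function(dir) {
  dd <- parse_data_definition(file.path(dir, "data-definition.yaml"))
  subsets <- lapply(c(training = "training", validation = "validation",
                      test = "test"), function(subset) {
    df <- read.delim(file.path(dir, paste0(subset, ".txt")),
                     colClasses = "character")
    ann <- read.delim(file.path(dir, paste0(subset, "-annotation.txt")),
                      colClasses = "character")
    if (nrow(ann) != nrow(df))
      stopf("%s: annotation file does not align with examples file", subset)
    df$a <- ann$annotation
    df
  })
  structure(c(subsets, list(data_definition = dd, seed = dd$seed)),
            class = "gb_dataset")
}

#' Export a dataset subset as FASTA
#'
#' Sequence records named `<subset>_<i>` with the condition label in
#' the description, for interoperability with standard sequence
#' tools. Uses Biostrings when available, plain writeLines otherwise.
#'
#' @param dataset A `gb_dataset`.
#' @param file Output FASTA path.
#' @param subset Subset name.
#' @return `file`, invisibly.
#' @export
export_fasta <- function(dataset, file, subset = "test") {
  df <- dataset[[subset]]
  ids <- sprintf("%s_%d %s", subset, seq_len(nrow(df)), df$y)
  if (requireNamespace("Biostrings", quietly = TRUE) &&
      dataset$data_definition$alphabet_kind == "DNA") {
    xs <- Biostrings::DNAStringSet(df$x)
    names(xs) <- ids
    Biostrings::writeXStringSet(xs, file)
  } else {
    writeLines(paste0(">", ids, "\n", df$x), file)
  }
  invisible(file)
}

serialize_params <- function(layers) {
  lapply(layers, function(l) {
    out <- list(type = l$type)
    for (p in c("W", "b", "gamma", "beta", "running_mean", "running_var"))
      if (!is.null(l[[p]]))
        out[[p]] <- if (is.matrix(l[[p]]))
          list(dim = dim(l[[p]]), data = as.vector(l[[p]]))
        else list(dim = length(l[[p]]), data = as.vector(l[[p]]))
    if (l$type == "skip") out$sub <- serialize_params(l$layers)
    out
  })
}

restore_params <- function(layers, stored) {
  for (i in seq_along(layers)) {
    s <- stored[[i]]
    if (!identical(layers[[i]]$type, s$type))
      stopf("checkpoint layer %d is '%s' but model expects '%s'",
            i, s$type, layers[[i]]$type)
    for (p in c("W", "b", "gamma", "beta", "running_mean", "running_var"))
      if (!is.null(s[[p]])) {
        v <- s[[p]]$data
        if (length(s[[p]]$dim) == 2) v <- matrix(v, s[[p]]$dim[1], s[[p]]$dim[2])
        layers[[i]][[p]] <- v
      }
    if (identical(s$type, "skip"))
      layers[[i]]$layers <- restore_params(layers[[i]]$layers, s$sub)
  }
  layers
}

#' Save a model checkpoint
#'
#' Writes a plain-text checkpoint directory: the originating model
#' definition (`model-definition.yaml`), learned parameters
#' (`parameters.json`), training history (`history.tsv`) and input
#' metadata (`metadata.json`).
#'
#' @param model A `gb_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "gb_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  serialize_model_definition(model$md, file.path(dir, "model-definition.yaml"))
  jsonlite::write_json(serialize_params(model$layers),
                       file.path(dir, "parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(model$history, file.path(dir, "history.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(input_shape = model$input_shape,
                            n_outputs = model$n_outputs,
                            output_activation = model$output_activation,
                            loss = model$loss,
                            alphabet = model$alphabet,
                            trained = model$trained),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_model()].
#' @return A `gb_model`.
#' @export
load_model <- function(dir) {
  md <- parse_model_definition(file.path(dir, "model-definition.yaml"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  model <- build_model(md, meta$input_shape, meta$n_outputs,
                       alphabet = meta$alphabet)
  stored <- jsonlite::read_json(file.path(dir, "parameters.json"),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
  norm_stored <- function(layers) lapply(layers, function(s) {
    for (p in c("W", "b", "gamma", "beta", "running_mean", "running_var"))
      if (!is.null(s[[p]])) {
        s[[p]]$dim <- unlist(s[[p]]$dim)
        s[[p]]$data <- unlist(s[[p]]$data)
      }
    if (!is.null(s$sub)) s$sub <- norm_stored(s$sub)
    s
  })
  model$layers <- restore_params(model$layers, norm_stored(stored))
  hist_file <- file.path(dir, "history.tsv")
  if (file.exists(hist_file)) model$history <- read.delim(hist_file)
  model$trained <- isTRUE(meta$trained)
  model$output_activation <- meta$output_activation
  model$loss <- meta$loss
  model
}

#' Write per-example attribution tables
#'
#' One tab-separated file per example: columns `position`, `value`,
#' `annotation` (if given).
#'
#' @param attrs List of `gb_position_attribution`.
#' @param dir Output directory.
#' @param annotations Optional aligned annotation strings.
#' @return `dir`, invisibly.
#' @export
write_attributions <- function(attrs, dir, annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(attrs)) {
    at <- attrs[[i]]
    df <- data.frame(position = seq_along(at$values), value = at$values)
    if (!is.null(annotations))
      df$annotation <- strsplit(annotations[i], "")[[1]]
    write.table(df, file.path(dir, sprintf("%s_example%03d.tsv",
                                           at$method, i)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
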