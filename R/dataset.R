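#' Labeled neural dataset
#'
#' The universal container consumed by every estimator in the package: a
#' `T x N` matrix of neural states (firing rates or spike counts, one column
#' per neuron) aligned row-by-row with a `T x M` matrix of labels (e.g. x
#' position, y position, running speed), plus per-label metadata and free-form
#' provenance.
#'
#' @param states numeric matrix or data frame, `T x N`; one row per time bin.
#' @param labels numeric matrix or data frame, `T x M`, same row count.
#' @param label_meta tibble with one row per label column: `name`,
#'   `circular` (logical), `period` (finite positive for circular labels,
#'   `NA` otherwise) and `units`. Defaults to non-circular, unit-less labels.
#' @param provenance named list of free-form metadata (seeds, source, ...).
#'
#' @return an object of class `labeled_dataset`: a list with elements
#'   `states`, `labels` (numeric matrices), `label_meta` (tibble) and
#'   `provenance` (list).
#' @export
labeled_dataset <- function(states, labels, label_meta = NULL, provenance = list()) {
  states <- as.matrix(states)
  labels <- as.matrix(labels)
  storage.mode(states) <- "double"
  storage.mode(labels) <- "double"
  if (nrow(states) != nrow(labels)) {
    stop("`states` and `labels` must have the same number of rows", call. = FALSE)
  }
  if (anyNA(states) || anyNA(labels)) {
    stop("missing values are not allowed in a labeled_dataset", call. = FALSE)
  }
  if (is.null(colnames(labels))) {
    colnames(labels) <- paste0("label", seq_len(ncol(labels)))
  }
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("n", seq_len(ncol(states)))
  }
  if (is.null(label_meta)) {
    label_meta <- tibble::tibble(
      name = colnames(labels),
      circular = FALSE,
      period = NA_real_,
      units = ""
    )
  }
  label_meta <- tibble::as_tibble(label_meta)
  stopifnot(all(c("name", "circular", "period") %in% names(label_meta)))
  if (!"units" %in% names(label_meta)) label_meta$units <- ""
  if (nrow(label_meta) != ncol(labels)) {
    stop("`label_meta` must have one row per label column", call. = FALSE)
  }
  bad <- label_meta$circular & !(is.finite(label_meta$period) & label_meta$period > 0)
  if (any(bad)) {
    stop("circular labels require a finite positive period", call. = FALSE)
  }
  structure(
    list(states = states, labels = labels, label_meta = label_meta,
         provenance = provenance),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %d time bins x %d neurons; labels: %s\n",
    nrow(x$states), ncol(x$states),
    paste(x$label_meta$name, collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) c(nrow(x$states), ncol(x$states))

#' Coerce a labeled dataset to a tibble
#'
#' Returns one row per time bin with label columns first, then one column per
#' neuron.
#'
#' @param x a [labeled_dataset()].
#' @param ... unused.
#' @exportS3Method tibble::as_tibble
as_tibble.labeled_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$labels, .name_repair = "minimal"),
    tibble::as_tibble(x$states, .name_repair = "minimal")
  )
}

#' Subset the rows of a labeled dataset
#'
#' @param data a [labeled_dataset()].
#' @param idx integer or logical row index.
#' @return a [labeled_dataset()] with the selected rows.
#' @export
dataset_slice <- function(data, idx) {
  labeled_dataset(
    data$states[idx, , drop = FALSE],
    data$labels[idx, , drop = FALSE],
    data$label_meta,
    data$provenance
  )
}

#' Write / read a labeled dataset as a plain-text directory
#'
#' The on-disk layout is a directory containing `states.csv`, `labels.csv`,
#' `label_meta.csv` and `provenance.json`.
#'
#' @param data a [labeled_dataset()].
#' @param path directory to create (or read).
#' @return `write_labeled_dataset()` returns `path` invisibly;
#'   `read_labeled_dataset()` returns a [labeled_dataset()].
#' @export
write_labeled_dataset <- function(data, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(data$states), file.path(path, "states.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(data$labels), file.path(path, "labels.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(data$label_meta), file.path(path, "label_meta.csv"), row.names = FALSE)
  jsonlite::write_json(data$provenance, file.path(path, "provenance.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_labeled_dataset
#' @export
read_labeled_dataset <- function(path) {
  states <- as.matrix(utils::read.csv(file.path(path, "states.csv")))
  labels <- as.matrix(utils::read.csv(file.path(path, "labels.csv")))
  meta <- tibble::as_tibble(utils::read.csv(file.path(path, "label_meta.csv")))
  meta$period <- as.numeric(meta$period)
  meta$units <- as.character(meta$units)
  prov_file <- file.path(path, "provenance.json")
  prov <- if (file.exists(prov_file)) jsonlite::read_json(prov_file, simplifyVector = TRUE) else list()
  labeled_dataset(states, labels, meta, as.list(prov))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
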