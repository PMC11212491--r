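#' Construct an aligned multi-omics dataset
#'
#' The central input container: one numeric sample-by-feature matrix per
#' omics block, all sharing the same samples in the same order, plus an
#' integer class label per sample. Labels are 0-based (`0 .. n_classes-1`).
#'
#' @param matrices named list of numeric matrices with identical row
#'   counts; rows are samples, columns are features.
#' @param labels integer vector, one 0-based class per sample; every
#'   class in `0..n_classes-1` must occur.
#' @param sample_ids character vector of unique sample identifiers.
#' @param n_classes number of classes; defaults to `max(labels) + 1`.
#' @return a `multiomics_dataset` with fields `omics_names`, `matrices`,
#'   `labels`, `sample_ids`, `n_classes`.
#' @export
multiomics_dataset <- function(matrices, labels, sample_ids,
                               n_classes = max(labels) + 1L) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  if (is.null(names(matrices)) || anyDuplicated(names(matrices))) {
    stop("matrices must be a uniquely named list", call. = FALSE)
  }
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n <- nrow(matrices[[1L]])
  labels <- as.integer(labels)
  n_classes <- as.integer(n_classes)
  if (!all(vapply(matrices, nrow, 0L) == n)) {
    stop("all omics matrices must have the same number of rows", call. = FALSE)
  }
  if (length(labels) != n || length(sample_ids) != n) {
    stop("labels and sample_ids must have one entry per sample", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample_ids", call. = FALSE)
  if (any(labels < 0L) || any(labels >= n_classes)) {
    stop("labels must lie in 0..n_classes-1", call. = FALSE)
  }
  if (!all((seq_len(n_classes) - 1L) %in% labels)) {
    stop("every class in 0..n_classes-1 must occur at least once", call. = FALSE)
  }
  for (nm in names(matrices)) {
    if (!all(is.finite(matrices[[nm]]))) {
      stop(sprintf("omics '%s' contains NA/NaN/Inf values", nm), call. = FALSE)
    }
    rownames(matrices[[nm]]) <- sample_ids
  }
  structure(
    list(
      omics_names = names(matrices),
      matrices = matrices,
      labels = labels,
      sample_ids = as.character(sample_ids),
      n_classes = n_classes
    ),
    class = "multiomics_dataset"
  )
}

#' Number of samples in a multi-omics dataset
#' @param dataset a `multiomics_dataset`.
#' @return integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' Subset a multi-omics dataset by sample
#'
#' Keeps row alignment across all omics blocks and the labels. Class
#' labels are left untouched (no re-indexing), so the subset may miss a
#' class; validation is relaxed accordingly.
#'
#' @param dataset a `multiomics_dataset`.
#' @param idx integer or logical sample index.
#' @return a `multiomics_dataset` over the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  out <- dataset
  out$matrices <- lapply(dataset$matrices, function(m) m[idx, , drop = FALSE])
  out$labels <- dataset$labels[idx]
  out$sample_ids <- dataset$sample_ids[idx]
  out
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf(
    "multiomics_dataset: %d samples, %d classes, %d omics block(s)\n",
    n_samples(x), x$n_classes, length(x$matrices)
  ))
  for (nm in x$omics_names) {
    cat(sprintf("  %-12s %d features\n", nm, ncol(x$matrices[[nm]])))
  }
  tab <- table(factor(x$labels, levels = 0:(x$n_classes - 1L)))
  cat("  class sizes:", paste(tab, collapse = "/"), "\n")
  invisible(x)
}
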