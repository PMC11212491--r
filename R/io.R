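#' Load a multi-omics dataset from per-omics tables and a label file
#'
#' Each omics file is CSV or TSV with a header row; its first column is
#' the sample identifier, remaining columns are numeric features. The
#' label file has two columns: sample identifier and 0-based integer
#' class. Samples are intersected across all files and ordered by sorted
#' sample identifier, so the result does not depend on file order;
#' identifiers dropped by the intersection are reported via a message and
#' the `"dropped_ids"` attribute.
#'
#' @param omics_paths named character vector/list of omics file paths;
#'   names become omics names (defaults to file base names).
#' @param label_path path of the 2-column label file.
#' @param impute `"error"` rejects missing values; `"mean"` replaces them
#'   with the column mean (columns that are entirely missing are an
#'   error in both modes).
#' @return a [multiomics_dataset()] with attribute `dropped_ids`.
#' @export
load_multiomics_dataset <- function(omics_paths, label_path,
                                    impute = c("error", "mean")) {
  impute <- match.arg(impute)
  omics_paths <- as.list(omics_paths)
  if (is.null(names(omics_paths)) || any(names(omics_paths) == "")) {
    names(omics_paths) <- vapply(
      omics_paths, function(p) sub("\\.[^.]*$", "", basename(p)), ""
    )
  }
  for (p in c(unlist(omics_paths), label_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }

  blocks <- lapply(names(omics_paths), function(nm) {
    dt <- data.table::fread(omics_paths[[nm]], header = TRUE,
                            colClasses = list(character = 1L))
    ids <- as.character(dt[[1L]])
    feat <- as.data.frame(dt[, -1L, drop = FALSE])
    for (j in seq_along(feat)) {
      col <- feat[[j]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
        stop(sprintf(
          "non-numeric value in omics '%s', row '%s', column '%s'",
          nm, ids[bad %||% 1L], names(feat)[j]
        ), call. = FALSE)
      }
    }
    m <- as.matrix(feat)
    rownames(m) <- ids
    m
  })
  names(blocks) <- names(omics_paths)

  lab_dt <- data.table::fread(label_path, header = TRUE,
                              colClasses = list(character = 1L))
  if (ncol(lab_dt) < 2L) stop("label file needs 2 columns", call. = FALSE)
  lab_ids <- as.character(lab_dt[[1L]])
  lab_vals <- lab_dt[[2L]]

  id_sets <- c(lapply(blocks, rownames), list(lab_ids))
  shared <- sort(Reduce(intersect, id_sets))
  dropped <- sort(setdiff(unique(unlist(id_sets)), shared))
  if (length(shared) < 2L) {
    stop("fewer than 2 samples shared across all input files", call. = FALSE)
  }
  # label file must cover every intersected sample (guaranteed by the
  # intersection) but flag samples whose label is missing/NA explicitly
  lab_map <- setNames(lab_vals, lab_ids)
  if (anyNA(lab_map[shared])) {
    miss <- shared[is.na(lab_map[shared])][1L]
    stop("missing label for sample '", miss, "'", call. = FALSE)
  }

  blocks <- lapply(blocks, function(m) {
    m <- m[shared, , drop = FALSE]
    if (anyNA(m) || any(!is.finite(m[!is.na(m)]))) {
      m[!is.finite(m)] <- NA_real_
      if (impute == "error") {
        stop("missing/non-finite values present (set impute = 'mean' to ",
             "replace with column means)", call. = FALSE)
      }
      mu <- colMeans(m, na.rm = TRUE)
      if (anyNA(mu)) stop("a column is entirely missing", call. = FALSE)
      na_ix <- which(is.na(m), arr.ind = TRUE)
      m[na_ix] <- mu[na_ix[, 2L]]
    }
    m
  })

  if (length(dropped)) {
    message("dropped ", length(dropped), " sample(s) absent from some input: ",
            paste(head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  }
  ds <- multiomics_dataset(blocks, as.integer(lab_map[shared]), shared)
  attr(ds, "dropped_ids") <- dropped
  ds
}

#' Write a multi-omics dataset as CSV files
#'
#' Produces one `<omics>.csv` per block (first column `sample_id`) and a
#' `labels.csv`, the layout [load_multiomics_dataset()] reads back.
#'
#' @param dataset a `multiomics_dataset`.
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of written paths.
#' @export
write_multiomics_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in dataset$omics_names) {
    m <- dataset$matrices[[nm]]
    dt <- data.table::data.table(sample_id = dataset$sample_ids)
    dt <- cbind(dt, data.table::as.data.table(m))
    p <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(dt, p)
    paths[nm] <- p
  }
  lp <- file.path(dir, "labels.csv")
  data.table::fwrite(
    data.table::data.table(sample_id = dataset$sample_ids,
                           label = dataset$labels), lp
  )
  paths["labels"] <- lp
  invisible(paths)
}
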