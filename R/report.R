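#' Assemble an experiment report from per-fold metrics
#'
#' @param per_fold list of named metric vectors, one per fold.
#' @param config the [run_config()] used (stored as snapshot).
#' @param seed master seed of the experiment.
#' @return an `experiment_report` with `per_fold`, `mean`, `std`
#'   (absent with a single fold), `config_snapshot`, `seed`.
#' @export
experiment_report <- function(per_fold, config = NULL, seed = NULL) {
  if (!length(per_fold)) stop("no folds to report", call. = FALSE)
  metrics <- names(per_fold[[1L]])
  m <- do.call(rbind, lapply(per_fold, function(x) x[metrics]))
  structure(
    list(
      per_fold = per_fold,
      mean = colMeans(m),
      std = if (nrow(m) >= 2L) apply(m, 2L, sd),
      config_snapshot = if (!is.null(config)) unclass(config),
      seed = seed
    ),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: %d fold(s)\n", length(x$per_fold)))
  for (nm in names(x$mean)) {
    if (!is.null(x$std)) {
      cat(sprintf("  %-12s %.3f +/- %.3f\n", nm, x$mean[nm], x$std[nm]))
    } else {
      cat(sprintf("  %-12s %.3f\n", nm, x$mean[nm]))
    }
  }
  invisible(x)
}

#' Save an experiment report
#'
#' Writes a machine-readable JSON file at `path` and a human-readable
#' table (`mean +/- std` per metric, plus per-fold values) next to it
#' with extension `.txt`.
#'
#' @param report an [experiment_report()].
#' @param path output JSON path.
#' @return invisibly, the paths written.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      per_fold = lapply(report$per_fold, as.list),
      mean = as.list(report$mean),
      std = if (!is.null(report$std)) as.list(report$std),
      config = report$config_snapshot,
      seed = report$seed
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  txt <- sub("\\.[^.]*$", "", path)
  txt <- paste0(txt, ".txt")
  lines <- c(
    sprintf("%-12s %s", "metric", "mean +/- std"),
    vapply(names(report$mean), function(nm) {
      if (!is.null(report$std)) {
        sprintf("%-12s %.4f +/- %.4f", nm, report$mean[nm], report$std[nm])
      } else {
        sprintf("%-12s %.4f", nm, report$mean[nm])
      }
    }, "")
  )
  writeLines(lines, txt)
  invisible(c(json = path, table = txt))
}
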