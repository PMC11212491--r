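#' Remove low-variance features
#'
#' Drops every column whose sample variance is less than or equal to
#' `threshold`; with the default threshold 0 this removes exactly the
#' constant columns. Column order is preserved.
#'
#' @param matrix numeric sample-by-feature matrix.
#' @param threshold non-negative variance cut-off.
#' @return list with `matrix` (reduced) and `kept` (original column
#'   indices of the surviving features).
#' @export
variance_filter <- function(matrix, threshold = 0) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1L, threshold >= 0)
  v <- unname(apply(matrix, 2L, var))
  kept <- which(v > threshold)
  if (!length(kept)) {
    stop("variance filter removed every feature", call. = FALSE)
  }
  list(matrix = matrix[, kept, drop = FALSE], kept = kept)
}

# one-way ANOVA F statistic for every column at once (between/within
# mean squares); identical to anova(aov(col ~ factor(labels)))$F
anova_f_statistics <- function(matrix, labels) {
  f <- factor(labels)
  g <- length(levels(f))
  n <- nrow(matrix)
  grand <- colMeans(matrix)
  ss_between <- numeric(ncol(matrix))
  ss_within <- numeric(ncol(matrix))
  for (lev in levels(f)) {
    rows <- f == lev
    mu <- colMeans(matrix[rows, , drop = FALSE])
    ss_between <- ss_between + sum(rows) * (mu - grand)^2
    ss_within <- ss_within +
      colSums(sweep(matrix[rows, , drop = FALSE], 2L, mu)^2)
  }
  ms_between <- ss_between / (g - 1L)
  ms_within <- ss_within / (n - g)
  ifelse(ms_within == 0, ifelse(ms_between == 0, 0, Inf),
         ms_between / ms_within)
}

#' Univariate ANOVA-F feature selection
#'
#' Keeps the `n_selected` columns with the largest one-way ANOVA F
#' statistic between classes. Ties are broken by ascending column index,
#' and the kept set is returned in original column order, so the result
#' is deterministic.
#'
#' @param matrix numeric sample-by-feature matrix.
#' @param labels class label per row (>= 2 classes present).
#' @param n_selected number of features to keep.
#' @return list with `matrix`, `kept` (original indices, ascending) and
#'   `f_statistics` for all input columns.
#' @export
select_features_anova <- function(matrix, labels, n_selected) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("feature selection needs at least two classes", call. = FALSE)
  }
  n_selected <- as.integer(n_selected)
  if (n_selected < 1L || n_selected > ncol(matrix)) {
    stop("n_selected must be in 1..ncol(matrix)", call. = FALSE)
  }
  fs <- anova_f_statistics(matrix, labels)
  ord <- order(-fs, seq_along(fs)) # largest F first, ties by low index
  kept <- sort(ord[seq_len(n_selected)])
  list(matrix = matrix[, kept, drop = FALSE], kept = kept, f_statistics = fs)
}

#' Fit a per-column scaling
#'
#' `"minmax"` maps each column affinely onto `[0, 1]` (constant columns
#' map to 0); `"zscore"` centres and scales to unit SD (constant columns
#' map to 0); `"none"` is the identity. The fitted parameters can be
#' applied to held-out rows with [apply_scaling()], which is how the
#' cross-validation pipeline avoids train/test leakage.
#'
#' @param matrix numeric training matrix.
#' @param mode `"minmax"`, `"zscore"` or `"none"`.
#' @return list with `matrix` (scaled training matrix) and `params`
#'   (reusable transform description).
#' @export
scale_features <- function(matrix, mode = c("minmax", "zscore", "none")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(matrix), nrow(matrix) >= 1L)
  params <- switch(mode,
    minmax = {
      lo <- apply(matrix, 2L, min)
      hi <- apply(matrix, 2L, max)
      list(mode = mode, center = lo, scale = ifelse(hi > lo, hi - lo, Inf))
    },
    zscore = {
      mu <- colMeans(matrix)
      s <- apply(matrix, 2L, sd)
      list(mode = mode, center = mu, scale = ifelse(s > 0, s, Inf))
    },
    none = list(mode = mode, center = NULL, scale = NULL)
  )
  list(matrix = apply_scaling(params, matrix), params = params)
}

#' Apply a fitted scaling to new rows
#' @param params `params` element returned by [scale_features()].
#' @param matrix numeric matrix with the same columns as the fit data.
#' @return scaled matrix.
#' @export
apply_scaling <- function(params, matrix) {
  if (params$mode == "none") return(matrix)
  # Inf scale encodes a constant training column: output identically 0
  sweep(sweep(matrix, 2L, params$center), 2L, params$scale, "/")
}

#' Preprocessing pipeline specification
#'
#' The generic filter/select/scale recipe applied per omics block:
#' variance filter, then univariate ANOVA-F selection, then column
#' scaling. In cross-validation the pipeline is always fitted on the
#' training rows only and applied to the held-out rows.
#'
#' @param variance_threshold variance cut-off (see [variance_filter()]).
#' @param n_selected_features features kept per block after filtering;
#'   `NULL` keeps all.
#' @param scale scaling mode (see [scale_features()]).
#' @return a `preprocess_spec` list.
#' @export
preprocess_spec <- function(variance_threshold = 0,
                            n_selected_features = NULL,
                            scale = c("minmax", "zscore", "none")) {
  structure(
    list(
      variance_threshold = as.numeric(variance_threshold),
      n_selected_features = if (!is.null(n_selected_features)) {
        as.integer(n_selected_features)
      },
      scale = match.arg(scale)
    ),
    class = "preprocess_spec"
  )
}

#' Fit the filter/select/scale pipeline on training rows
#'
#' @param matrix full sample-by-feature matrix of one omics block.
#' @param labels class labels aligned with `matrix` rows.
#' @param train_idx rows the pipeline may look at while fitting.
#' @param spec a [preprocess_spec()].
#' @return a `fitted_preprocess` with `kept` (original column indices)
#'   and `scaling` params; apply with [apply_preprocess()].
#' @export
fit_preprocess <- function(matrix, labels, train_idx, spec) {
  stopifnot(inherits(spec, "preprocess_spec"))
  tr <- matrix[train_idx, , drop = FALSE]
  vf <- variance_filter(tr, spec$variance_threshold)
  kept <- vf$kept
  if (!is.null(spec$n_selected_features)) {
    n_sel <- min(spec$n_selected_features, length(kept))
    sel <- select_features_anova(vf$matrix, labels[train_idx], n_sel)
    kept <- kept[sel$kept]
  }
  sc <- scale_features(matrix[train_idx, kept, drop = FALSE], spec$scale)
  structure(list(kept = kept, scaling = sc$params),
            class = "fitted_preprocess")
}

#' Apply a fitted preprocessing pipeline
#' @param fit a `fitted_preprocess` from [fit_preprocess()].
#' @param matrix matrix with the original (pre-filter) columns.
#' @return reduced, scaled matrix.
#' @export
apply_preprocess <- function(fit, matrix) {
  stopifnot(inherits(fit, "fitted_preprocess"))
  apply_scaling(fit$scaling, matrix[, fit$kept, drop = FALSE])
}
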