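#' Stratified fold assignment
#'
#' Splits samples into `n_folds` test folds with class proportions
#' preserved; fold sizes differ by at most one within each class.
#' Deterministic given the seed.
#'
#' @param labels integer class labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector assigning each sample a fold in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 2L, length(labels) >= n_folds)
  if (min(table(labels)) < n_folds) {
    stop("a class has fewer samples than folds", call. = FALSE)
  }
  fold <- integer(length(labels))
  pos <- 0L
  withr::with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(labels)) {
      ix <- sample(which(labels == cl))
      # continue the fold cycle across classes so total fold sizes stay
      # within 1 of each other while every class is spread over folds
      fold[ix] <- (pos + seq_along(ix) - 1L) %% n_folds + 1L
      pos <- pos + length(ix)
    }
  })
  fold
}

# stratified single train/test split (test_fraction held out)
stratified_split <- function(labels, test_fraction, seed) {
  test <- integer(0)
  withr::with_seed(derive_seed(seed, "split"), {
    for (cl in unique(labels)) {
      ix <- sample(which(labels == cl))
      n_test <- max(1L, round(test_fraction * length(ix)))
      test <- c(test, ix[seq_len(n_test)])
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

# fit on train_idx (with optional per-fold preprocessing) and return
# test metrics plus the fused opinion over all samples
fit_and_score <- function(dataset, train_idx, test_idx, config,
                          preprocess = NULL) {
  ds <- dataset
  if (!is.null(preprocess)) {
    ds$matrices <- lapply(dataset$matrices, function(X) {
      fp <- fit_preprocess(X, dataset$labels, train_idx, preprocess)
      apply_preprocess(fp, X)
    })
  }
  model <- train_model(ds, train_idx, config)
  fused <- model_fused_opinion(model, ds$matrices)
  pred <- max.col(fused$P, ties.method = "first") - 1L
  metrics <- compute_metrics(
    dataset$labels[test_idx], pred[test_idx],
    scores = fused$P[test_idx, , drop = FALSE]
  )
  list(metrics = metrics, model = model, fused = fused, pred = pred)
}

#' Stratified k-fold cross-validation
#'
#' The reference evaluation protocol: stratified folds (default 5, i.e.
#' 80% train / 20% test), a fresh model per fold, metrics on the held
#' out fold, and mean +/- SD across folds. Any preprocessing is fitted
#' per fold on the training rows only.
#'
#' @param dataset a [multiomics_dataset()].
#' @param config a [run_config()]; its seed drives fold assignment and
#'   all per-fold training.
#' @param n_folds number of folds.
#' @param preprocess optional [preprocess_spec()] applied per omics
#'   block, fitted within each fold.
#' @return an [experiment_report()] with attribute `fold_assignment`.
#' @export
cross_validate <- function(dataset, config = run_config(), n_folds = 5L,
                           preprocess = NULL) {
  fold <- stratified_folds(dataset$labels, n_folds, config$seed)
  per_fold <- lapply(seq_len(n_folds), function(f) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "fold", f)
    fit_and_score(dataset, train_idx, test_idx, cfg, preprocess)$metrics
  })
  rep <- experiment_report(per_fold, config, config$seed)
  attr(rep, "fold_assignment") <- fold
  rep
}

#' Noise-robustness experiment
#'
#' Adds Gaussian noise of increasing standard deviation to one omics
#' block (before hypergraph construction, so structure degradation is
#' part of the measurement), retrains on a stratified split, and records
#' test accuracy and the mean fused uncertainty of the test samples.
#' Each sigma is repeated with distinct derived seeds.
#'
#' @param dataset a [multiomics_dataset()].
#' @param config a [run_config()] (fusion must be `"trusted"` for the
#'   uncertainty column to be defined).
#' @param sigmas non-negative noise SDs; should include 0 as reference.
#' @param target_omics name or index of the block to corrupt.
#' @param n_repeats repeats per sigma.
#' @return data.frame with one row per sigma: mean/sd of ACC and of the
#'   mean test-set uncertainty; per-repeat values in attribute
#'   `per_repeat`.
#' @export
noise_experiment <- function(dataset, config = run_config(),
                             sigmas = c(0, 0.5, 1, 2, 5),
                             target_omics = 1L, n_repeats = 3L) {
  stopifnot(all(sigmas >= 0))
  if (is.character(target_omics)) {
    target_omics <- match(target_omics, dataset$omics_names)
  }
  rows <- list()
  for (si in seq_along(sigmas)) {
    for (r in seq_len(n_repeats)) {
      seed_r <- derive_seed(config$seed, "noise-rep", r)
      noisy <- dataset
      noisy$matrices[[target_omics]] <- add_gaussian_noise(
        dataset$matrices[[target_omics]], sigmas[si],
        derive_seed(seed_r, "sigma", si)
      )
      sp <- stratified_split(dataset$labels, config$test_fraction, seed_r)
      cfg <- config
      cfg$seed <- seed_r
      fit <- fit_and_score(noisy, sp$train, sp$test, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma = sigmas[si], rep = r,
        acc = unname(fit$metrics["ACC"]),
        mean_u = mean(fit$fused$U[sp$test])
      )
    }
  }
  per_repeat <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_repeat, per_repeat$sigma), function(d) {
    data.frame(sigma = d$sigma[1L],
               acc_mean = mean(d$acc), acc_sd = sd(d$acc),
               mean_u = mean(d$mean_u), mean_u_sd = sd(d$mean_u))
  }))
  agg <- agg[order(agg$sigma), ]
  rownames(agg) <- NULL
  attr(agg, "per_repeat") <- per_repeat
  agg
}

#' Ablation experiments
#'
#' Re-runs cross-validation under controlled variants of one design
#' axis, with identical seeds (hence identical folds) across variants:
#'
#' * `"structure"` — hypergraph Laplacian vs normalised graph adjacency;
#' * `"fusion"` — trusted evidential fusion vs mean-evidence softmax;
#' * `"similarity"` — cosine vs Euclidean neighbourhoods;
#' * `"k_sweep"` — hyperedge sizes in `ks`;
#' * `"omics_subsets"` — every non-empty subset of the omics blocks.
#'
#' @param dataset a [multiomics_dataset()].
#' @param config base [run_config()].
#' @param axis which axis to ablate.
#' @param ks hyperedge sizes for `"k_sweep"`.
#' @param n_folds folds per variant.
#' @return data.frame with one row per variant (mean and sd of each
#'   metric); full reports in attribute `reports`.
#' @export
ablation_run <- function(dataset, config = run_config(),
                         axis = c("structure", "fusion", "similarity",
                                  "k_sweep", "omics_subsets"),
                         ks = c(1L, 5L, 10L), n_folds = 5L) {
  axis <- match.arg(axis)
  variants <- switch(axis,
    structure = {
      v <- lapply(c("hypergraph", "graph"), function(s) {
        cfg <- config
        cfg$structure <- s
        list(label = s, config = cfg, omics = NULL)
      })
      v
    },
    fusion = lapply(c("trusted", "mean_evidence"), function(f) {
      cfg <- config
      cfg$fusion <- f
      list(label = f, config = cfg, omics = NULL)
    }),
    similarity = lapply(c("cosine", "euclidean"), function(s) {
      cfg <- config
      cfg$similarity <- s
      list(label = s, config = cfg, omics = NULL)
    }),
    k_sweep = lapply(ks, function(k) {
      cfg <- config
      cfg$k_neighbors <- as.integer(k)
      list(label = paste0("k=", k), config = cfg, omics = NULL)
    }),
    omics_subsets = {
      nms <- dataset$omics_names
      subsets <- unlist(lapply(seq_along(nms), function(sz) {
        utils::combn(nms, sz, simplify = FALSE)
      }), recursive = FALSE)
      lapply(subsets, function(s) {
        list(label = paste(s, collapse = "+"), config = config, omics = s)
      })
    }
  )
  reports <- list()
  rows <- list()
  for (v in variants) {
    ds <- dataset
    if (!is.null(v$omics)) {
      ds$matrices <- dataset$matrices[v$omics]
      ds$omics_names <- v$omics
    }
    rep <- cross_validate(ds, v$config, n_folds)
    reports[[v$label]] <- rep
    rows[[v$label]] <- data.frame(
      variant = v$label,
      t(setNames(rep$mean, paste0(names(rep$mean), "_mean"))),
      t(setNames(rep$std, paste0(names(rep$std), "_sd")))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Permutation feature importance through the fitted model
#'
#' Wrapper-style importance: for every retained feature, permute its
#' column across samples, re-run the per-omics networks and fusion
#' (structures fixed), and record the drop in test accuracy; repeats
#' with different permutation seeds are averaged. Constant columns get
#' importance exactly 0.
#'
#' @param model a fitted `trusted_model`.
#' @param dataset the dataset the model was trained on.
#' @param config [run_config()] providing the seed for permutations.
#' @param n_repeats permutations per feature.
#' @param test_idx samples to score (default: complement of the model's
#'   training indices).
#' @return data.frame ranked by descending importance (ties by omics
#'   then ascending feature index): `omics`, `feature_index`, `feature`,
#'   `importance`, `rank`.
#' @export
feature_importance <- function(model, dataset, config = model$config,
                               n_repeats = 3L, test_idx = NULL) {
  stopifnot(inherits(model, "trusted_model"))
  test_idx <- test_idx %||%
    setdiff(seq_len(n_samples(dataset)), model$train_idx)
  y_test <- dataset$labels[test_idx]
  base_fused <- model_fused_opinion(model, dataset$matrices)
  base_acc <- mean((max.col(base_fused$P, ties.method = "first") - 1L)[test_idx] == y_test)

  # evidence of untouched blocks never changes: cache it once
  evid0 <- base_fused$evidences
  rows <- list()
  for (o in seq_along(dataset$matrices)) {
    X <- dataset$matrices[[o]]
    for (j in seq_len(ncol(X))) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        perm <- withr::with_seed(
          derive_seed(config$seed, sprintf("perm-%d-%d", o, j), r),
          sample(nrow(X))
        )
        if (all(X[perm, j] == X[, j])) return(0) # constant column
        Xp <- X
        Xp[, j] <- X[perm, j]
        ev <- evid0
        ev[[o]] <- hgcn_forward(Xp, model$operators[[o]], model$params[[o]],
                                model$specs[[o]])$evidence
        P <- if (model$config$fusion == "trusted") {
          ds_combine_all(lapply(ev, opinion_from_evidence))$P
        } else {
          softmax_rows(Reduce(`+`, ev) / length(ev))
        }
        acc <- mean((max.col(P, ties.method = "first") - 1L)[test_idx] == y_test)
        base_acc - acc
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        omics = dataset$omics_names[o],
        feature_index = j,
        feature = colnames(X)[j] %||% paste0("f", j),
        importance = mean(drops)
      )
    }
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$importance, match(out$omics, dataset$omics_names),
               out$feature_index)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
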