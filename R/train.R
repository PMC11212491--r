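adam_state <- function(params) {
  zero <- function(x) list(m = x * 0, v = x * 0)
  list(
    conv = lapply(params$conv, zero),
    fc = list(W = zero(params$fc$W), b = zero(params$fc$b))
  )
}

# one Adam update over an hgcn_params / gradient pair (nested lists)
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  for (l in seq_along(params$conv)) {
    r <- step(params$conv[[l]], grads$conv[[l]], state$conv[[l]])
    params$conv[[l]] <- r$p
    state$conv[[l]] <- r$s
  }
  for (nm in c("W", "b")) {
    r <- step(params$fc[[nm]], grads$fc[[nm]], state$fc[[nm]])
    params$fc[[nm]] <- r$p
    state$fc[[nm]] <- r$s
  }
  list(params = params, state = state)
}

add_weight_decay <- function(grads, params, wd) {
  if (wd == 0) return(grads)
  for (l in seq_along(params$conv)) {
    grads$conv[[l]] <- grads$conv[[l]] + wd * params$conv[[l]]
  }
  grads$fc$W <- grads$fc$W + wd * params$fc$W
  grads
}

# loss + per-network parameter gradients for the whole model at one epoch
model_loss_and_grads <- function(Xs, operators, params_list, specs, y,
                                 sample_mask, epoch, config) {
  n_omics <- length(Xs)
  fw <- lapply(seq_len(n_omics), function(o) {
    hgcn_forward(Xs[[o]], operators[[o]], params_list[[o]], specs[[o]],
                 keep_cache = TRUE)
  })
  evidences <- lapply(fw, `[[`, "evidence")
  fuse <- if (config$fusion == "trusted") {
    trusted_loss_and_evidence_grads(evidences, y, sample_mask,
                                    epoch, config$annealing_step)
  } else {
    mean_evidence_loss_and_grads(evidences, y, sample_mask)
  }
  grads <- lapply(seq_len(n_omics), function(o) {
    g <- hgcn_backward(fuse$grads[[o]], Xs[[o]], operators[[o]],
                       params_list[[o]], specs[[o]], fw[[o]]$cache)
    add_weight_decay(g, params_list[[o]], config$weight_decay)
  })
  list(loss = fuse$loss, grads = grads, evidences = evidences, fuse = fuse)
}

#' Train the trusted multi-omics classifier
#'
#' Builds one KNN structure operator and one evidence network per omics
#' block, then trains all networks jointly, full-batch, with Adam on the
#' evidential loss (fused + per-omics terms) evaluated on the training
#' samples only. Training is transductive: the structure spans all
#' samples, labels of non-training samples are never used.
#'
#' @param dataset a [multiomics_dataset()].
#' @param train_idx integer indices of the labelled training samples;
#'   every class must appear among them.
#' @param config a [run_config()].
#' @param operators optional precomputed list of structure operators
#'   (one n-by-n matrix per omics), e.g. to share structures across
#'   ablation variants.
#' @return a `trusted_model`: per-omics parameters and operators, the
#'   config, training indices and the per-epoch loss trace.
#' @export
train_model <- function(dataset, train_idx, config = run_config(),
                        operators = NULL) {
  stopifnot(inherits(dataset, "multiomics_dataset"), length(train_idx) >= 1L)
  b <- dataset$n_classes
  present <- sort(unique(dataset$labels[train_idx]))
  if (!identical(present, 0:(b - 1L))) {
    stop("every class must be represented in the training split",
         call. = FALSE)
  }
  if (config$k_neighbors > n_samples(dataset)) {
    stop("k_neighbors exceeds the number of samples", call. = FALSE)
  }
  Xs <- lapply(dataset$matrices, unname)
  if (is.null(operators)) {
    operators <- lapply(Xs, function(X) {
      build_structure_operator(X, config$k_neighbors,
                               config$similarity, config$structure)$operator
    })
  }
  specs <- lapply(Xs, function(X) {
    hgcn_spec(ncol(X), config$hidden_dims, b,
              config$leaky_slope, config$evidence_activation)
  })
  params_list <- lapply(seq_along(Xs), function(o) {
    init_hgcn_params(specs[[o]], derive_seed(config$seed, "params", o))
  })
  y <- one_hot(dataset$labels, b)

  state <- lapply(params_list, adam_state)
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lg <- model_loss_and_grads(Xs, operators, params_list, specs, y,
                               train_idx, epoch - 1L, config)
    trace[epoch] <- lg$loss
    if (!is.finite(lg$loss)) {
      stop("non-finite training loss at epoch ", epoch, call. = FALSE)
    }
    for (o in seq_along(params_list)) {
      upd <- adam_update(params_list[[o]], lg$grads[[o]], state[[o]],
                         config$learning_rate, epoch)
      params_list[[o]] <- upd$params
      state[[o]] <- upd$state
    }
  }
  structure(
    list(
      params = params_list,
      specs = specs,
      operators = operators,
      omics_names = dataset$omics_names,
      n_classes = b,
      config = config,
      train_idx = sort(as.integer(train_idx)),
      loss_trace = trace
    ),
    class = "trusted_model"
  )
}

# forward all networks and fuse; optionally with replaced feature blocks
model_fused_opinion <- function(model, Xs) {
  evidences <- lapply(seq_along(Xs), function(o) {
    hgcn_forward(Xs[[o]], model$operators[[o]], model$params[[o]],
                 model$specs[[o]])$evidence
  })
  if (model$config$fusion == "trusted") {
    fused <- ds_combine_all(lapply(evidences, opinion_from_evidence))
    list(P = fused$P, U = fused$U, evidences = evidences)
  } else {
    Fbar <- Reduce(`+`, evidences) / length(evidences)
    list(P = softmax_rows(Fbar), U = rep(NA_real_, nrow(Fbar)),
         evidences = evidences)
  }
}

#' Predict classes, confidences and uncertainties
#'
#' Runs every per-omics network on the stored structure operators, fuses
#' the resulting opinions, and predicts the class with the highest fused
#' confidence (ties resolved towards the lowest class index). For the
#' trusted fusion the per-sample uncertainty `u` is reported; the
#' mean-evidence baseline has no uncertainty notion and reports `NA`.
#'
#' @param object a `trusted_model` from [train_model()].
#' @param dataset the dataset the model was fitted on (the structure is
#'   transductive, so the samples must match).
#' @param idx samples to report (default all).
#' @param ... unused.
#' @return data.frame with `sample_id`, `true`, `pred`, fused
#'   confidences `p_0 .. p_{b-1}` and uncertainty `u`.
#' @export
predict.trusted_model <- function(object, dataset, idx = NULL, ...) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  idx <- idx %||% seq_len(n_samples(dataset))
  fused <- model_fused_opinion(object, dataset$matrices)
  pred <- max.col(fused$P, ties.method = "first") - 1L
  out <- data.frame(
    sample_id = dataset$sample_ids[idx],
    true = dataset$labels[idx],
    pred = pred[idx],
    stringsAsFactors = FALSE
  )
  P <- fused$P[idx, , drop = FALSE]
  colnames(P) <- paste0("p_", seq_len(ncol(P)) - 1L)
  out <- cbind(out, as.data.frame(P))
  out$u <- fused$U[idx]
  out
}

#' @export
print.trusted_model <- function(x, ...) {
  cat(sprintf(
    "trusted_model: %d omics network(s), %d classes, %s fusion, %s structure\n",
    length(x$params), x$n_classes, x$config$fusion, x$config$structure
  ))
  cat(sprintf("  trained %d epochs, final loss %.4f, %d training samples\n",
              length(x$loss_trace), x$loss_trace[length(x$loss_trace)],
              length(x$train_idx)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive holding the architecture specs, weights,
#' structure operators and config, at full numeric precision.
#'
#' @param model a `trusted_model`.
#' @param path output file.
#' @return `save_checkpoint`: invisibly, `path`. `load_checkpoint`: the
#'   restored `trusted_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "trusted_model"))
  strip <- function(x) {
    if (is.list(x)) {
      lapply(x, strip)
    } else {
      x
    }
  }
  jsonlite::write_json(strip(unclass(model)), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  to_mat <- function(x) if (is.list(x)) lapply(x, to_mat) else as.matrix(x)
  model <- list(
    params = lapply(raw$params, function(p) {
      structure(list(
        conv = lapply(p$conv, as.matrix),
        fc = list(W = as.matrix(p$fc$W), b = as.numeric(p$fc$b))
      ), class = "hgcn_params")
    }),
    specs = lapply(raw$specs, function(s) {
      do.call(hgcn_spec, s[c("input_dim", "hidden_dims", "n_classes",
                             "leaky_slope", "evidence_activation")])
    }),
    operators = lapply(raw$operators, as.matrix),
    omics_names = raw$omics_names,
    n_classes = as.integer(raw$n_classes),
    config = do.call(run_config, raw$config),
    train_idx = as.integer(raw$train_idx),
    loss_trace = as.numeric(raw$loss_trace)
  )
  class(model) <- "trusted_model"
  model
}
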