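#' Run configuration
#'
#' Collects every tunable of the end-to-end classifier. Defaults are the
#' package's desk-scale working configuration; all of them can be
#' overridden per call or from a YAML file ([load_run_config()]).
#'
#' @param k_neighbors hyperedge size k: each hyperedge holds a sample and
#'   its k-1 most cosine-similar other samples. Must not exceed the
#'   sample count of the dataset it is applied to.
#' @param hidden_dims integer vector; one hypergraph convolution layer
#'   per entry, entry = layer width.
#' @param learning_rate Adam step size.
#' @param epochs full-batch training epochs.
#' @param annealing_step epochs over which the wrong-evidence penalty
#'   weight ramps linearly from 0 to 1.
#' @param seed master integer seed; every random stream derives from it.
#' @param test_fraction held-out fraction for single-split training.
#' @param similarity neighbourhood metric: `"cosine"` similarity or
#'   `"euclidean"` distance.
#' @param fusion `"trusted"` (Dirichlet opinions combined by the reduced
#'   Dempster-Shafer rule) or `"mean_evidence"` (softmax over the
#'   across-omics mean evidence; no uncertainty).
#' @param structure `"hypergraph"` (normalised hypergraph Laplacian
#'   operator) or `"graph"` (symmetrically normalised KNN adjacency).
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param evidence_activation non-negativity head on the final layer:
#'   `"softplus"`, `"relu"` or `"exp"`.
#' @param weight_decay L2 penalty coefficient on all weights.
#' @return a validated `run_config` list.
#' @export
run_config <- function(k_neighbors = 10L,
                       hidden_dims = c(64L, 32L),
                       learning_rate = 1e-3,
                       epochs = 500L,
                       annealing_step = 50L,
                       seed = 1L,
                       test_fraction = 0.2,
                       similarity = c("cosine", "euclidean"),
                       fusion = c("trusted", "mean_evidence"),
                       structure = c("hypergraph", "graph"),
                       leaky_slope = 0.01,
                       evidence_activation = c("softplus", "relu", "exp"),
                       weight_decay = 1e-4) {
  cfg <- list(
    k_neighbors = as.integer(k_neighbors),
    hidden_dims = as.integer(hidden_dims),
    learning_rate = as.numeric(learning_rate),
    epochs = as.integer(epochs),
    annealing_step = as.integer(annealing_step),
    seed = as.integer(seed),
    test_fraction = as.numeric(test_fraction),
    similarity = match.arg(similarity),
    fusion = match.arg(fusion),
    structure = match.arg(structure),
    leaky_slope = as.numeric(leaky_slope),
    evidence_activation = match.arg(evidence_activation),
    weight_decay = as.numeric(weight_decay)
  )
  stopifnot(
    cfg$k_neighbors >= 1L,
    length(cfg$hidden_dims) >= 1L, all(cfg$hidden_dims >= 1L),
    cfg$learning_rate > 0,
    cfg$epochs >= 1L,
    cfg$annealing_step >= 1L,
    cfg$test_fraction > 0, cfg$test_fraction < 1,
    cfg$leaky_slope > 0, cfg$leaky_slope < 1,
    cfg$weight_decay >= 0
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys absent from the file keep their [run_config()] defaults; unknown
#' keys are an error.
#'
#' @param path YAML file whose keys are `run_config` arguments.
#' @param overrides named list applied on top of the file (e.g. a
#'   command-line `--seed`).
#' @return a `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else {
    list()
  }
  vals <- modifyList(vals, overrides)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
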