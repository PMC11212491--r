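#' Specification of a simulated multi-omics study
#'
#' Class-conditional Gaussian blocks with planted informative features.
#' Within each omics block a fraction of columns is informative: those
#' columns receive a class-dependent mean shift of
#' `effect_size * noise_sd`, all other columns are pure
#' `N(0, noise_sd^2)` noise. How the class signal is distributed across
#' blocks is set by `information_split`:
#'
#' * `"redundant"` — every block carries every class contrast (its
#'   informative columns are divided round-robin over the classes; the
#'   columns assigned to class c are shifted for class-c samples).
#' * `"complementary"` — block o only separates class `(o-1) %% b` from
#'   the rest, so any single block is ambiguous between the remaining
#'   classes and only fusion can resolve all of them.
#' * `"one_noisy"` — as `"redundant"` but the last block gets effect
#'   size 0 (pure noise), for robustness experiments.
#'
#' Defaults are the package's reference simulation: 300 samples, 3
#' balanced classes, 3 blocks of 100/80/60 features, 10% informative
#' columns, shift of 5 noise SDs.
#'
#' @param n_samples number of samples.
#' @param n_classes number of classes (balanced to within one sample).
#' @param n_features integer vector, features per omics block; names
#'   become omics names (default `omics1..`).
#' @param informative_fraction fraction of columns per block that carry
#'   class signal, in (0, 1].
#' @param effect_size mean shift on informative columns, in noise-SD
#'   units; 0 gives a null dataset.
#' @param noise_sd Gaussian noise standard deviation.
#' @param information_split `"redundant"`, `"complementary"` or
#'   `"one_noisy"`.
#' @param seed integer seed; the same spec and seed reproduce the
#'   dataset exactly.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 300L,
                           n_classes = 3L,
                           n_features = c(omics1 = 100L, omics2 = 80L, omics3 = 60L),
                           informative_fraction = 0.1,
                           effect_size = 5,
                           noise_sd = 1,
                           information_split = c("redundant", "complementary", "one_noisy"),
                           seed = 1L) {
  spec <- list(
    n_samples = as.integer(n_samples),
    n_classes = as.integer(n_classes),
    n_features = setNames(
      as.integer(n_features),
      names(n_features) %||% paste0("omics", seq_along(n_features))
    ),
    informative_fraction = as.numeric(informative_fraction),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    information_split = match.arg(information_split),
    seed = as.integer(seed)
  )
  if (any(spec$n_features == "" | is.na(names(spec$n_features)))) {
    names(spec$n_features) <- paste0("omics", seq_along(spec$n_features))
  }
  stopifnot(
    spec$n_samples >= spec$n_classes, spec$n_classes >= 2L,
    all(spec$n_features >= 1L),
    spec$informative_fraction > 0, spec$informative_fraction <= 1,
    spec$effect_size >= 0, spec$noise_sd > 0
  )
  class(spec) <- "synthetic_spec"
  spec
}

#' Simulate a multi-omics dataset with planted class structure
#'
#' Draws each block as `N(0, noise_sd^2)` noise and adds class-specific
#' mean shifts on the informative columns according to the spec's
#' `information_split` (see [synthetic_spec()]). The ground truth is
#' attached as attribute `"manifest"`: per block, the informative column
#' indices and the class each column marks.
#'
#' @param spec a [synthetic_spec()].
#' @return a [multiomics_dataset()] with attribute `manifest`, a named
#'   list with per-omics `informative` (column indices) and `marks_class`
#'   (0-based class each informative column shifts).
#' @export
simulate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  b <- spec$n_classes
  labels <- rep_len(0:(b - 1L), n) # balanced to within 1 sample
  sample_ids <- sprintf("S%04d", seq_len(n))

  withr::with_seed(derive_seed(spec$seed, "simulate"), {
    matrices <- list()
    manifest <- list()
    for (o in seq_along(spec$n_features)) {
      nm <- names(spec$n_features)[o]
      d <- spec$n_features[[o]]
      X <- matrix(rnorm(n * d, sd = spec$noise_sd), n, d)
      n_inf <- max(1L, round(spec$informative_fraction * d))
      inf_cols <- seq_len(n_inf)

      eff <- spec$effect_size
      if (spec$information_split == "one_noisy" && o == length(spec$n_features)) {
        eff <- 0
      }
      marks <- if (spec$information_split == "complementary") {
        rep((o - 1L) %% b, n_inf) # this block only separates one class
      } else {
        rep_len(0:(b - 1L), n_inf) # every class contrast present
      }
      if (eff > 0) {
        shift <- eff * spec$noise_sd
        for (j in seq_len(n_inf)) {
          rows <- labels == marks[j]
          X[rows, inf_cols[j]] <- X[rows, inf_cols[j]] + shift
        }
      }
      colnames(X) <- sprintf("%s_f%03d", nm, seq_len(d))
      matrices[[nm]] <- X
      manifest[[nm]] <- list(informative = inf_cols, marks_class = marks)
    }
    ds <- multiomics_dataset(matrices, labels, sample_ids, n_classes = b)
    attr(ds, "manifest") <- manifest
    ds
  })
}

#' Add entrywise Gaussian noise to a matrix
#'
#' `sigma = 0` returns the input unchanged. Used by the noise-robustness
#' experiment to corrupt one omics block before hypergraph construction.
#'
#' @param matrix numeric matrix.
#' @param sigma noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return matrix of the same shape.
#' @export
add_gaussian_noise <- function(matrix, sigma, seed) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(matrix)
  withr::with_seed(derive_seed(seed, "noise"), {
    matrix + matrix(rnorm(length(matrix), sd = sigma),
                    nrow(matrix), ncol(matrix))
  })
}
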