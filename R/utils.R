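`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific RNG seed from a master seed
#'
#' All stochastic steps (fold splits, weight initialisation, simulated
#' noise, permutations) draw their seed from one master integer through
#' this function, so a run is reproducible from a single seed while the
#' streams stay decoupled.
#'
#' @param seed master integer seed.
#' @param what character tag naming the consumer stream.
#' @param index optional integer distinguishing repeats within a stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, what, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps results in integer range
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(seed) %% m * 48271 + h * 69621 + index * 16807) %% m)
}

softplus <- function(x) {
  # log(1 + exp(x)), overflow-safe: for large x, log1p(exp(x)) ~ x
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

one_hot <- function(labels, n_classes) {
  stopifnot(all(labels >= 0L), all(labels < n_classes))
  y <- matrix(0, length(labels), n_classes)
  y[cbind(seq_along(labels), labels + 1L)] <- 1
  y
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(x)
}
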