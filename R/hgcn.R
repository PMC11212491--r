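#' Architecture of one per-omics hypergraph convolutional network
#'
#' Stacked spectral convolutions on the normalised hypergraph Laplacian
#' (`LeakyReLU(Lh %*% H %*% Z)` per layer), one fully connected layer to
#' `n_classes` outputs, and a non-negativity head so the output can act
#' as Dirichlet evidence.
#'
#' @param input_dim feature count d of the omics block.
#' @param hidden_dims widths of the convolution layers (>= 1 layer).
#' @param n_classes output dimension b (>= 2).
#' @param leaky_slope LeakyReLU negative slope in (0, 1).
#' @param evidence_activation `"softplus"` (default, smooth), `"relu"`
#'   or `"exp"`.
#' @return an `hgcn_spec` list.
#' @export
hgcn_spec <- function(input_dim, hidden_dims = c(64L, 32L), n_classes,
                      leaky_slope = 0.01,
                      evidence_activation = c("softplus", "relu", "exp")) {
  spec <- list(
    input_dim = as.integer(input_dim),
    hidden_dims = as.integer(hidden_dims),
    n_classes = as.integer(n_classes),
    leaky_slope = as.numeric(leaky_slope),
    evidence_activation = match.arg(evidence_activation)
  )
  stopifnot(
    spec$input_dim >= 1L, length(spec$hidden_dims) >= 1L,
    all(spec$hidden_dims >= 1L), spec$n_classes >= 2L,
    spec$leaky_slope > 0, spec$leaky_slope < 1
  )
  class(spec) <- "hgcn_spec"
  spec
}

glorot_uniform <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialise network parameters
#'
#' Glorot-uniform weights, zero fully-connected bias; deterministic
#' given the seed.
#'
#' @param spec an [hgcn_spec()].
#' @param seed integer seed.
#' @return `hgcn_params`: list with `conv` (list of weight matrices) and
#'   `fc` (`W`, `b`).
#' @export
init_hgcn_params <- function(spec, seed) {
  stopifnot(inherits(spec, "hgcn_spec"))
  withr::with_seed(derive_seed(seed, "init"), {
    dims <- c(spec$input_dim, spec$hidden_dims)
    conv <- lapply(seq_len(length(dims) - 1L), function(l) {
      glorot_uniform(dims[l], dims[l + 1L])
    })
    fc <- list(
      W = glorot_uniform(dims[length(dims)], spec$n_classes),
      b = numeric(spec$n_classes)
    )
    structure(list(conv = conv, fc = fc), class = "hgcn_params")
  })
}

#' One hypergraph convolution layer
#'
#' `LeakyReLU(Lh %*% Hin %*% Z)`: the Laplacian smooths each feature
#' channel over hyperedge neighbourhoods, the weight matrix mixes
#' channels, the activation adds non-linearity without dead units.
#'
#' @param Hin n-by-c input activations.
#' @param Lh n-by-n operator (normalised hypergraph Laplacian).
#' @param Z c-by-c' weight matrix.
#' @param slope LeakyReLU negative slope.
#' @return n-by-c' matrix.
#' @export
hgconv_layer <- function(Hin, Lh, Z, slope = 0.01) {
  stopifnot(ncol(Lh) == nrow(Hin), ncol(Hin) == nrow(Z))
  leaky_relu(Lh %*% Hin %*% Z, slope)
}

evidence_head <- function(O, activation) {
  switch(activation,
    softplus = softplus(O),
    relu = pmax(O, 0),
    exp = exp(pmin(O, 30)) # capped to keep evidence finite
  )
}

#' Forward pass of the evidence network
#'
#' Stacks the convolution layers, applies the fully connected layer and
#' the non-negativity head. With `keep_cache = TRUE` the intermediate
#' activations needed by the internal backward pass are attached.
#'
#' @param X n-by-d feature matrix.
#' @param Lh n-by-n operator.
#' @param params an `hgcn_params`.
#' @param spec the matching [hgcn_spec()].
#' @param keep_cache retain intermediates for backpropagation.
#' @return list with `evidence` (n-by-b, non-negative) and, if
#'   requested, `cache`.
#' @export
hgcn_forward <- function(X, Lh, params, spec, keep_cache = FALSE) {
  stopifnot(ncol(X) == spec$input_dim)
  H <- X
  Ms <- list() # Lh %*% H_{l-1}, reused in backward
  As <- list() # pre-activations
  for (l in seq_along(params$conv)) {
    M <- Lh %*% H
    A <- M %*% params$conv[[l]]
    H <- leaky_relu(A, spec$leaky_slope)
    if (keep_cache) {
      Ms[[l]] <- M
      As[[l]] <- A
    }
  }
  O <- H %*% params$fc$W + rep(params$fc$b, each = nrow(H))
  FE <- evidence_head(O, spec$evidence_activation)
  if (!all(is.finite(FE))) {
    stop("non-finite activations in evidence head", call. = FALSE)
  }
  out <- list(evidence = FE)
  if (keep_cache) {
    out$cache <- list(Ms = Ms, As = As, H_last = H, O = O)
  }
  out
}

# Backpropagate d(loss)/d(evidence) to parameter gradients.
# Returns gradients with the same shape as `params`.
hgcn_backward <- function(dF, X, Lh, params, spec, cache) {
  dO <- switch(spec$evidence_activation,
    softplus = dF * sigmoid(cache$O),
    relu = dF * (cache$O > 0),
    exp = dF * evidence_head(cache$O, "exp") * (cache$O < 30)
  )
  gW <- crossprod(cache$H_last, dO)
  gb <- colSums(dO)
  dH <- tcrossprod(dO, params$fc$W)
  g_conv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    dA <- dH * ifelse(cache$As[[l]] > 0, 1, spec$leaky_slope)
    g_conv[[l]] <- crossprod(cache$Ms[[l]], dA)
    if (l > 1L) {
      dH <- Lh %*% tcrossprod(dA, params$conv[[l]]) # Lh symmetric
    }
  }
  list(conv = g_conv, fc = list(W = gW, b = gb))
}
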