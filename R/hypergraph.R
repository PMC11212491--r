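#' Pairwise cosine similarity between sample rows
#'
#' `S[i, j] = x_i . x_j / (||x_i|| ||x_j||)`. Rows with zero norm have
#' no defined angle; by convention they get similarity 0 to every other
#' row and 1 to themselves, so downstream KNN selection never sees NaN.
#'
#' @param X numeric n-by-d matrix, n >= 2.
#' @return symmetric n-by-n matrix with entries in `[-1, 1]`.
#' @export
cosine_similarity_matrix <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  Xn <- X / nrm
  S <- tcrossprod(Xn)
  S[zero, ] <- 0
  S[, zero] <- 0
  diag(S) <- 1
  S
}

#' Pairwise Euclidean distance between sample rows
#'
#' Kept as the traditional neighbourhood metric for the
#' similarity-ablation comparison against cosine similarity.
#'
#' @param X numeric n-by-d matrix, n >= 2.
#' @return symmetric non-negative n-by-n matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  D <- as.matrix(stats::dist(X, method = "euclidean"))
  dimnames(D) <- NULL
  D
}

#' Build the KNN hypergraph incidence structure
#'
#' One hyperedge per sample: hyperedge `e_v` contains vertex v itself
#' plus its k-1 nearest neighbours under the given affinity matrix
#' (most similar in `"similarity"` mode, least distant in `"distance"`
#' mode). Ties are broken by ascending vertex index. The incidence
#' matrix G is n-by-n (rows vertices, columns hyperedges), every column
#' sums to k.
#'
#' @param S n-by-n affinity matrix (similarity or distance).
#' @param k hyperedge size, `1 <= k <= n`.
#' @param mode `"similarity"` (larger is closer) or `"distance"`.
#' @return a `hypergraph_structure` with fields `incidence` (G),
#'   `vertex_degrees`, `edge_degrees`, `k`; the Laplacian is filled in by
#'   [hypergraph_laplacian()].
#' @export
build_incidence <- function(S, k, mode = c("similarity", "distance")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  n <- nrow(S)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must be in 1..n", call. = FALSE)
  G <- matrix(0, n, n)
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    if (k > 1L) {
      key <- S[v, others]
      if (mode == "similarity") key <- -key # order(): smallest first
      picked <- others[order(key, others)][seq_len(k - 1L)]
    } else {
      picked <- integer(0)
    }
    G[c(v, picked), v] <- 1
  }
  structure(
    list(
      incidence = G,
      vertex_degrees = rowSums(G),
      edge_degrees = colSums(G),
      k = k,
      laplacian = NULL
    ),
    class = "hypergraph_structure"
  )
}

#' Normalised hypergraph Laplacian
#'
#' `Lh = Dv^{-1/2} G De^{-1} G^T Dv^{-1/2}` with Dv/De the diagonal
#' vertex/hyperedge degree matrices. All hyperedges carry weight 1. Lh is
#' symmetric positive semidefinite with eigenvalues in `[0, 1]`; it acts
#' as the smoothing operator inside each convolution layer.
#'
#' @param H a `hypergraph_structure` from [build_incidence()].
#' @return the same structure with `laplacian` filled in.
#' @export
hypergraph_laplacian <- function(H) {
  stopifnot(inherits(H, "hypergraph_structure"))
  G <- H$incidence
  dv_isqrt <- 1 / sqrt(H$vertex_degrees)
  de_inv <- 1 / H$edge_degrees
  # Dv^{-1/2} G De^{-1} G^T Dv^{-1/2}, kept dense (n is desk-scale)
  M <- (dv_isqrt * G) %*% (de_inv * t(G) * rep(dv_isqrt, each = nrow(G)))
  H$laplacian <- (M + t(M)) / 2 # exact symmetry against rounding
  H
}

#' Symmetrically normalised KNN graph adjacency
#'
#' Plain-graph counterpart used by the structure ablation: each vertex
#' links to its k nearest neighbours (self included), the adjacency is
#' symmetrised by `A <- max(A, A^T)`, and the convolution operand is
#' `D^{-1/2} A D^{-1/2}`.
#'
#' @param S affinity matrix as in [build_incidence()].
#' @param k neighbourhood size including self.
#' @param mode `"similarity"` or `"distance"`.
#' @return symmetric n-by-n operator matrix.
#' @export
simple_graph_operator <- function(S, k, mode = c("similarity", "distance")) {
  mode <- match.arg(mode)
  H <- build_incidence(S, k, mode)
  A <- pmax(H$incidence, t(H$incidence)) # mutualise directed KNN
  d_isqrt <- 1 / sqrt(rowSums(A))
  M <- d_isqrt * A * rep(d_isqrt, each = nrow(A))
  (M + t(M)) / 2
}

#' Build the convolution operator for one omics block
#'
#' Convenience wrapper: affinity matrix (cosine or Euclidean) -> KNN
#' structure (hypergraph or plain graph) -> normalised operator.
#'
#' @param X sample-by-feature matrix.
#' @param k neighbourhood size.
#' @param similarity `"cosine"` or `"euclidean"`.
#' @param structure `"hypergraph"` or `"graph"`.
#' @return list with `operator` (n-by-n matrix fed to the network) and,
#'   for hypergraphs, the full `hypergraph_structure`.
#' @export
build_structure_operator <- function(X, k,
                                     similarity = c("cosine", "euclidean"),
                                     structure = c("hypergraph", "graph")) {
  similarity <- match.arg(similarity)
  structure <- match.arg(structure)
  if (similarity == "cosine") {
    S <- cosine_similarity_matrix(X)
    mode <- "similarity"
  } else {
    S <- euclidean_distance_matrix(X)
    mode <- "distance"
  }
  if (structure == "hypergraph") {
    H <- hypergraph_laplacian(build_incidence(S, k, mode))
    list(operator = H$laplacian, hypergraph = H)
  } else {
    list(operator = simple_graph_operator(S, k, mode), hypergraph = NULL)
  }
}

#' Dump a hypergraph's incidence and Laplacian as MatrixMarket files
#'
#' Debug helper; writes `incidence.mtx` (coordinate, pattern-like 0/1
#' entries) and `laplacian.mtx` (coordinate, real) into `dir`.
#'
#' @param H a `hypergraph_structure` (Laplacian may be NULL).
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
dump_hypergraph_mtx <- function(H, dir) {
  stopifnot(inherits(H, "hypergraph_structure"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx <- function(M, path) {
    ix <- which(M != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("%%MatrixMarket matrix coordinate real general", con)
    writeLines(sprintf("%d %d %d", nrow(M), ncol(M), nrow(ix)), con)
    writeLines(sprintf("%d %d %.17g", ix[, 1L], ix[, 2L], M[ix]), con)
    path
  }
  out <- c(write_mtx(H$incidence, file.path(dir, "incidence.mtx")))
  if (!is.null(H$laplacian)) {
    out <- c(out, write_mtx(H$laplacian, file.path(dir, "laplacian.mtx")))
  }
  invisible(out)
}
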