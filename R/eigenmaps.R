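#' Gaussian-kernel affinity matrix
#'
#' Converts distances into similarities with the Gaussian kernel
#' `S_ij = exp(-M_ij^2 / (2 sigma^2))`. Entries lie in (0, 1\], the
#' diagonal is exactly 1, and symmetry is inherited from `M`. Affinities
#' for very distant pairs can underflow to exact floating-point zero; no
#' thresholding is applied (the kernel is used on the full matrix, with no
#' kNN sparsification).
#'
#' @param M symmetric distance matrix.
#' @param sigma kernel bandwidth, > 0; 0.3 is the usual setting for
#'   normalized edit distances.
#' @param affinity_floor affinities strictly below this value are set to
#'   0 (default 0 = keep all).
#' @return a symmetric affinity matrix with unit diagonal.
#' @export
gaussian_affinity <- function(M, sigma = 0.3, affinity_floor = 0) {
  M <- check_distmat(M)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_nedmap("`sigma` must be a single positive number")
  S <- exp(-M^2 / (2 * sigma^2))
  if (affinity_floor > 0) {
    off <- S < affinity_floor
    diag(off) <- FALSE
    S[off] <- 0
  }
  S
}

#' Unnormalized graph Laplacian
#'
#' `G = D - S` with `D = diag(rowSums(S))`. Every row sums to zero by
#' construction and `G` is positive semidefinite with the constant vector
#' in its null space (one zero eigenvalue per connected component of the
#' affinity graph).
#'
#' @param S symmetric non-negative affinity matrix.
#' @return the Laplacian matrix.
#' @export
laplacian <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop_nedmap("`S` must be square")
  if (max(abs(S - t(S))) > 1e-9)
    stop_nedmap("`S` must be symmetric (tolerance 1e-9)")
  if (any(S < 0)) stop_nedmap("`S` must be non-negative")
  diag(rowSums(S)) - S
}

#' Edit-distance Laplacian Eigenmaps embedding
#'
#' Applies the Gaussian kernel to the distance matrix, forms the
#' unnormalized Laplacian `G = D - S`, and eigendecomposes it. Eigenvalues
#' are sorted ascending; the trivial constant eigenvector(s) at eigenvalue
#' 0 (exactly one for a strictly positive kernel) are discarded and the
#' embedding columns are the next `k` eigenvectors — unit length, no
#' eigenvalue scaling, signs fixed deterministically. With
#' `generalized = TRUE` the generalized problem `G v = lambda D v` is
#' solved instead (via the symmetric form on `D^{-1/2} G D^{-1/2}`).
#'
#' @param M symmetric distance matrix with ids as dimnames.
#' @param sigma Gaussian bandwidth (default 0.3).
#' @param k target dimension; requires `n >= k + 2`.
#' @param generalized solve `G v = lambda D v` instead of `G v = lambda v`.
#' @param affinity_floor see [gaussian_affinity()].
#' @return a `ned_embedding`.
#' @examples
#' recs <- synth_families(list(family_spec("a", 8, 60), family_spec("b", 8, 80)),
#'                        seed = 1)$records
#' emb <- le_embed(distance_matrix(recs), k = 2)
#' @export
le_embed <- function(M, sigma = 0.3, k = 2, generalized = FALSE,
                     affinity_floor = 0) {
  M <- check_distmat(M)
  n <- nrow(M)
  k <- check_count(k, "k")
  if (n < k + 2L) stop_nedmap(sprintf("need n >= k + 2 points (n = %d, k = %d)", n, k))
  ids <- rownames(M) %||% as.character(seq_len(n))
  S <- gaussian_affinity(M, sigma, affinity_floor)
  G <- laplacian(S)
  if (check_flag(generalized, "generalized")) {
    d <- rowSums(S)
    if (any(d <= 0)) stop_nedmap("generalized form needs strictly positive degrees")
    isd <- 1 / sqrt(d)
    Gn <- (isd %o% isd) * G
    Gn <- (Gn + t(Gn)) / 2
    eig <- eigen(Gn, symmetric = TRUE)
    vecs <- isd * eig$vectors
  } else {
    eig <- eigen(G, symmetric = TRUE)
    vecs <- eig$vectors
  }
  ord <- order(eig$values)                      # ascending spectrum
  vals <- eig$values[ord]
  vecs <- vecs[, ord, drop = FALSE]
  tol <- max(abs(vals)) * 1e-9 + 1e-12
  n_trivial <- sum(vals < tol & apply(vecs, 2L, function(v)
    diff(range(v)) < 1e-6 * max(abs(v), 1)))
  n_trivial <- max(1L, n_trivial)
  if (n_trivial + k > n)
    stop_nedmap(sprintf(
      "only %d non-trivial eigenvectors available; the achievable dimension is %d",
      n - n_trivial, n - n_trivial))
  take <- seq.int(n_trivial + 1L, n_trivial + k)
  V <- vecs[, take, drop = FALSE]
  V <- sweep(V, 2L, sqrt(colSums(V^2)), `/`)    # unit columns
  V <- fix_signs(V)
  new_embedding(V, ids, method = "laplacian_eigenmaps",
                eigenvalues = vals[take],
                params = list(sigma = sigma, k = k, generalized = generalized,
                              affinity_floor = affinity_floor,
                              n_trivial_discarded = n_trivial))
}
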