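#' K-nearest-neighbour graph on a distance matrix
#'
#' For each point the K smallest off-diagonal distances are retained as
#' directed edges; the graph is then symmetrized by union (an edge is kept
#' if either endpoint selected it), so every node ends with at least K
#' finite neighbours. Ties at the K-th neighbour are broken by (distance,
#' then column index), which makes the graph deterministic.
#'
#' @param M a symmetric distance matrix (e.g. from [distance_matrix()]).
#' @param K neighbour count, `1 <= K <= n - 1`.
#' @return an n x n matrix of class `"ned_knn_graph"`: retained edges keep
#'   their distance, non-edges are `Inf`, the diagonal is 0. `K` is stored
#'   as an attribute.
#' @examples
#' M <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
#' knn_graph(M, K = 1)
#' @export
knn_graph <- function(M, K) {
  M <- check_distmat(M)
  n <- nrow(M)
  K <- check_count(K, "K")
  if (K > n - 1L)
    stop_nedmap(sprintf("K = %d out of range: need 1 <= K <= n - 1 = %d", K, n - 1L))
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    ord <- cand[order(M[i, cand], cand)]
    keep[i, ord[seq_len(K)]] <- TRUE
  }
  keep <- keep | t(keep)                      # union symmetrization
  G <- matrix(Inf, n, n, dimnames = dimnames(M))
  G[keep] <- M[keep]
  diag(G) <- 0
  structure(G, K = K, class = c("ned_knn_graph", "matrix", "array"))
}

#' All-pairs shortest paths on a neighbour graph
#'
#' Geodesic distances via the Floyd–Warshall recurrence
#' `S[i,j] <- min(S[i,j], S[i,k] + S[k,j])` over all intermediate nodes
#' (the reference method), or per-source Dijkstra (`method = "dijkstra"`,
#' via igraph) which must agree with Floyd to floating-point accuracy.
#' Infinite entries survive iff the graph is disconnected.
#'
#' @param g a `ned_knn_graph` (or any symmetric non-negative weight matrix
#'   with `Inf` marking absent edges).
#' @param method `"floyd"` (default) or `"dijkstra"`.
#' @return a symmetric matrix of geodesic distances.
#' @export
shortest_paths <- function(g, method = c("floyd", "dijkstra")) {
  method <- match.arg(method)
  S <- as.matrix(g)
  if (nrow(S) != ncol(S) || max(abs(S - t(S)), na.rm = TRUE) > 1e-9)
    stop_nedmap("neighbour graph must be a symmetric square matrix")
  if (method == "floyd") {
    n <- nrow(S)
    for (k in seq_len(n))
      S <- pmin(S, outer(S[, k], S[k, ], `+`))
    return(S)
  }
  finite <- is.finite(g) & upper.tri(g)
  edges <- which(finite, arr.ind = TRUE)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               weight = g[finite]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(g))))
  D <- igraph::distances(ig, algorithm = "dijkstra")
  ord <- order(as.integer(rownames(D)))
  D <- D[ord, ord, drop = FALSE]
  dimnames(D) <- dimnames(g)
  D
}

#' Double centering of squared geodesic distances
#'
#' Squares `S` entrywise and converts it into a Gram-like matrix whose top
#' eigenvectors yield MDS-style coordinates. Two variants of the additive
#' constant are provided:
#' \describe{
#'   \item{`"classical"`}{(default) textbook double centering
#'     `G = -1/2 * J S^2 J` with `J = I - 11'/n`, whose last term is the
#'     grand mean of the squared distances. This is the variant that
#'     provably recovers a Euclidean configuration from its distance
#'     matrix.}
#'   \item{`"product"`}{replaces the grand-mean term with the product of
#'     row sums `D_i * D_j / n^2`, i.e.
#'     `G_ij = -1/2 (S_ij^2 - D_i/n - D_j/n + D_i D_j / n^2)` with
#'     `D_i = sum_j S_ij^2`.}
#' }
#' The result is explicitly symmetrized.
#'
#' @param S finite geodesic distance matrix.
#' @param variant `"classical"` or `"product"`.
#' @return a symmetric matrix of class `"matrix"`.
#' @export
center_gram <- function(S, variant = c("classical", "product")) {
  variant <- match.arg(variant)
  S <- as.matrix(S)
  if (any(!is.finite(S)))
    stop_nedmap("geodesic matrix has non-finite entries: the neighbour graph is ",
                "disconnected; increase K or use component_policy = \"largest\"")
  S2 <- S^2
  n <- nrow(S2)
  rs <- rowSums(S2)
  G <- if (variant == "classical") {
    -0.5 * (S2 - outer(rs / n, rep(1, n)) - outer(rep(1, n), rs / n) +
              sum(S2) / n^2)
  } else {
    -0.5 * (S2 - outer(rs / n, rep(1, n)) - outer(rep(1, n), rs / n) +
              outer(rs, rs) / n^2)
  }
  (G + t(G)) / 2
}

# Merge disconnected neighbour-graph components by repeatedly adding the
# globally smallest original-distance edge between two different
# components (the edges of a minimum spanning tree over components).
bridge_components <- function(g, M, comp) {
  gm <- as.matrix(g)
  while (max(comp) > 1L) {
    cross <- outer(comp, comp, `!=`)
    cand <- M
    cand[!cross] <- Inf
    idx <- arrayInd(which.min(cand), dim(cand))
    i <- idx[1L]; j <- idx[2L]
    gm[i, j] <- M[i, j]
    gm[j, i] <- M[i, j]
    comp[comp == comp[j]] <- comp[i]
    comp <- match(comp, sort(unique(comp)))
  }
  structure(gm, K = attr(g, "K"), class = class(g))
}

# connected components of a finite-weight graph (Inf = no edge)
graph_components <- function(g) {
  n <- nrow(g)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(is.finite(g[v, ]) & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Edit-distance Isomap embedding
#'
#' Composes the Isomap pipeline on a (normalized edit-) distance matrix:
#' kNN graph, shortest-path geodesics, entrywise squaring with double
#' centering, and symmetric eigendecomposition. Column `p` of the
#' embedding is `sqrt(lambda_p) * v_p` for the p-th largest eigenvalue, so
#' each column's squared norm equals its eigenvalue. Negative eigenvalues
#' (edit-distance geodesics are generally non-Euclidean) are never used;
#' if fewer than `k` strictly positive eigenvalues exist an error names
#' the achievable dimension. Eigenvector signs are fixed deterministically.
#'
#' @param M symmetric distance matrix with ids as dimnames.
#' @param K neighbour count; default `round(0.30 * n)` clamped to
#'   `[1, n - 1]` (the usual 30\%-of-dataset setting).
#' @param k target dimension (2 or 3 typical).
#' @param variant centering variant, see [center_gram()].
#' @param component_policy what to do when the neighbour graph is
#'   disconnected (which always happens when K is smaller than the size
#'   of a tightly-knit, well-separated group): `"connect"` (default)
#'   bridges the components with the smallest available original
#'   distances (one MST-style edge per merge) so geodesics stay finite;
#'   `"error"` fails with a suggestion to increase K; `"largest"` embeds
#'   only the largest component with a warning and records the dropped
#'   ids.
#' @return a `ned_embedding`.
#' @examples
#' recs <- synth_families(list(family_spec("a", 8, 60), family_spec("b", 8, 80)),
#'                        seed = 1)$records
#' emb <- isomap_embed(distance_matrix(recs), k = 2)
#' @export
isomap_embed <- function(M, K = NULL, k = 2,
                         variant = c("classical", "product"),
                         component_policy = c("connect", "error", "largest")) {
  variant <- match.arg(variant)
  component_policy <- match.arg(component_policy)
  M <- check_distmat(M)
  n <- nrow(M)
  k <- check_count(k, "k")
  if (n < k + 1L) stop_nedmap(sprintf("need n >= k + 1 points (n = %d, k = %d)", n, k))
  if (is.null(K)) K <- min(max(1L, as.integer(round(0.30 * n))), n - 1L)
  ids <- rownames(M) %||% as.character(seq_len(n))
  g <- knn_graph(M, K)
  comp <- graph_components(g)
  dropped <- character(0)
  if (max(comp) > 1L) {
    if (component_policy == "error")
      stop_nedmap(sprintf(
        "neighbour graph has %d connected components; increase K (currently %d) or use component_policy \"connect\" or \"largest\"",
        max(comp), K))
    if (component_policy == "connect") {
      g <- bridge_components(g, M, comp)
      comp <- rep(1L, n)
    }
  }
  if (max(comp) > 1L) {
    main <- which.max(tabulate(comp))
    keep <- comp == main
    dropped <- ids[!keep]
    warning(sprintf("embedding largest component only; dropped %d ids",
                    length(dropped)), call. = FALSE)
    g <- structure(as.matrix(g)[keep, keep], K = attr(g, "K"))
    ids <- ids[keep]
    if (length(ids) < k + 1L)
      stop_nedmap("largest component too small for the requested dimension")
  }
  S <- shortest_paths(g)
  G <- center_gram(S, variant)
  eig <- eigen(G, symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * .Machine$double.eps * nrow(G))
  pos <- pos[eig$values[pos] > 0]
  if (length(pos) < k)
    stop_nedmap(sprintf(
      "only %d strictly positive eigenvalues available; the achievable dimension is %d",
      length(pos), length(pos)))
  lam <- eig$values[seq_len(k)]
  V <- fix_signs(eig$vectors[, seq_len(k), drop = FALSE])
  Y <- sweep(V, 2L, sqrt(lam), `*`)
  new_embedding(Y, ids, method = "isomap", eigenvalues = lam,
                params = list(K = attr(g, "K"), k = k, variant = variant,
                              component_policy = component_policy),
                dropped_ids = dropped)
}
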