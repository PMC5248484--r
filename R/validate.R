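#' Seeded Lloyd K-means on an embedding
#'
#' Lloyd's algorithm with Euclidean distance exactly as the classical
#' procedure: sample K data points as initial centroids, assign every
#' point to its nearest centroid, recompute centroids as cluster means,
#' and repeat until the centroids no longer change (or 300 iterations).
#' The best of `restarts` random restarts by within-cluster sum of squares
#' is returned; the within-cluster sum of squares is checked to be
#' non-increasing across iterations. If a cluster empties, its centroid is
#' re-seeded at the point farthest from its current centroid. Fully
#' reproducible given `seed`; the caller's RNG state is left untouched.
#'
#' @param Y a `ned_embedding` or an n x k numeric matrix.
#' @param K number of clusters, `1 <= K <= n`.
#' @param seed integer RNG seed for centroid initialization.
#' @param restarts random restarts (default 10).
#' @param max_iter iteration cap per restart (default 300).
#' @return a list of class `"ned_kmeans"`: `cluster` (1-based index per
#'   row), `centers` (K x k), `withinss`, `tot_withinss`, `n_iter`,
#'   `seed`, `restarts`.
#' @examples
#' Y <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
#' fit <- kmeans_fit(Y, K = 2, seed = 1)
#' table(fit$cluster)
#' @export
kmeans_fit <- function(Y, K, seed = 1L, restarts = 10L, max_iter = 300L) {
  if (inherits(Y, "ned_embedding")) Y <- as.matrix(Y)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (anyNA(Y) || any(!is.finite(Y))) stop_nedmap("embedding rows must be finite")
  n <- nrow(Y)
  K <- check_count(K, "K")
  if (K > n) stop_nedmap(sprintf("K = %d exceeds the number of points n = %d", K, n))
  restarts <- check_count(restarts, "restarts")
  max_iter <- check_count(max_iter, "max_iter")
  if (K > 1L && nrow(unique(Y)) == 1L)
    stop_nedmap("all rows identical: K-means with K > 1 is degenerate")

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd_once(Y, K, max_iter)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })
  best$seed <- seed
  best$restarts <- restarts
  class(best) <- "ned_kmeans"
  best
}

# squared Euclidean distances from every row of Y to every centroid
sqdist_to_centers <- function(Y, C) {
  outer(rowSums(Y^2), rep(1, nrow(C))) - 2 * Y %*% t(C) +
    outer(rep(1, nrow(Y)), rowSums(C^2))
}

lloyd_once <- function(Y, K, max_iter) {
  n <- nrow(Y)
  C <- Y[sample.int(n, K), , drop = FALSE]
  assign <- integer(n)
  prev_wcss <- Inf
  for (iter in seq_len(max_iter)) {
    D2 <- sqdist_to_centers(Y, C)
    assign <- max.col(-D2, ties.method = "first")
    # re-seed empty clusters at the point farthest from its own centroid
    empty <- setdiff(seq_len(K), unique(assign))
    for (e in empty) {
      own <- D2[cbind(seq_len(n), assign)]
      far <- which.max(own)
      C[e, ] <- Y[far, ]
      assign[far] <- e
      D2 <- sqdist_to_centers(Y, C)
    }
    wcss <- sum(pmax(D2[cbind(seq_len(n), assign)], 0))
    if (wcss > prev_wcss + 1e-8 * max(1, prev_wcss))
      stop_nedmap("within-cluster sum of squares increased; numerical failure")
    prev_wcss <- wcss
    newC <- C
    for (j in seq_len(K))
      newC[j, ] <- colMeans(Y[assign == j, , drop = FALSE])
    if (identical(newC, C)) break
    C <- newC
  }
  D2 <- sqdist_to_centers(Y, C)
  per_point <- pmax(D2[cbind(seq_len(n), assign)], 0)
  list(cluster = assign, centers = C,
       withinss = vapply(seq_len(K), function(j) sum(per_point[assign == j]),
                         numeric(1)),
       tot_withinss = sum(per_point), n_iter = iter)
}

#' @export
print.ned_kmeans <- function(x, ...) {
  cat(sprintf("ned_kmeans: %d clusters, %d points, WCSS = %.6g (%d iterations, seed %s)\n",
              nrow(x$centers), length(x$cluster), x$tot_withinss, x$n_iter,
              format(x$seed)))
  print(table(cluster = x$cluster))
  invisible(x)
}

# Optimal one-to-one matching between clusters and true classes,
# maximizing the number of correctly assigned samples. Solved exactly by
# dynamic programming over subsets of the smaller side (assignment
# problem); sizes here are the handful of sequence types, so 2^m is tiny.
match_clusters <- function(tab) {
  nr <- nrow(tab); nc <- ncol(tab)
  transposed <- nr > nc
  if (transposed) tab <- t(tab)
  m <- nrow(tab)                                # m <= ncol(tab)
  if (m > 20L) stop_nedmap("too many clusters/classes for exact matching")
  nslots <- ncol(tab)
  # dp[mask + 1]: best total over rows 1..popcount(mask ... ) assigning
  # row r to some unused column; iterate rows in order.
  full <- bitwShiftL(1L, nslots) - 1L
  dp <- rep(-Inf, bitwShiftL(1L, nslots))
  choice <- matrix(NA_integer_, m, bitwShiftL(1L, nslots))
  dp[1L] <- 0
  for (r in seq_len(m)) {
    ndp <- rep(-Inf, length(dp))
    for (mask in which(dp > -Inf) - 1L) {
      if (sum(bitwAnd(mask, bitwShiftL(1L, 0:(nslots - 1L))) > 0) != r - 1L) next
      for (cidx in seq_len(nslots)) {
        bit <- bitwShiftL(1L, cidx - 1L)
        if (bitwAnd(mask, bit) > 0L) next
        nm <- bitwOr(mask, bit)
        val <- dp[mask + 1L] + tab[r, cidx]
        if (val > ndp[nm + 1L]) {
          ndp[nm + 1L] <- val
          choice[r, nm + 1L] <- cidx
        }
      }
    }
    dp <- ndp
  }
  best_mask <- which.max(dp) - 1L
  best <- dp[best_mask + 1L]
  # reconstruct
  assign_col <- integer(m)
  mask <- best_mask
  for (r in rev(seq_len(m))) {
    cidx <- choice[r, mask + 1L]
    assign_col[r] <- cidx
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, cidx - 1L)))
  }
  if (transposed) {
    # rows were columns of the original table
    list(rows = assign_col, cols = seq_len(m), total = best,
         cluster_to_class = stats::setNames(seq_len(m), NULL),
         map = data.frame(cluster = assign_col, class = seq_len(m)))
  } else {
    list(rows = seq_len(m), cols = assign_col, total = best,
         map = data.frame(cluster = seq_len(m), class = assign_col))
  }
}

#' Clustering accuracy against known labels
#'
#' Matches clusters to true classes one-to-one so that the total number of
#' correctly assigned samples is maximized (the optimal assignment over
#' all matchings), then reports `accuracy = sum(c_i) / N` where `c_i` is
#' the number of samples correctly assigned to the i-th cluster. A greedy
#' majority-vote (many-to-one) accuracy is reported alongside for
#' diagnostics; the headline accuracy uses the optimal one-to-one
#' matching.
#'
#' @param assign a `ned_kmeans` fit, or an integer/character vector of
#'   cluster indices.
#' @param truth vector of true labels, same length.
#' @return a list of class `"ned_accuracy"`: `accuracy`, `correct`
#'   (per-cluster `c_i` under the matching), `n`, `matching` (data frame
#'   cluster -> class), `majority_accuracy`.
#' @examples
#' accuracy(c(1, 1, 1, 2), c("a", "a", "b", "b"))$accuracy  # 0.75
#' @export
accuracy <- function(assign, truth) {
  if (inherits(assign, "ned_kmeans")) assign <- assign$cluster
  if (length(assign) != length(truth))
    stop_nedmap(sprintf("length mismatch: %d cluster assignments vs %d labels",
                        length(assign), length(truth)))
  cl <- factor(assign)
  tr <- factor(truth)
  tab <- table(cluster = cl, class = tr)
  mm <- match_clusters(unclass(tab))
  n <- length(assign)
  correct <- stats::setNames(integer(nlevels(cl)), levels(cl))
  matched <- mm$map
  for (i in seq_len(nrow(matched)))
    correct[matched$cluster[i]] <- tab[matched$cluster[i], matched$class[i]]
  matching <- data.frame(cluster = levels(cl)[matched$cluster],
                         class = levels(tr)[matched$class],
                         stringsAsFactors = FALSE)
  structure(list(accuracy = sum(correct) / n,
                 correct = correct, n = n, matching = matching,
                 majority_accuracy = sum(apply(tab, 1L, max)) / n),
            class = "ned_accuracy")
}

#' @export
print.ned_accuracy <- function(x, ...) {
  cat(sprintf("clustering accuracy: %.4f (%d/%d correct; majority-vote %.4f)\n",
              x$accuracy, sum(x$correct), x$n, x$majority_accuracy))
  cat("matching:\n")
  print(x$matching, row.names = FALSE)
  invisible(x)
}

#' End-to-end embedding validation pipeline
#'
#' Distance matrix -> embedding (Isomap or Laplacian Eigenmaps) -> K-means
#' with K = number of distinct true labels -> clustering accuracy. One
#' seeded, reproducible run.
#'
#' @param records a [seq_records()] set.
#' @param labels true type label per record, named by id or aligned to
#'   `records`.
#' @param method `"isomap"` or `"le"`.
#' @param k embedding dimension (default 2).
#' @param K_frac Isomap neighbour fraction of n (default 0.30).
#' @param sigma Laplacian Eigenmaps bandwidth (default 0.3).
#' @param weights [edit_weights()] for the distance stage.
#' @param variant Isomap centering variant.
#' @param seed RNG seed for K-means.
#' @param restarts K-means restarts (default 10).
#' @param M optional precomputed distance matrix (skips the distance stage).
#' @return a list: `report` (`ned_accuracy`), `embedding`, `kmeans`,
#'   `distmat`, `params`.
#' @export
evaluate_pipeline <- function(records, labels, method = c("isomap", "le"),
                              k = 2, K_frac = 0.30, sigma = 0.3,
                              weights = edit_weights(),
                              variant = c("classical", "product"),
                              seed = 1L, restarts = 10L, M = NULL) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  if (is.null(M)) M <- distance_matrix(records, weights)
  ids <- rownames(M)
  if (!is.null(names(labels))) {
    miss <- setdiff(ids, names(labels))
    if (length(miss))
      stop_nedmap("labels missing for ids: ", paste(utils::head(miss, 5), collapse = ", "))
    labels <- labels[ids]
  } else if (length(labels) != nrow(M)) {
    stop_nedmap("labels must be named by id or aligned to the records")
  }
  n <- nrow(M)
  emb <- if (method == "isomap") {
    K <- min(max(1L, as.integer(round(K_frac * n))), n - 1L)
    isomap_embed(M, K = K, k = k, variant = variant)
  } else {
    le_embed(M, sigma = sigma, k = k)
  }
  kept <- setdiff(rownames(as.matrix(emb)), emb$dropped_ids)
  fit <- kmeans_fit(emb, K = length(unique(labels)), seed = seed,
                    restarts = restarts)
  rep <- accuracy(fit, labels[match(kept, ids)])
  list(report = rep, embedding = emb, kmeans = fit, distmat = M,
       params = list(method = method, k = k, K_frac = K_frac, sigma = sigma,
                     variant = variant, seed = seed, restarts = restarts))
}
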