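test_that("knn_graph keeps K nearest per row and symmetrizes by union", {
  M <- matrix(c(0, 1, 2,
                1, 0, 3,
                2, 3, 0), 3, byrow = TRUE)
  g <- knn_graph(M, K = 1)
  # node 1 picks 2; node 2 picks 1; node 3 picks 1 -> union edges {1,2},{1,3}
  expect_identical(g[1, 2], 1); expect_identical(g[2, 1], 1)
  expect_identical(g[1, 3], 2); expect_identical(g[3, 1], 2)
  expect_identical(g[2, 3], Inf)
  expect_identical(diag(g), c(0, 0, 0))

  expect_true(all(is.finite(knn_graph(M, K = 2))))   # complete graph

  set.seed(501)
  M10 <- rand_symmetric_dist(10)
  g10 <- knn_graph(M10, K = 3)
  finite_per_row <- rowSums(is.finite(g10)) - 1L
  expect_true(all(finite_per_row >= 3L))
  expect_identical(unclass(g10), t(unclass(g10)))
  expect_error(knn_graph(M10, K = 10), "out of range")
  expect_error(knn_graph(M10, K = 0), "integer")
})

test_that("knn ties break by distance then index, deterministically", {
  M <- matrix(0, 4, 4)
  M[1, 2:4] <- 1; M[2:4, 1] <- 1          # all of 1's neighbours tie
  M[2, 3] <- M[3, 2] <- 0.5
  M[2, 4] <- M[4, 2] <- 0.5
  M[3, 4] <- M[4, 3] <- 0.5
  g <- knn_graph(M, K = 1)
  # 1's single neighbour under (distance, index) ordering is node 2
  expect_true(is.finite(g[1, 2]))
  expect_identical(knn_graph(M, K = 1), g)  # rerun is bit-identical
})

test_that("shortest paths form a graph metric and agree with Dijkstra", {
  path <- matrix(c(0, 1, Inf,
                   1, 0, 1,
                   Inf, 1, 0), 3, byrow = TRUE)
  S <- shortest_paths(path)
  expect_identical(S[1, 3], 2)

  set.seed(502)
  X <- matrix(rnorm(12), ncol = 2)
  D <- planted_distmat(X)        # metric, complete -> already shortest
  expect_equal(shortest_paths(D), D, tolerance = 1e-12)

  for (rep in 1:10) {
    g <- rand_connected_graph(12)
    F <- shortest_paths(g, method = "floyd")
    Dk <- shortest_paths(g, method = "dijkstra")
    expect_equal(F, Dk, tolerance = 1e-12, ignore_attr = TRUE)
    expect_identical(F, t(F))
    expect_true(all(diag(F) == 0))
    # exact triangle inequality of the shortest-path metric
    n <- nrow(F)
    for (k in seq_len(n))
      expect_true(all(F <= outer(F[, k], F[k, ], `+`) + 1e-12))
  }
})

test_that("geodesics never increase when K grows", {
  set.seed(503)
  M <- rand_symmetric_dist(12)
  prev <- NULL
  for (K in c(2, 4, 6, 11)) {
    g <- knn_graph(M, K)
    S <- shortest_paths(g)
    if (!is.null(prev)) expect_true(all(S <= prev + 1e-12))
    prev <- S
  }
})

test_that("double centering matches hand algebra and recovers planted geometry", {
  Z <- matrix(0, 3, 3)
  expect_identical(center_gram(Z, "classical"), Z)
  expect_identical(center_gram(Z, "product"), Z)

  d <- 1.7
  S2 <- matrix(c(0, d, d, 0), 2)
  G <- center_gram(S2, "classical")
  expect_equal(G, matrix(c(d^2 / 4, -d^2 / 4, -d^2 / 4, d^2 / 4), 2))

  # product variant differs from classical off the Euclidean case
  set.seed(504)
  S <- rand_symmetric_dist(5)
  expect_gt(max(abs(center_gram(S, "classical") - center_gram(S, "product"))),
            1e-6)
  expect_error(center_gram(matrix(c(0, Inf, Inf, 0), 2)), "disconnected")
})

test_that("classical-variant embedding reproduces planted Euclidean configurations", {
  set.seed(505)
  X <- matrix(rnorm(12), ncol = 2)             # 6 planted 2-D points
  M <- planted_distmat(X)
  emb <- isomap_embed(M, K = 5, k = 2, variant = "classical")
  expect_equal(as.matrix(dist(as.matrix(emb))),
               as.matrix(dist(X)), tolerance = 1e-8, ignore_attr = TRUE)

  # 8 points on a line, k = 1
  x_line <- sort(runif(8, 0, 10))
  Ml <- planted_distmat(cbind(x_line, 0))
  e1 <- isomap_embed(Ml, K = 7, k = 1)
  expect_equal(as.matrix(dist(as.matrix(e1))),
               as.matrix(dist(x_line)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("isomap eigen-accounting, duplicates and determinism", {
  fams <- small_families()
  M <- distance_matrix(fams$records)
  emb <- isomap_embed(M, k = 3)
  expect_equal(colSums(as.matrix(emb)^2), emb$eigenvalues,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(as.matrix(emb),
                   as.matrix(isomap_embed(M, k = 3)))   # bit-identical rerun

  # identical sequences get identical embedding rows
  recs <- seq_records(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTTTGGGGCC",
                        d = "ACGGACGTAC", e = "TTCTGGGGCC", f = "AAAACCGGTT"))
  Md <- distance_matrix(recs)
  Y <- as.matrix(isomap_embed(Md, K = 5, k = 2))
  expect_equal(Y["a", ], Y["b", ], tolerance = 1e-9)
})

test_that("isomap error and component policies", {
  set.seed(506)
  M <- planted_distmat(matrix(rnorm(8), ncol = 2))
  expect_error(isomap_embed(M, K = 3, k = 10), "n >= k")
  # 4 planted 2-D points have a rank-2 Gram: k = 3 is unachievable
  expect_error(isomap_embed(M, K = 3, k = 3, variant = "classical"),
               "achievable dimension")
  # two far blocks with tiny K disconnect
  X <- rbind(matrix(rnorm(10, 0, 0.1), ncol = 2),
             matrix(rnorm(10, 50, 0.1), ncol = 2))
  Mb <- planted_distmat(X)
  expect_error(isomap_embed(Mb, K = 2, k = 2, component_policy = "error"),
               "connected components")
  expect_warning(el <- isomap_embed(Mb, K = 2, k = 2,
                                    component_policy = "largest"),
                 "largest component")
  expect_identical(nrow(as.matrix(el)) + length(el$dropped_ids), 10L)
  ec <- isomap_embed(Mb, K = 2, k = 2, component_policy = "connect")
  expect_identical(nrow(as.matrix(ec)), 10L)
  expect_length(ec$dropped_ids, 0)
})
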