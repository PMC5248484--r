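test_that("gaussian affinity matches the scalar kernel cell by cell", {
  sigma <- 0.3
  M <- matrix(c(0, sigma * sqrt(2), sigma * sqrt(2), 0), 2)
  S <- gaussian_affinity(M, sigma)
  expect_equal(S[1, 2], exp(-1))
  expect_identical(diag(S), c(1, 1))

  set.seed(601)
  M5 <- rand_symmetric_dist(5)
  S5 <- gaussian_affinity(M5, 0.3)
  for (i in 1:5) for (j in 1:5)
    expect_identical(S5[i, j], exp(-M5[i, j]^2 / (2 * 0.3^2)))
  expect_true(all(S5 > 0) && all(S5 <= 1))
  expect_error(gaussian_affinity(M5, 0), "positive")
  expect_error(gaussian_affinity(M5, -1), "positive")

  floored <- gaussian_affinity(M5, 0.05, affinity_floor = 1e-4)
  expect_true(any(floored == 0))
  expect_identical(diag(floored), rep(1, 5))
})

test_that("laplacian has zero row sums, PSD spectrum and constant null vector", {
  S1 <- diag(3)
  expect_identical(laplacian(S1), matrix(0, 3, 3))

  S2 <- matrix(1, 3, 3)
  expect_equal(laplacian(S2),
               matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3))

  set.seed(602)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    S <- gaussian_affinity(rand_symmetric_dist(n), runif(1, 0.1, 0.6))
    G <- laplacian(S)
    expect_true(all(abs(rowSums(G)) < 1e-9))
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10))
    v0 <- eigen(G, symmetric = TRUE)$vectors[, n]
    expect_lt(diff(range(v0)), 1e-8)           # constant eigenvector at 0
  }
  bad <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(laplacian(bad), "symmetric")
})

test_that("first non-trivial eigenvector separates two tight groups by sign", {
  recs <- seq_records(c(a1 = "ACGTACGTACGTACGT", a2 = "ACGTACGTACGTACGA",
                        a3 = "ACGTACGTACGTTCGT",
                        b1 = "TTGGCCAATTGGCCAA", b2 = "TTGGCCAATTGGCCAT",
                        b3 = "TTGGCCAATAGGCCAA"))
  M <- distance_matrix(recs)
  emb <- le_embed(M, sigma = 0.3, k = 1)
  f <- as.matrix(emb)[, 1]
  expect_true(all(sign(f[1:3]) == sign(f[1])))
  expect_true(all(sign(f[4:6]) == -sign(f[1])))
})

test_that("le embedding is scale-equivariant, deterministic and handles duplicates", {
  fams <- small_families()
  M <- distance_matrix(fams$records)
  Y1 <- as.matrix(le_embed(M, sigma = 0.3, k = 2))
  expect_identical(Y1, as.matrix(le_embed(M, sigma = 0.3, k = 2)))

  c_scale <- 2.5
  Y2 <- as.matrix(le_embed(M * c_scale, sigma = 0.3 * c_scale, k = 2))
  expect_equal(Y1, Y2, tolerance = 1e-10)

  recs <- seq_records(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTTTGGGGCC",
                        d = "ACGGACGTAC", e = "TTCTGGGGCC", f = "AAAACCGGTT"))
  Y <- as.matrix(le_embed(distance_matrix(recs), k = 2))
  expect_equal(Y["a", ], Y["b", ], tolerance = 1e-9)

  expect_error(le_embed(M[1:3, 1:3], k = 2), "n >= k")
})

test_that("returned embedding minimizes the weighted pairwise objective", {
  le_objective <- function(Y, S) {
    tot <- 0
    for (i in seq_len(nrow(Y))) for (j in seq_len(nrow(Y)))
      tot <- tot + sum((Y[i, ] - Y[j, ])^2) * S[i, j]
    tot
  }
  set.seed(603)
  M <- rand_symmetric_dist(12)
  S <- gaussian_affinity(M, 0.3)
  emb <- le_embed(M, sigma = 0.3, k = 2)
  Y <- as.matrix(emb)
  obj <- le_objective(Y, S)
  norms <- sqrt(colSums(Y^2))
  for (rep in 1:100) {
    # competitors in the same class as the embedding: matched column
    # norms and no component along the constant null vector (which the
    # objective cannot see)
    Z <- matrix(rnorm(length(Y)), nrow(Y))
    Z <- sweep(Z, 2, colMeans(Z), `-`)
    Z <- sweep(Z, 2, sqrt(colSums(Z^2)), `/`)
    Z <- sweep(Z, 2, norms, `*`)
    expect_gte(le_objective(Z, S), obj - 1e-9)
  }
})

test_that("generalized eigenproblem form also separates planted families", {
  fams <- small_families(n_per = 10L)
  M <- distance_matrix(fams$records)
  emb <- le_embed(M, sigma = 0.3, k = 2, generalized = TRUE)
  fit <- kmeans_fit(emb, K = 3, seed = 5)
  expect_gte(accuracy(fit, fams$labels)$accuracy, 0.9)
})
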