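test_that("edit distance matches the worked 7-base example and basic closed forms", {
  expect_identical(edit_distance("ATCAGTA", "TCGACTA"), 3)
  T <- dp_table("ATCAGTA", "TCGACTA")
  expect_identical(dim(T), c(8L, 8L))
  expect_identical(T[8L, 8L], 3)

  expect_identical(edit_distance("ACGT", "ACGT"), 0)
  expect_identical(edit_distance("ACGT", ""), 4)    # deletion-only path
  expect_identical(edit_distance("", "ACGT"), 4)
  expect_identical(normalized_edit_distance("ATCAGTA", "TCGACTA"), 3 / 7)
  expect_identical(normalized_edit_distance("AAAA", "TTTT"), 1)
  expect_identical(normalized_edit_distance("ACGT", "ACGT"), 0)
  expect_error(normalized_edit_distance("", ""), "undefined")
})

test_that("DP table boundaries and recursion hold cell by cell", {
  expect_identical(dp_table("A", "A"), matrix(c(0, 1, 1, 0), 2,
                                              dimnames = list(c("", "A"), c("", "A"))))
  expect_identical(dp_table("AG", "GA")[3L, 3L], 2)  # two substitutions

  w <- edit_weights(w_ins = 0.7, w_del = 1.3, w_sub = 1.1, w_mat = 0.2)
  set.seed(401)
  for (rep in 1:10) {
    x <- rand_dna(sample(3:9, 1)); y <- rand_dna(sample(3:9, 1))
    T <- dp_table(x, y, w)
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    expect_equal(T[, 1L], (0:length(xs)) * w[["w_del"]], ignore_attr = TRUE)
    expect_equal(T[1L, ], (0:length(ys)) * w[["w_ins"]], ignore_attr = TRUE)
    for (i in seq_along(xs)) for (j in seq_along(ys)) {
      diag_w <- if (xs[i] == ys[j]) w[["w_mat"]] else w[["w_sub"]]
      expect_equal(T[i + 1L, j + 1L],
                   min(T[i, j + 1L] + w[["w_del"]],
                       T[i + 1L, j] + w[["w_ins"]],
                       T[i, j] + diag_w))
    }
    # monotone by at most the largest single-operation weight per step
    step <- max(w[c("w_ins", "w_del", "w_sub")])
    expect_true(all(diff(t(T)) >= -step - 1e-12))
    expect_true(all(diff(T) >= -step - 1e-12))
  }
})

test_that("DP equals the exhaustive edit-script oracle, including custom weights", {
  strs <- all_strings(c("A", "C"), 3L)
  for (x in strs) for (y in strs) {
    expect_identical(edit_distance(x, y), edit_oracle(x, y))
  }
  set.seed(402)
  w <- edit_weights(w_ins = 0.5, w_del = 2, w_sub = 1.5, w_mat = 0.25)
  for (rep in 1:25) {
    x <- rand_dna(sample(0:5, 1)); y <- rand_dna(sample(0:5, 1))
    expect_equal(edit_distance(x, y, w),
                 edit_oracle(x, y, 0.5, 2, 1.5, 0.25))
  }
})

test_that("DP agrees with the independent generalized-distance routine in base R", {
  set.seed(403)
  for (rep in 1:50) {
    x <- rand_dna(sample(1:40, 1)); y <- rand_dna(sample(1:40, 1))
    expect_identical(edit_distance(x, y), as.numeric(adist(x, y)[1L, 1L]))
  }
})

test_that("metric-style properties hold for the unnormalized distance", {
  set.seed(404)
  for (rep in 1:200) {
    x <- rand_dna(sample(1:15, 1)); y <- rand_dna(sample(1:15, 1))
    z <- rand_dna(sample(1:15, 1))
    dxy <- edit_distance(x, y)
    expect_identical(dxy, edit_distance(y, x))          # symmetry
    expect_true(dxy <= max(nchar(x), nchar(y)))          # upper bound
    expect_true(dxy >= abs(nchar(x) - nchar(y)))         # lower bound
    expect_identical(dxy == 0, x == y)                   # identity
    expect_true(edit_distance(x, z) <= dxy + edit_distance(y, z) + 1e-12)
  }
})

test_that("distance_matrix mirrors per-pair normalized distances exactly", {
  recs <- seq_records(c(a = "ATCAGTA", b = "TCGACTA"))
  M <- distance_matrix(recs)
  expect_equal(unclass(M), matrix(c(0, 3 / 7, 3 / 7, 0), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))),
               ignore_attr = TRUE)

  same <- seq_records(setNames(rep("ACGTACGT", 4), paste0("r", 1:4)))
  expect_true(all(distance_matrix(same) == 0))

  set.seed(405)
  seqs <- vapply(1:6, function(i) rand_dna(sample(5:20, 1)), character(1))
  recs <- seq_records(setNames(seqs, paste0("s", 1:6)))
  M <- distance_matrix(recs)
  expect_identical(unclass(M), t(unclass(M)))
  expect_true(all(diag(M) == 0) && all(M >= 0) && all(M <= 1))
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    expect_identical(M[i, j], normalized_edit_distance(seqs[i], seqs[j]))
  }
})

test_that("input normalization policies behave as documented", {
  expect_error(seq_records(c(ok = "ACGT", bad = "ACNT")),
               "record 'bad' has non-ACGT symbol 'N' at position 3")
  expect_error(seq_records(c(a = "ACGT", a = "ACGT")), "duplicate record ids")
  expect_identical(unclass(seq_records(c(x = "acgt")))[["x"]], "ACGT")

  stripped <- seq_records(c(x = "ACNNGT"), iupac_policy = "strip")
  expect_identical(unclass(stripped)[["x"]], "ACGT")
  expect_error(seq_records(c(x = "NNN"), iupac_policy = "strip"),
               "empty after input normalization")

  # under as-mismatch, ambiguous symbols never match, even themselves
  keep <- seq_records(c(u = "ANA", v = "ANA"), iupac_policy = "as-mismatch")
  M <- distance_matrix(keep)
  expect_identical(M[1L, 2L], 1 / 3)
})

test_that("edit weights are validated", {
  expect_error(edit_weights(w_sub = -1), "non-negative")
  expect_error(edit_weights(w_mat = 2, w_sub = 1), "w_mat")
  w <- edit_weights(w_ins = 2, w_del = 1)
  expect_false(edit_distance("AC", "ACG", w) ==
                 edit_distance("ACG", "AC", w))  # asymmetric ins/del weights
})
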