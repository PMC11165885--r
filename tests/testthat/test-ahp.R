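test_that("judgment scale admits 1-9 and exact reciprocals only", {
  expect_length(judgment_scale(), 17)
  good <- data.frame(criterion_i = "a", criterion_j = "b", value = 9)
  expect_silent(pairwise_matrix(good, c("a", "b")))
  for (bad_val in list(10, 9.5, 0, -3, 2.5)) {
    bad <- data.frame(criterion_i = "a", criterion_j = "b", value = bad_val)
    expect_error(pairwise_matrix(bad, c("a", "b")), "inadmissible")
  }
})

test_that("matrix expansion fills diagonal and exact reciprocals", {
  A <- pairwise_matrix(
    data.frame(
      criterion_i = c("a", "a", "b"), criterion_j = c("b", "c", "c"),
      value = c("2", "4", "2")
    ),
    c("a", "b", "c")
  )
  expect_identical(dim(A), c(3L, 3L))
  expect_equal(unname(A), rbind(c(1, 2, 4), c(1 / 2, 1, 2), c(1 / 4, 1 / 2, 1)))
  # reciprocal closure is exact, not approximate
  expect_true(all(A * t(A) == 1))

  # all-equal judgments give the all-ones matrix
  ones <- pairwise_matrix(
    data.frame(criterion_i = c("a", "a", "b"), criterion_j = c("b", "c", "c"), value = 1),
    c("a", "b", "c")
  )
  expect_equal(unname(ones), matrix(1, 3, 3))
})

test_that("missing or surplus judgment pairs are rejected by name", {
  four <- c("w", "x", "y", "z")
  five <- data.frame(
    criterion_i = c("w", "w", "w", "x", "x"),
    criterion_j = c("x", "y", "z", "y", "z"),
    value = 1
  )
  expect_error(pairwise_matrix(five, four), "\\(y, z\\)")
  dup <- data.frame(criterion_i = c("a", "a"), criterion_j = c("b", "b"), value = c(2, 3))
  expect_error(pairwise_matrix(dup, c("a", "b")), "duplicate")
})

test_that("weights and consistency match closed forms on reference matrices", {
  # equal-importance matrices: uniform weights, lambda_max = n, CR = 0
  for (n in 3:4) {
    ids <- letters[seq_len(n)]
    pairs <- t(combn(n, 2))
    A <- pairwise_matrix(
      data.frame(criterion_i = ids[pairs[, 1]], criterion_j = ids[pairs[, 2]], value = 1),
      ids
    )
    for (m in c("eigenvector", "geometric-mean")) {
      w <- compute_weights(A, method = m)
      expect_equal(unname(w$weights), rep(1 / n, n), tolerance = 1e-12)
      expect_equal(w$lambda_max, n, tolerance = 1e-9)
      expect_equal(w$cr, 0, tolerance = 1e-9)
      expect_false(w$cr_flag)
    }
  }

  # consistent 3x3: weights are exactly proportional to (4, 2, 1)
  A <- consistent_matrix_3()
  for (m in c("eigenvector", "geometric-mean")) {
    w <- compute_weights(A, method = m)
    expect_equal(unname(w$weights), c(4, 2, 1) / 7, tolerance = 1e-9)
    expect_equal(w$lambda_max, 3, tolerance = 1e-9)
    expect_equal(w$cr, 0, tolerance = 1e-9)
  }

  # maximally cyclic 3x3: lambda_max = 1 + 3 + 1/3, CR = (2/3)/0.58
  wc <- compute_weights(cyclic_matrix_3())
  expect_equal(wc$lambda_max, 13 / 3, tolerance = 1e-9)
  expect_equal(wc$ci, 2 / 3, tolerance = 1e-9)
  expect_equal(wc$cr, (2 / 3) / 0.58, tolerance = 1e-9)
  expect_true(wc$cr_flag)
})

test_that("power iteration agrees with a dense eigensolver oracle", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:4, 1)
    # random admissible upper triangle
    vals <- sample(judgment_scale(), n * (n - 1) / 2, replace = TRUE)
    A <- diag(n)
    A[upper.tri(A)] <- vals
    A[lower.tri(A)] <- 1 / t(A)[lower.tri(A)]
    w <- compute_weights(A)
    ev <- eigen(A)
    k <- which.max(Re(ev$values))
    oracle_w <- Re(ev$vectors[, k])
    oracle_w <- oracle_w / sum(oracle_w)
    expect_equal(unname(w$weights), oracle_w, tolerance = 1e-8)
    expect_equal(w$lambda_max, Re(ev$values[k]), tolerance = 1e-8)
    # Perron root of a reciprocal matrix is never below its dimension
    expect_gte(w$lambda_max, n - 1e-9)
  }
})

test_that("eigenvector and geometric-mean agree on consistent matrices", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:4, 1)
    w_true <- rexp(n) + 0.05
    w_true <- w_true / sum(w_true)
    A <- consistent_matrix_from(w_true)
    we <- compute_weights(A, method = "eigenvector")
    wg <- compute_weights(A, method = "geometric-mean")
    expect_equal(unname(we$weights), unname(wg$weights), tolerance = 1e-9)
    expect_equal(unname(we$weights), unname(w_true), tolerance = 1e-9)
  }
})

test_that("permuting criteria permutes weights identically", {
  A <- consistent_matrix_3()
  # add inconsistency so the test is not trivially symmetric
  A[1, 2] <- 3
  A[2, 1] <- 1 / 3
  w <- compute_weights(A)$weights
  perm <- c(3, 1, 2)
  wp <- compute_weights(A[perm, perm])$weights
  expect_equal(unname(wp), unname(w[perm]), tolerance = 1e-10)
})

test_that("ahp_weights builds the per-group table and strict mode blocks high CR", {
  crit <- default_criteria()
  jd <- rbind(
    data.frame(
      group = "G1", stream = "risk",
      criterion_i = c("scope", "scope", "frequency"),
      criterion_j = c("frequency", "mitigation", "mitigation"),
      value = c(2, 4, 2)
    ),
    data.frame(
      group = "G2", stream = "risk",
      criterion_i = c("scope", "scope", "frequency"),
      criterion_j = c("frequency", "mitigation", "mitigation"),
      value = c(3, 1 / 3, 3)
    )
  )
  w <- ahp_weights(jd, crit)
  expect_identical(nrow(w), 6L)
  expect_equal(sum(w$weight[w$group == "G1"]), 1, tolerance = 1e-12)
  expect_false(any(w$cr_flag[w$group == "G1"]))
  expect_true(all(w$cr_flag[w$group == "G2"]))
  expect_error(ahp_weights(jd, crit, strict = TRUE), "strict")
})
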