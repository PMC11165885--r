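test_that("composite scores match hand-computed reference values", {
  # equal weights, all-3 scores, max multiplier: upper bound 9
  expect_equal(
    risk_impact_score(c(3, 3, 3), rep(1 / 3, 3), 3)$value, 9,
    tolerance = 1e-12
  )
  # (0.5*2 + 0.3*3 + 0.2*1) * 2 = 4.2
  r <- risk_impact_score(
    c(scope = 2, frequency = 3, mitigation = 1),
    c(scope = 0.5, frequency = 0.3, mitigation = 0.2), 2
  )
  expect_equal(r$weighted_sum, 2.1, tolerance = 1e-12)
  expect_equal(r$value, 4.2, tolerance = 1e-12)
  # all-minimum inputs: lower bound 1
  expect_equal(risk_impact_score(c(1, 1, 1), c(0.6, 0.3, 0.1), 1)$value, 1)

  expect_equal(
    disease_burden_score(c(2, 2, 2, 2), rep(0.25, 4), 3)$value, 6,
    tolerance = 1e-12
  )
  # (0.4*3 + 0.3*1 + 0.2*2 + 0.1*2) * 2 = 4.2
  d <- disease_burden_score(c(3, 1, 2, 2), c(0.4, 0.3, 0.2, 0.1), 2)
  expect_equal(d$value, 4.2, tolerance = 1e-12)
  expect_equal(disease_burden_score(c(1, 1, 1, 1), rep(0.25, 4), 1)$value, 1)
})

test_that("composite scores reject malformed inputs", {
  expect_error(
    risk_impact_score(c(a = 2, b = 2, c = 2), c(a = 0.5, b = 0.25, x = 0.25), 2),
    "mismatch"
  )
  expect_error(risk_impact_score(c(2, 2, 2), c(0.5, 0.5), 2), "expected 3")
  expect_error(risk_impact_score(c(2, 2.5, 2), rep(1 / 3, 3), 2), "1,2,3")
  expect_error(risk_impact_score(c(2, 2, 2), rep(1 / 3, 3), 4), "multiplier")
  expect_error(risk_impact_score(c(2, 2, 2), c(0.5, 0.4, 0.3), 2), "sum to 1")
})

test_that("composites stay in [1,9], hit bounds only at extremes, and match a brute-force oracle", {
  set.seed(97)
  for (i in 1:300) {
    n <- sample(c(3L, 4L), 1)
    w <- rexp(n) + 0.01
    w <- w / sum(w)
    s <- sample(1:3, n, replace = TRUE)
    m <- sample(1:3, 1)
    fn <- if (n == 3L) risk_impact_score else disease_burden_score
    got <- fn(s, w, m)
    # term-by-term oracle
    oracle <- 0
    for (j in seq_len(n)) oracle <- oracle + s[j] * w[j]
    oracle <- oracle * m
    expect_equal(got$value, oracle, tolerance = 1e-12)
    expect_gte(got$value, 1 - 1e-9)
    expect_lte(got$value, 9 + 1e-9)
    if (got$value == 9) expect_true(all(s == 3) && m == 3)
    if (got$value == 1) expect_true(all(s == 1) && m == 1)
    # strict monotonicity in each criterion score
    for (j in which(s < 3)) {
      s2 <- s
      s2[j] <- s2[j] + 1L
      expect_gt(fn(s2, w, m)$value, got$value)
    }
  }
})

test_that("shifting weight toward a higher-scoring criterion never lowers the weighted sum", {
  set.seed(13)
  for (i in 1:50) {
    w <- rexp(3) + 0.05
    w <- w / sum(w)
    s <- sample(1:3, 3, replace = TRUE)
    hi <- which.max(s)
    lo <- which.min(s)
    delta <- min(0.9 * w[lo], 0.2)
    w2 <- w
    w2[hi] <- w2[hi] + delta
    w2[lo] <- w2[lo] - delta
    expect_gte(
      risk_impact_score(s, w2, 1)$weighted_sum,
      risk_impact_score(s, w, 1)$weighted_sum - 1e-12
    )
  }
})

test_that("score-sheet validation finds missing, out-of-range and off-list cells", {
  crit <- default_criteria()
  groups <- c("G1", "G2")
  items <- c("rf01", "rf02")
  sheet <- expand.grid(
    group = groups, item = items, criterion = crit$id[crit$stream == "risk"],
    stringsAsFactors = FALSE
  )
  sheet$stream <- "risk"
  sheet$value <- 2
  shortlists <- list(risk = data.frame(item = items))

  expect_identical(
    nrow(report_errors(validate_scores(sheet, shortlists, crit, groups))), 0L
  )

  bad <- sheet
  bad$value[1] <- 4
  errs <- report_errors(validate_scores(bad, shortlists, crit, groups))
  expect_identical(nrow(errs), 1L)
  expect_match(errs$message, bad$item[1])
  expect_match(errs$message, bad$criterion[1])
  expect_match(errs$message, bad$group[1])

  offlist <- rbind(sheet, data.frame(
    group = "G1", item = "rf09", criterion = "scope", stream = "risk", value = 2
  ))
  errs2 <- report_errors(validate_scores(offlist, shortlists, crit, groups))
  expect_true(any(grepl("not on the shortlist", errs2$message)))

  incomplete <- sheet[-1, ]
  errs3 <- report_errors(validate_scores(incomplete, shortlists, crit, groups))
  expect_true(any(grepl("missing score", errs3$message)))
})

test_that("composite_scores applies each group's own weights", {
  crit <- default_criteria()
  wc <- weighted_criteria(crit, "risk")
  scores <- expand.grid(
    group = c("G1", "G2"), item = "rf01",
    criterion = crit$id[crit$stream == "risk"], stringsAsFactors = FALSE
  )
  scores$stream <- "risk"
  scores$value <- ifelse(scores$criterion == "scope", 3, 2)
  weights <- rbind(
    data.frame(
      group = "G1", stream = "risk", criterion = wc,
      weight = c(0.5, 0.3, 0.2), lambda_max = 3, ci = 0, cr = 0, cr_flag = FALSE
    ),
    data.frame(
      group = "G2", stream = "risk", criterion = wc,
      weight = rep(1 / 3, 3), lambda_max = 3, ci = 0, cr = 0, cr_flag = FALSE
    )
  )
  comp <- composite_scores(scores, weights, crit)
  # G1: (0.5*3 + 0.3*2 + 0.2*2) * 2 = 5.0 ; G2: (7/3) * 2
  expect_equal(comp$value[comp$group == "G1"], 5.0, tolerance = 1e-12)
  expect_equal(comp$value[comp$group == "G2"], 14 / 3, tolerance = 1e-12)
})
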