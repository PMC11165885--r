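test_that("min-max normalisation maps extremes to 0 and 1", {
  n <- normalise_scores(c(A = 2, B = 5, C = 9))
  expect_equal(as.numeric(n), c(0, 3 / 7, 1), tolerance = 1e-12)
  expect_false(attr(n, "degenerate"))

  deg <- normalise_scores(c(A = 4.2, B = 4.2))
  expect_equal(as.numeric(deg), c(0, 0))
  expect_true(attr(deg, "degenerate"))

  single <- normalise_scores(c(A = 7))
  expect_equal(as.numeric(single), 0)
  expect_true(attr(single, "degenerate"))

  expect_error(normalise_scores(numeric(0)), "empty")
})

test_that("normalisation is invariant under positive affine transforms", {
  set.seed(5)
  for (i in 1:30) {
    v <- setNames(runif(6, 1, 9), paste0("i", 1:6))
    a <- runif(1, 0.1, 5)
    b <- runif(1, -3, 3)
    expect_equal(
      as.numeric(normalise_scores(v)),
      as.numeric(normalise_scores(a * v + b)),
      tolerance = 1e-9
    )
  }
})

test_that("competition ranking shares the best rank and skips after ties", {
  r <- rank_scores(c(A = 1.0, B = 0.0, C = 0.4286))
  expect_identical(r$rank, c(A = 1L, B = 3L, C = 2L))
  expect_length(r$ties, 0)

  r2 <- rank_scores(c(A = 1.0, B = 1.0, C = 0.2))
  expect_identical(r2$rank, c(A = 1L, B = 1L, C = 3L))
  expect_identical(r2$ties, list(c("A", "B")))

  r3 <- rank_scores(c(A = 0, B = 0, C = 0))
  expect_identical(unname(r3$rank), c(1L, 1L, 1L))
  expect_identical(r3$ties, list(c("A", "B", "C")))
})

test_that("ranks depend only on score order (monotone-transform invariance)", {
  set.seed(23)
  for (i in 1:30) {
    v <- setNames(runif(7, 1, 9), paste0("i", 1:7))
    transformed <- exp(2 * v) + 1 # strictly monotone
    expect_identical(
      rank_scores(normalise_scores(v))$rank,
      rank_scores(normalise_scores(transformed))$rank
    )
  }
})

make_composites <- function(values_by_group, stream = "risk") {
  do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(
      group = g, stream = stream, item = names(v),
      weighted_sum = v, multiplier = 1L, value = v, stringsAsFactors = FALSE
    )
  }))
}

test_that("ranking table combines groups by mean normalised score", {
  comp <- make_composites(list(
    G1 = c(A = 9, B = 1),
    G2 = c(A = 5, B = 9)
  ))
  tab <- ranking_table(comp, "risk")
  # A: normalised (1, 0), B: (0, 1) -> combined 0.5 each: a full tie
  expect_equal(tab$combined_score, c(0.5, 0.5))
  expect_identical(tab$combined_rank, c(1L, 1L))
  expect_identical(attr(tab, "tie_sets"), list(c("A", "B")))

  comp2 <- make_composites(list(
    G1 = c(A = 9, B = 1, C = 5),
    G2 = c(A = 7, B = 9, C = 1)
  ))
  tab2 <- ranking_table(comp2, "risk")
  # A: (1, 0.75) -> 0.875 ; B: (0, 1) -> 0.5 ; C: (0.5, 0) -> 0.25
  expect_equal(
    setNames(tab2$combined_score, tab2$item),
    c(A = 0.875, B = 0.5, C = 0.25),
    tolerance = 1e-12
  )
  expect_identical(setNames(tab2$combined_rank, tab2$item), c(A = 1L, B = 2L, C = 3L))
  # combined score reaches 1 only for an item top-ranked in every group
  expect_true(all(tab2$combined_score < 1))

  # single group: combined rank equals the group rank
  comp1 <- make_composites(list(G1 = c(A = 9, B = 3, C = 1)))
  tab1 <- ranking_table(comp1, "risk")
  expect_identical(tab1$combined_rank, tab1$rank_G1)
})

test_that("degenerate groups are flagged and all-degenerate collapses to one tie", {
  comp <- make_composites(list(
    G1 = c(A = 4, B = 4),
    G2 = c(A = 6, B = 6)
  ))
  tab <- ranking_table(comp, "risk")
  expect_identical(attr(tab, "degenerate_groups"), c("G1", "G2"))
  expect_equal(tab$combined_score, c(0, 0))
  expect_identical(tab$combined_rank, c(1L, 1L))
  expect_identical(attr(tab, "tie_sets"), list(c("A", "B")))
})

test_that("items missing from a group are a hard error", {
  comp <- make_composites(list(G1 = c(A = 9, B = 1), G2 = c(A = 5)))
  expect_error(ranking_table(comp, "risk"), "\\(B, G2\\)")
})

test_that("manual overrides resolve ties but cannot touch non-tied items", {
  comp <- make_composites(list(
    G1 = c(A = 9, B = 1, C = 5),
    G2 = c(A = 1, B = 9, C = 5)
  ))
  tab <- ranking_table(comp, "risk")
  expect_identical(attr(tab, "tie_sets"), list(c("A", "B", "C")))

  fixed <- apply_overrides(tab, c(A = 1L, B = 2L, C = 3L))
  expect_identical(setNames(fixed$combined_rank, fixed$item), c(A = 1L, B = 2L, C = 3L))
  expect_true(all(fixed$override))
  expect_match(fixed$note[1], "manual tie-break")
  expect_length(attr(fixed, "tie_sets"), 0)

  # override on a non-tied item
  comp2 <- make_composites(list(G1 = c(A = 9, B = 5, C = 1)))
  tab2 <- ranking_table(comp2, "risk")
  expect_error(apply_overrides(tab2, c(B = 1L)), "not in any reported tie set")

  # override that leaves rank 1 unoccupied is an invalid competition ranking
  expect_error(apply_overrides(tab, c(A = 2L, B = 2L, C = 3L)), "invalid competition ranking")
})
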