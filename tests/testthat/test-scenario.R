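test_that("combo_scenario validates probabilities and monotonicity", {
  expect_error(combo_scenario(matrix(c(0, 0.2, 0.3, 0.4), 2, 2), gamma = 0.2),
               "strictly in \\(0, 1\\)")
  expect_error(combo_scenario(matrix(c(0.3, 0.2, 0.25, 0.4), 2, 2,
                                     byrow = TRUE), gamma = 0.2),
               "monotone")
  expect_error(combo_scenario(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2),
                              gamma = 1.2),
               "gamma")
  # efficacy must decrease (default direction) along the grid
  expect_error(
    combo_scenario(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2),
                   eff = matrix(c(0, 1, 2, 3), 2, 2), gamma = 0.2),
    "efficacy"
  )
})

test_that("derive_targets finds all cells closest to gamma", {
  tox <- matrix(c(0.05, 0.30, 0.30, 0.45), 2, 2, byrow = TRUE)
  tg <- derive_targets(tox, 0.30)
  expect_equal(tg, matrix(c(1L, 2L, 2L, 1L), 2, 2,
                          dimnames = list(NULL, c("k", "l"))))
  # no exact hit: unique nearest cell
  tg2 <- derive_targets(matrix(c(0.1, 0.2, 0.32, 0.5), 2, 2, byrow = TRUE),
                        0.30)
  expect_equal(nrow(tg2), 1L)
  expect_equal(unname(tg2[1, ]), c(2L, 1L))
})

test_that("assignments permute the sorted values and recover the truth", {
  sc <- worked_scenario()
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  expect_equal(a$sorted_values, c(0.10, 0.20, 0.30, 0.40))
  # true ordering's assignment reproduces the scenario matrix
  expect_equal(matrix(a$values[a$true_index, ], 2, 2, byrow = TRUE), sc$tox)
  # worked example: the other ordering swaps the anti-diagonal
  other <- a$values[-a$true_index, ]
  expect_equal(matrix(other, 2, 2, byrow = TRUE),
               matrix(c(0.10, 0.20, 0.30, 0.40), 2, 2, byrow = TRUE))
})

test_that("every assignment is monotone along the grid partial order", {
  sc <- combo_scenario(distinct_tox(3, 3), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  for (s in seq_len(os$S)) {
    m <- matrix(a$values[s, ], 3, 3, byrow = TRUE)
    expect_true(all(m[, -1] >= m[, -3]))
    expect_true(all(m[-1, ] >= m[-3, ]))
  }
})

test_that("assignment round-trip: rank inversion recovers the sorted values", {
  sc <- combo_scenario(distinct_tox(2, 4), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  for (s in seq_len(os$S)) {
    inv <- order(a$ranks[s, ])
    expect_equal(a$values[s, inv], a$sorted_values)
  }
})

test_that("worked-example prior is 1/2 at contested positions, 1 at corners", {
  sc <- worked_scenario()
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  expect_equal(a$t, matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE))
  h <- matrix(exp(a$log_prior[1, ]), 2, 2, byrow = TRUE)
  expect_equal(h, matrix(c(1, 0.5, 0.5, 1), 2, 2))
})

test_that("prior modes: distinct-value masses sum to 1 under the default", {
  sc <- combo_scenario(distinct_tox(2, 3), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  for (mode in c("distinct_values", "ordering_frequency")) {
    a <- ordering_assignments(sc, os, prior_mode = mode)
    for (pos in seq_len(6)) {
      df <- unique(data.frame(v = a$values[, pos],
                              h = exp(a$log_prior[, pos])))
      expect_equal(sum(df$h), 1, tolerance = 1e-12)
    }
  }
})

test_that("all prior modes coincide on the 2x2 example", {
  sc <- worked_scenario()
  os <- enumerate_orderings(sc$grid)
  a1 <- ordering_assignments(sc, os, prior_mode = "distinct_values")
  a2 <- ordering_assignments(sc, os, prior_mode = "per_ordering")
  a3 <- ordering_assignments(sc, os, prior_mode = "ordering_frequency")
  # per_ordering is 1/S = 1/2 everywhere; the others are 1/2 at contested
  # positions only -- but all are position-constant across orderings here,
  # so the induced posteriors agree (checked in test-posterior.R); the
  # frequency mode matches distinct_values exactly on this grid
  expect_equal(a1$log_prior, a3$log_prior)
  expect_true(all(a2$log_prior == log(0.5)))
})

test_that("efficacy assignments sort decreasing for decreasing direction", {
  eff <- matrix(c(0.5, 0, -1.5, -2.5, -1.5, -2, -3.5, -4.5), 2, 4,
                byrow = TRUE)
  tox <- distinct_tox(2, 4)
  sc <- combo_scenario(tox, eff = eff, phi = 0.3, psi = 0, n = 10,
                       targets = cbind(2, 2))
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os, endpoint = "efficacy")
  expect_equal(a$sorted_values, sort(as.vector(eff), decreasing = TRUE))
  expect_equal(matrix(a$values[a$true_index, ], 2, 4, byrow = TRUE), eff)
})

test_that("mismatched grids and missing efficacy are rejected", {
  sc <- worked_scenario()
  os3 <- enumerate_orderings(dose_grid(3, 3))
  expect_error(ordering_assignments(sc, os3), "different grid")
  os <- enumerate_orderings(sc$grid)
  expect_error(ordering_assignments(sc, os, endpoint = "efficacy"),
               "no efficacy")
})

test_that("candidate_value_counts has 1 at corners for distinct values", {
  sc <- combo_scenario(distinct_tox(3, 5), gamma = 0.3)
  a <- ordering_assignments(sc, enumerate_orderings(sc$grid))
  tc <- candidate_value_counts(a)
  expect_equal(tc[1, 1], 1L)
  expect_equal(tc[3, 5], 1L)
  expect_true(all(tc >= 1L))
})
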