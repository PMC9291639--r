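test_that("worked example: binomial anchors, posterior (0.69, 0.31)", {
  expect_equal(round(dbinom(1, 10, 0.10), 2), 0.39)
  expect_equal(round(dbinom(6, 10, 0.40), 2), 0.11)
  expect_equal(round(dbinom(5, 10, 0.30), 2), 0.10)
  expect_equal(round(dbinom(5, 10, 0.20), 2), 0.03)
  expect_equal(round(dbinom(2, 10, 0.20), 2), 0.30)
  expect_equal(round(dbinom(2, 10, 0.30), 2), 0.23)

  sc <- worked_scenario()
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  x <- binary_responses(as_profiles(worked_profiles()), sc$tox)
  post <- ordering_posterior_binary(x, a)
  probs <- sort(post$probs, decreasing = TRUE)
  expect_equal(round(probs, 2), c(0.69, 0.31))
  # the mass 0.69 sits on the true ordering
  expect_equal(which.max(post$probs), a$true_index)
})

test_that("posteriors are normalized and nonnegative", {
  sc <- combo_scenario(distinct_tox(3, 3), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  x <- binary_responses(generate_profiles(20, seed = 1), sc$tox)
  post <- ordering_posterior_binary(x, a)
  expect_true(all(post$probs >= 0))
  expect_equal(sum(post$probs), 1, tolerance = 1e-12)
})

test_that("S = 1 grid gives a unit posterior", {
  sc <- combo_scenario(distinct_tox(1, 4), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  x <- binary_responses(generate_profiles(15, seed = 2), sc$tox)
  expect_equal(ordering_posterior_binary(x, a)$probs, 1)
})

test_that("all-zero weights annihilate the likelihood: uniform posterior", {
  sc <- combo_scenario(distinct_tox(2, 3), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  x <- binary_responses(generate_profiles(12, seed = 3), sc$tox)
  post <- ordering_posterior_binary(x, a, weights = matrix(0, 2, 3))
  expect_equal(post$probs, rep(1 / os$S, os$S))
})

test_that("binary posterior agrees with the brute-force oracle on small grids", {
  set.seed(42)
  for (dims in list(c(2, 2), c(2, 3))) {
    sc <- combo_scenario(distinct_tox(dims[1], dims[2]), gamma = 0.3)
    os <- enumerate_orderings(sc$grid)
    for (mode in c("distinct_values", "per_ordering", "ordering_frequency")) {
      a <- ordering_assignments(sc, os, prior_mode = mode)
      for (rep in 1:5) {
        n <- sample(4:12, 1)
        x <- binary_responses(generate_profiles(n), sc$tox)
        got <- ordering_posterior_binary(x, a)$probs
        want <- brute_posterior_binary(x$counts, n, a)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("continuous posterior agrees with the brute-force oracle", {
  eff <- matrix(c(1, 0.5, -0.5, -1), 2, 2, byrow = TRUE)
  sc <- combo_scenario(distinct_tox(2, 2), eff = eff, gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os, endpoint = "efficacy")
  y <- continuous_responses(generate_profiles(6, seed = 4), eff)
  got <- ordering_posterior_continuous(y, a)$probs
  want <- brute_posterior_continuous(y$y, a)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("continuous posterior concentrates on the generating ordering", {
  eff <- matrix(c(2, 1, -1, -2), 2, 2, byrow = TRUE)
  sc <- combo_scenario(distinct_tox(2, 2), eff = eff, gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os, endpoint = "efficacy")
  y <- continuous_responses(generate_profiles(500, seed = 5), eff)
  post <- ordering_posterior_continuous(y, a)
  expect_gt(post$probs[a$true_index], 0.99)
})

test_that("identical assignments under all orderings give a uniform posterior", {
  # constant efficacy surface: every ordering assigns the same values
  eff <- matrix(-1, 2, 2)
  sc <- combo_scenario(distinct_tox(2, 2), eff = eff, gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os, endpoint = "efficacy")
  y <- continuous_responses(generate_profiles(10, seed = 6), eff)
  expect_equal(ordering_posterior_continuous(y, a)$probs, c(0.5, 0.5))
})

test_that("permutation equivariance: relabeling orderings permutes probs", {
  sc <- combo_scenario(distinct_tox(2, 3), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  x <- binary_responses(generate_profiles(10, seed = 7), sc$tox)
  post <- ordering_posterior_binary(x, a)$probs

  perm <- rev(seq_len(os$S))
  a2 <- a
  a2$ranks <- a$ranks[perm, , drop = FALSE]
  a2$values <- a$values[perm, , drop = FALSE]
  a2$log_prior <- a$log_prior[perm, , drop = FALSE]
  post2 <- ordering_posterior_binary(x, a2)$probs
  expect_equal(post2, post[perm], tolerance = 1e-12)
})

test_that("replicating the data does not increase posterior entropy on average", {
  sc <- combo_scenario(distinct_tox(2, 3), gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  set.seed(8)
  d <- replicate(200, {
    n <- 10
    x <- binary_responses(generate_profiles(n), sc$tox)
    e1 <- entropy_nats(ordering_posterior_binary(x, a)$probs)
    e2 <- entropy_nats(
      ordering_posterior_binary(2 * x$counts, a, n = 2 * n)$probs
    )
    e2 - e1
  })
  expect_lte(mean(d), 0)
})

test_that("degenerate likelihoods are reported with the position", {
  sc <- worked_scenario()
  os <- enumerate_orderings(sc$grid)
  a <- ordering_assignments(sc, os)
  a$sorted_values[1] <- 0 # impossible candidate given positive counts
  expect_error(ordering_posterior_binary(matrix(c(5, 5, 5, 5), 2, 2), a,
                                         n = 5),
               "degenerate likelihood at position")
})

test_that("count bounds are validated", {
  sc <- worked_scenario()
  a <- ordering_assignments(sc, enumerate_orderings(sc$grid))
  expect_error(ordering_posterior_binary(matrix(c(1, 2, 3, 11), 2, 2), a,
                                         n = 10),
               "0..n")
  expect_error(ordering_posterior_binary(matrix(1, 2, 2), a), "n must be")
})

test_that("joint posterior is the renormalized outer product", {
  p1 <- c(0.2, 0.3, 0.5)
  p2 <- c(0.1, 0.2, 0.3, 0.4)
  post_t <- pobench:::new_ordering_posterior(p1, log(p1), "toxicity")
  post_e <- pobench:::new_ordering_posterior(p2, log(p2), "efficacy")
  jp <- joint_ordering_posterior(post_t, post_e)
  expect_equal(jp$probs, outer(p1, p2) / sum(outer(p1, p2)))
  expect_equal(sum(jp$probs), 1)
  # uniform x uniform is uniform over pairs
  u1 <- rep(1 / 3, 3)
  u2 <- rep(1 / 4, 4)
  ju <- joint_ordering_posterior(
    pobench:::new_ordering_posterior(u1, log(u1), "toxicity"),
    pobench:::new_ordering_posterior(u2, log(u2), "efficacy")
  )
  expect_true(all(abs(ju$probs - 1 / 12) < 1e-12))
  # degenerate marginals give a point mass at the pair
  d1 <- c(1, 0, 0)
  d2 <- c(0, 1, 0, 0)
  jd <- joint_ordering_posterior(
    pobench:::new_ordering_posterior(d1, NULL, "toxicity"),
    pobench:::new_ordering_posterior(d2, NULL, "efficacy")
  )
  expect_equal(jd$probs[1, 2], 1)
  expect_equal(sum(jd$probs), 1)
})

test_that("shared posterior: constant efficacy reduces to the binary posterior", {
  tox <- distinct_tox(2, 2)
  eff <- matrix(-1, 2, 2)
  sc <- combo_scenario(tox, eff = eff, gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a_t <- ordering_assignments(sc, os, "toxicity")
  a_e <- ordering_assignments(sc, os, "efficacy")
  pr <- generate_profiles(10, endpoints = 2, seed = 9)
  x <- binary_responses(pr, tox, endpoint = 1)
  y <- continuous_responses(pr, eff, endpoint = 2)
  shared <- shared_ordering_posterior(x, y, a_t, a_e)
  alone <- ordering_posterior_binary(x, a_t)
  expect_equal(shared$probs, alone$probs, tolerance = 1e-12)
})

test_that("shared posterior matches a brute-force oracle on a 2x2 instance", {
  tox <- distinct_tox(2, 2)
  eff <- matrix(c(1, 0.2, -0.6, -1.4), 2, 2, byrow = TRUE)
  sc <- combo_scenario(tox, eff = eff, gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a_t <- ordering_assignments(sc, os, "toxicity")
  a_e <- ordering_assignments(sc, os, "efficacy")
  pr <- generate_profiles(8, endpoints = 2, seed = 10)
  x <- binary_responses(pr, tox, endpoint = 1)
  y <- continuous_responses(pr, eff, endpoint = 2)
  got <- shared_ordering_posterior(x, y, a_t, a_e)$probs

  w <- as.vector(t(ordering_weights(sc$grid)))
  terms <- vapply(seq_len(os$S), function(s) {
    lik_t <- dbinom(as.vector(t(x$counts)), 8, a_t$values[s, ])
    lik_e <- vapply(1:4, function(pos) {
      prod(dnorm(y$y[, pos], a_e$values[s, pos], 1))
    }, numeric(1))
    h <- exp(a_t$log_prior[s, ])
    prod((lik_t * lik_e * h)^w)
  }, numeric(1))
  expect_equal(got, terms / sum(terms), tolerance = 1e-10)
})

test_that("mismatched ordering sets are rejected for the shared posterior", {
  tox <- distinct_tox(2, 2)
  eff <- matrix(c(1, 0.2, -0.6, -1.4), 2, 2, byrow = TRUE)
  sc <- combo_scenario(tox, eff = eff, gamma = 0.3)
  os <- enumerate_orderings(sc$grid)
  a_t <- ordering_assignments(sc, os, "toxicity")
  a_e <- ordering_assignments(sc, os, "efficacy")
  a_e$ranks <- a_e$ranks[c(2, 1), ]
  pr <- generate_profiles(8, endpoints = 2, seed = 11)
  x <- binary_responses(pr, tox, endpoint = 1)
  y <- continuous_responses(pr, eff, endpoint = 2)
  expect_error(shared_ordering_posterior(x, y, a_t, a_e),
               "common ordering set")
})

test_that("entropy helper handles zeros and uniform vectors", {
  expect_equal(entropy_nats(c(1, 0, 0)), 0)
  expect_equal(entropy_nats(rep(0.25, 4)), log(4))
})
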