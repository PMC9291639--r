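# Shared fixtures: the 2x2 worked example (ten printed latent profiles) and a
# direct, non-log brute-force posterior used as an oracle on small grids.

worked_profiles <- function() {
  c(0.59, 0.01, 0.29, 0.28, 0.81, 0.26, 0.72, 0.31, 0.95, 0.11)
}

worked_scenario <- function() {
  combo_scenario(
    tox = matrix(c(0.10, 0.30, 0.20, 0.40), 2, 2, byrow = TRUE),
    gamma = 0.20
  )
}

# Straight-line direct-space reimplementation of the weighted-likelihood
# ordering posterior (binary endpoint). Only usable for small n (no log
# space): probs[s] = prod_pos (Bin(x_pos; n, q_pos^(s)) * h_pos^(s))^w_pos.
brute_posterior_binary <- function(x_mat, n, assignments, weights = NULL) {
  if (is.null(weights)) weights <- ordering_weights(assignments$grid)
  w <- as.vector(t(weights))
  x <- as.vector(t(x_mat))
  S <- assignments$n_orderings
  terms <- numeric(S)
  for (s in seq_len(S)) {
    q <- assignments$values[s, ]
    h <- exp(assignments$log_prior[s, ])
    terms[s] <- prod((dbinom(x, n, q) * h)^w)
  }
  terms / sum(terms)
}

# Same for a continuous normal endpoint with responses y (n x positions).
brute_posterior_continuous <- function(y, assignments, sd = 1,
                                       weights = NULL) {
  if (is.null(weights)) weights <- ordering_weights(assignments$grid)
  w <- as.vector(t(weights))
  S <- assignments$n_orderings
  terms <- numeric(S)
  for (s in seq_len(S)) {
    lik <- vapply(seq_len(ncol(y)), function(pos) {
      prod(dnorm(y[, pos], assignments$values[s, pos], sd))
    }, numeric(1))
    h <- exp(assignments$log_prior[s, ])
    terms[s] <- prod((lik * h)^w)
  }
  terms / sum(terms)
}

# A strictly monotone K x L toxicity matrix with distinct entries in (0, 1).
distinct_tox <- function(K, L) {
  matrix(seq_len(K * L), K, L, byrow = TRUE) / (K * L + 1)
}
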