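# Ordering posteriors via the weighted (power) likelihood.
#
# All arithmetic is in log space with max-subtraction normalization: with up
# to 6006 orderings and 15 combinations, direct-space products underflow.

# Normalize a vector of unnormalized log masses; positions with w == 0 have
# been skipped upstream, so an all -Inf vector signals a degenerate
# likelihood.
softmax_log <- function(log_terms) {
  m <- max(log_terms)
  if (!is.finite(m)) {
    stop("degenerate likelihood: all orderings have zero mass", call. = FALSE)
  }
  p <- exp(log_terms - m)
  p / sum(p)
}

new_ordering_posterior <- function(probs, log_terms, endpoint) {
  structure(list(probs = probs, log_terms = log_terms, endpoint = endpoint),
            class = "ordering_posterior")
}

#' @export
print.ordering_posterior <- function(x, ...) {
  cat(sprintf("<ordering_posterior> %s, %d orderings\n",
              paste(x$endpoint, collapse = " x "), length(x$probs)))
  if (length(x$probs) <= 10) print(round(x$probs, 4))
  invisible(x)
}

#' Shannon entropy in nats
#'
#' @param p Probability vector (summing to 1); zero entries contribute 0.
#' @return Entropy in nats.
#' @export
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Core scorer: log_terms[s] = sum_pos w[pos] * (loglik[rank, pos] + log h)
# where loglik_by_rank is a (K*L) x (K*L) matrix of the position-pos
# log-likelihood evaluated at the rank-r candidate value. Positions with
# w == 0 are skipped (their power term is identically 1).
score_orderings <- function(loglik_by_rank, assignments, w_vec) {
  S <- assignments$n_orderings
  active <- which(w_vec > 0)
  log_terms <- numeric(S)
  if (length(active)) {
    lw <- sweep(loglik_by_rank[, active, drop = FALSE], 2, w_vec[active], `*`)
    n_rank <- nrow(loglik_by_rank)
    # keep lin a plain vector: a 2-column index matrix would be read as
    # (row, col) coordinate pairs instead of linear indices
    lin <- as.vector(assignments$ranks[, active, drop = FALSE] +
                       rep((seq_along(active) - 1L) * n_rank, each = S))
    log_terms <- .rowSums(lw[lin], S, length(active)) +
      as.vector(assignments$log_prior[, active, drop = FALSE] %*%
                  w_vec[active])
  }
  if (any(is.nan(log_terms))) {
    stop("degenerate likelihood (0 * Inf) encountered while scoring orderings",
         call. = FALSE)
  }
  log_terms
}

check_degenerate <- function(ll, grid) {
  if (any(is.infinite(ll))) {
    bad <- which(is.infinite(ll), arr.ind = TRUE)[1, ]
    kl <- pos_to_kl(bad[["col"]], grid$L)
    stop(sprintf(
      "degenerate likelihood at position (%d,%d): candidate value incompatible with the observed responses",
      kl[1, "k"], kl[1, "l"]
    ), call. = FALSE)
  }
  invisible(ll)
}

#' Posterior probability of each ordering, binary endpoint
#'
#' Given complete-information DLT counts \eqn{x_{kl}} out of n patients, the
#' probability that ordering s' is the correct one is proportional to the
#' weighted (power) likelihood
#' \deqn{\prod_{k,l} \left[ \mathrm{Bin}(x_{kl}; n, q^{(s')}_{kl}) \,
#'   h^{(s')}_{kl} \right]^{w_{kl}},}
#' normalized over the S feasible orderings. The binomial coefficient is kept
#' inside the power bracket: it cancels only when the weights are constant.
#'
#' @param responses A binary `response_set` from [binary_responses()], or a
#'   K x L count matrix (then `n` must be given).
#' @param assignments An [ordering_assignments()] result (toxicity endpoint).
#' @param weights K x L weight matrix; defaults to [ordering_weights()] on
#'   the assignment's grid.
#' @param n Sample size when `responses` is a plain matrix.
#' @return An `ordering_posterior` with `probs` (length S, summing to 1) and
#'   `log_terms` (unnormalized log masses, diagnostic).
#' @examples
#' sc <- combo_scenario(matrix(c(0.10, 0.30, 0.20, 0.40), 2, 2, byrow = TRUE),
#'                      gamma = 0.20)
#' os <- enumerate_orderings(sc$grid)
#' a <- ordering_assignments(sc, os)
#' u <- c(0.59, 0.01, 0.29, 0.28, 0.81, 0.26, 0.72, 0.31, 0.95, 0.11)
#' x <- binary_responses(as_profiles(u), sc$tox)
#' round(ordering_posterior_binary(x, a)$probs, 2)
#' @export
ordering_posterior_binary <- function(responses, assignments, weights = NULL,
                                      n = NULL) {
  stopifnot(inherits(assignments, "ordering_assignment"))
  if (inherits(responses, "response_set")) {
    x_mat <- responses$counts
    n <- responses$n
  } else {
    x_mat <- as.matrix(responses)
    if (is.null(n)) stop("n must be supplied with a raw count matrix",
                         call. = FALSE)
  }
  if (any(x_mat < 0) || any(x_mat > n)) {
    stop("counts must lie in 0..n", call. = FALSE)
  }
  if (is.null(weights)) weights <- ordering_weights(assignments$grid)
  w_vec <- as.vector(t(as.matrix(weights)))
  x_vec <- as.vector(t(x_mat))

  ll <- outer(assignments$sorted_values, x_vec,
              function(q, x) stats::dbinom(x, size = n, prob = q, log = TRUE))
  check_degenerate(ll, assignments$grid)
  log_terms <- score_orderings(ll, assignments, w_vec)
  new_ordering_posterior(softmax_log(log_terms), log_terms, "toxicity")
}

#' Posterior probability of each ordering, continuous endpoint
#'
#' Same construction as [ordering_posterior_binary()] with the
#' product-density likelihood
#' \eqn{\mathcal{L}(y_{kl}, \lambda) = \prod_i f(y^{(i)}_{kl}; \lambda)}
#' per combination.
#'
#' @param responses A continuous `response_set` from
#'   [continuous_responses()].
#' @param assignments An [ordering_assignments()] result (efficacy endpoint).
#' @param weights K x L weight matrix; defaults to [ordering_weights()].
#' @return An `ordering_posterior`.
#' @export
ordering_posterior_continuous <- function(responses, assignments,
                                          weights = NULL) {
  stopifnot(inherits(responses, "response_set"),
            responses$type == "continuous",
            inherits(assignments, "ordering_assignment"))
  if (is.null(weights)) weights <- ordering_weights(assignments$grid)
  w_vec <- as.vector(t(as.matrix(weights)))
  fam <- responses$family

  sv <- assignments$sorted_values
  ll <- vapply(
    seq_len(ncol(responses$y)),
    function(pos) vapply(sv, function(th) {
      sum(fam$logdens(responses$y[, pos], th))
    }, numeric(1)),
    numeric(length(sv))
  )
  if (any(!is.finite(ll))) check_degenerate(ll, assignments$grid)
  log_terms <- score_orderings(ll, assignments, w_vec)
  new_ordering_posterior(softmax_log(log_terms), log_terms, "efficacy")
}

#' Joint posterior over pairs of endpoint orderings
#'
#' When the toxicity and efficacy orderings may differ, the probability of
#' identifying the pair (s_t, s_e) is the product of the marginal ordering
#' posteriors, renormalized over all pairs.
#'
#' @param post_t,post_e `ordering_posterior` objects for the two endpoints.
#' @return An `ordering_posterior` whose `probs` is an S_t x S_e matrix.
#' @export
joint_ordering_posterior <- function(post_t, post_e) {
  stopifnot(inherits(post_t, "ordering_posterior"),
            inherits(post_e, "ordering_posterior"))
  m <- outer(post_t$probs, post_e$probs)
  m <- m / sum(m)
  new_ordering_posterior(m, log(m), c(post_t$endpoint, post_e$endpoint))
}

#' Posterior of a single ordering shared by two endpoints
#'
#' When toxicity and efficacy are assumed to follow the same complete
#' ordering, the per-position likelihoods of both endpoints multiply inside
#' the power bracket:
#' \deqn{\mathbb{P}(s = s' \mid \cdot) \propto \prod_{k,l}
#'   [\mathcal{L}_t \, \mathcal{L}_e \, h^{(s')}_{kl}]^{w_{kl}}.}
#'
#' @param tox_responses Binary `response_set` for toxicity.
#' @param eff_responses Continuous `response_set` for efficacy.
#' @param assignments_t,assignments_e [ordering_assignments()] for the two
#'   endpoints, built from the same ordering set (same S, common index).
#' @param weights K x L weight matrix; defaults to [ordering_weights()].
#' @return An `ordering_posterior` of length S.
#' @export
shared_ordering_posterior <- function(tox_responses, eff_responses,
                                      assignments_t, assignments_e,
                                      weights = NULL) {
  stopifnot(inherits(assignments_t, "ordering_assignment"),
            inherits(assignments_e, "ordering_assignment"))
  if (assignments_t$n_orderings != assignments_e$n_orderings ||
      !identical(assignments_t$ranks, assignments_e$ranks)) {
    stop("shared-ordering posterior requires a common ordering set",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- ordering_weights(assignments_t$grid)
  w_vec <- as.vector(t(as.matrix(weights)))

  x_vec <- as.vector(t(tox_responses$counts))
  n <- tox_responses$n
  ll_t <- outer(assignments_t$sorted_values, x_vec,
                function(q, x) stats::dbinom(x, size = n, prob = q,
                                             log = TRUE))
  check_degenerate(ll_t, assignments_t$grid)
  fam <- eff_responses$family
  sv_e <- assignments_e$sorted_values
  ll_e <- vapply(
    seq_len(ncol(eff_responses$y)),
    function(pos) vapply(sv_e, function(th) {
      sum(fam$logdens(eff_responses$y[, pos], th))
    }, numeric(1)),
    numeric(length(sv_e))
  )

  # score with the combined likelihood; priors enter once
  S <- assignments_t$n_orderings
  active <- which(w_vec > 0)
  log_terms <- numeric(S)
  if (length(active)) {
    n_rank <- nrow(ll_t)
    lin <- as.vector(assignments_t$ranks[, active, drop = FALSE] +
                       rep((seq_along(active) - 1L) * n_rank, each = S))
    lt <- sweep(ll_t[, active, drop = FALSE], 2, w_vec[active], `*`)
    le <- sweep(ll_e[, active, drop = FALSE], 2, w_vec[active], `*`)
    log_terms <- .rowSums(lt[lin], S, length(active)) +
      .rowSums(le[lin], S, length(active)) +
      as.vector(assignments_t$log_prior[, active, drop = FALSE] %*%
                  w_vec[active])
  }
  new_ordering_posterior(softmax_log(log_terms), log_terms,
                         "shared toxicity-efficacy")
}
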