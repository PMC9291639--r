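# Benchmark engine: original (known-ordering) benchmark and the
# partial-ordering benchmark, binary and multi-endpoint.

# Per-replicate substream seed, derived from the root seed so that any
# replicate is reproducible in isolation and execution order is irrelevant.
# Kept below 2^31 - 1 (R integer range).
replicate_seed <- function(seed, z) {
  s0 <- as.double(seed) %% 2147483647
  as.integer((s0 + as.double(z) * 1000003) %% 2147483646 + 1)
}

#' Maximum-tolerated-combination selection by absolute distance
#'
#' Selects the combination whose estimated toxicity probability is closest to
#' the target \eqn{\gamma}: the minimizer of \eqn{R(\hat q_{kl}, \gamma) =
#' |\hat q_{kl} - \gamma|}. Exact ties (within `tol`) split the selection
#' mass equally among the tied minimizers.
#'
#' @param estimates K x L matrix (or vector) of estimated toxicity
#'   probabilities.
#' @param gamma Target toxicity probability.
#' @param tol Tie tolerance on the distance.
#' @return A matrix (same shape as `estimates`) of selection mass summing
#'   to 1.
#' @examples
#' est <- matrix(c(0.10, 0.50, 0.20, 0.60), 2, 2, byrow = TRUE)
#' select_mtd(est, gamma = 0.20) # all mass on (2, 1)
#' @export
select_mtd <- function(estimates, gamma, tol = 1e-12) {
  est <- as.matrix(estimates)
  crit <- abs(est - gamma)
  hit <- crit <= min(crit) + tol
  mass <- matrix(0, nrow(est), ncol(est))
  mass[hit] <- 1 / sum(hit)
  mass
}

# Precomputations shared by every replicate of a binary-endpoint
# partial-ordering run.
po_prep <- function(scenario, orderings, gamma, prior_mode) {
  assign <- ordering_assignments(scenario, orderings, "toxicity", prior_mode)
  grid <- scenario$grid
  n_pos <- grid$K * grid$L
  w_vec <- as.vector(t(ordering_weights(grid)))
  active <- which(w_vec > 0)
  S <- orderings$S
  # invpos[s, r] = position holding rank r under ordering s
  invpos <- t(apply(orderings$ranks, 1, order))
  if (S == 1) invpos <- matrix(invpos, nrow = 1)
  # plain vector: a 2-column index matrix would be read as coordinate pairs
  lin <- as.vector(orderings$ranks[, active, drop = FALSE] +
                     rep((seq_along(active) - 1L) * n_pos, each = S))
  p_vec <- as.vector(t(scenario$tox))
  list(
    assign = assign,
    sv = assign$sorted_values,
    r0 = match(p_vec, assign$sorted_values),
    w_active = w_vec[active],
    active = active,
    lin = lin,
    S = S,
    n_pos = n_pos,
    prior_term = as.vector(assign$log_prior[, active, drop = FALSE] %*%
                             w_vec[active]),
    gamma = gamma,
    invpos = invpos
  )
}

# One complete-information replicate of the partial-ordering benchmark:
# counts, ordering posterior, per-ordering selection, weighted aggregation.
po_replicate <- function(prep, u, n) {
  cnt_r <- vapply(prep$sv, function(q) sum(u < q), numeric(1))
  x_vec <- cnt_r[prep$r0]
  ll <- outer(prep$sv, x_vec,
              function(q, x) stats::dbinom(x, size = n, prob = q, log = TRUE))
  lw <- sweep(ll[, prep$active, drop = FALSE], 2, prep$w_active, `*`)
  log_terms <- .rowSums(lw[prep$lin], prep$S, length(prep$active)) +
    prep$prior_term
  post <- softmax_log(log_terms)

  est_r <- cnt_r / n
  crit <- abs(est_r - prep$gamma)
  rmin <- which(crit <= min(crit) + 1e-12)
  Qz <- numeric(prep$n_pos)
  for (r in rmin) {
    rs <- rowsum(post, prep$invpos[, r])
    idx <- as.integer(rownames(rs))
    Qz[idx] <- Qz[idx] + rs[, 1]
  }
  Qz <- Qz / length(rmin)
  list(Qz = Qz, posterior = post, x = x_vec, counts_by_rank = cnt_r)
}

#' One benchmark replicate from explicit profiles
#'
#' Runs a single complete-information replicate of the partial-ordering
#' benchmark from given latent profiles: DLT counts, power-likelihood
#' ordering posterior, per-ordering MTC selection, and the
#' ordering-probability-weighted selection mass.
#'
#' @param scenario A [combo_scenario()] with `gamma`.
#' @param profiles A [generate_profiles()] or [as_profiles()] object.
#' @param orderings Optional pre-enumerated [enumerate_orderings()].
#' @param gamma Target toxicity; defaults to `scenario$gamma`.
#' @param prior_mode See [ordering_assignments()].
#' @return A list with `selection` (K x L matrix of selection mass),
#'   `posterior` (the `ordering_posterior`), and `counts` (K x L DLT counts).
#' @examples
#' sc <- combo_scenario(matrix(c(0.10, 0.30, 0.20, 0.40), 2, 2, byrow = TRUE),
#'                      gamma = 0.20)
#' u <- c(0.59, 0.01, 0.29, 0.28, 0.81, 0.26, 0.72, 0.31, 0.95, 0.11)
#' rep1 <- po_benchmark_single(sc, as_profiles(u))
#' round(rep1$selection, 2) # (0.00, 0.31 / 0.69, 0.00)
#' @export
po_benchmark_single <- function(scenario, profiles, orderings = NULL,
                                gamma = scenario$gamma,
                                prior_mode = "distinct_values") {
  stopifnot(inherits(scenario, "combo_scenario"),
            inherits(profiles, "profile_set"))
  if (is.null(orderings)) orderings <- enumerate_orderings(scenario$grid)
  prep <- po_prep(scenario, orderings, gamma, prior_mode)
  r <- po_replicate(prep, profiles$u[, 1], profiles$n)
  K <- scenario$grid$K
  L <- scenario$grid$L
  list(
    selection = matrix(r$Qz, K, L, byrow = TRUE),
    posterior = new_ordering_posterior(r$posterior, NULL, "toxicity"),
    counts = matrix(r$x, K, L, byrow = TRUE)
  )
}

new_benchmark_result <- function(proportions, no_selection, scenario, mode,
                                 n, Z, seed, settings,
                                 replicates = NULL) {
  pcs <- if (!is.null(scenario$targets)) {
    100 * sum(proportions[scenario$targets])
  } else {
    NA_real_
  }
  structure(
    list(
      proportions = proportions,
      no_selection = no_selection,
      pcs = pcs,
      targets = scenario$targets,
      scenario = scenario,
      mode = mode,
      n = n,
      Z = Z,
      seed = seed,
      settings = settings,
      replicates = replicates
    ),
    class = "po_benchmark_result"
  )
}

#' Partial-ordering benchmark, single binary toxicity endpoint
#'
#' Runs the full benchmark over `Z` simulated trials. Per replicate:
#' generate n latent toxicity profiles, derive complete-information DLT
#' counts at every combination, compute the power-likelihood posterior over
#' all feasible complete orderings, select the MTC under each ordering (by
#' absolute distance of the ordering-specific estimates to `gamma`, reusing
#' the same profiles), and accumulate the ordering-probability-weighted
#' selection mass. Averaging over replicates gives the selection proportion
#' of each combination; the sum over the scenario's target set is the PCS
#' upper bound.
#'
#' @param scenario A [combo_scenario()] with `gamma` and targets.
#' @param n Patients per simulated trial; defaults to `scenario$n`.
#' @param Z Number of simulated trials (default 10^4).
#' @param seed Root RNG seed; replicate z uses a derived substream seed so
#'   results do not depend on execution order.
#' @param gamma Target toxicity; defaults to the scenario's.
#' @param orderings Optional pre-enumerated ordering set (re-used across
#'   runs on the same grid).
#' @param prior_mode See [ordering_assignments()].
#' @param keep_replicates Keep the Z x (K*L) matrix of per-replicate
#'   selection masses (diagnostic).
#' @return A `po_benchmark_result`; see [tidy.po_benchmark_result()] and
#'   [compute_pcs()].
#' @export
run_po_benchmark <- function(scenario, n = scenario$n, Z = 1e4, seed = 1,
                             gamma = scenario$gamma, orderings = NULL,
                             prior_mode = "distinct_values",
                             keep_replicates = FALSE) {
  stopifnot(inherits(scenario, "combo_scenario"), !is.null(gamma),
            !is.null(n), n >= 1, Z >= 1)
  if (is.null(orderings)) orderings <- enumerate_orderings(scenario$grid)
  prep <- po_prep(scenario, orderings, gamma, prior_mode)
  Q <- numeric(prep$n_pos)
  reps <- if (keep_replicates) matrix(NA_real_, Z, prep$n_pos)
  for (z in seq_len(Z)) {
    set.seed(replicate_seed(seed, z))
    u <- stats::runif(n)
    r <- po_replicate(prep, u, n)
    Q <- Q + r$Qz
    if (keep_replicates) reps[z, ] <- r$Qz
  }
  Q <- Q / Z
  K <- scenario$grid$K
  L <- scenario$grid$L
  new_benchmark_result(
    proportions = matrix(Q, K, L, byrow = TRUE),
    no_selection = 0,
    scenario = scenario, mode = "po_benchmark",
    n = n, Z = Z, seed = seed,
    settings = list(gamma = gamma, prior_mode = prior_mode,
                    S = orderings$S),
    replicates = reps
  )
}

#' Original (known-ordering) benchmark, binary toxicity endpoint
#'
#' The complete-information benchmark under a known ordering: per replicate
#' the toxicity probabilities are estimated at every combination as
#' \eqn{\hat p_{kl} = x_{kl}/n} and the combination minimizing
#' \eqn{|\hat p_{kl} - \gamma|} is selected (ties split equally). No
#' ordering uncertainty enters; the result upper-bounds designs that know
#' the monotonic ordering.
#'
#' @inheritParams run_po_benchmark
#' @return A `po_benchmark_result` with mode `"original_benchmark"`.
#' @export
run_original_benchmark <- function(scenario, n = scenario$n, Z = 1e4,
                                   seed = 1, gamma = scenario$gamma,
                                   keep_replicates = FALSE) {
  stopifnot(inherits(scenario, "combo_scenario"), !is.null(gamma),
            !is.null(n), n >= 1, Z >= 1)
  p_vec <- as.vector(t(scenario$tox))
  n_pos <- length(p_vec)
  Q <- numeric(n_pos)
  reps <- if (keep_replicates) matrix(NA_real_, Z, n_pos)
  for (z in seq_len(Z)) {
    set.seed(replicate_seed(seed, z))
    u <- stats::runif(n)
    est <- vapply(p_vec, function(p) sum(u < p), numeric(1)) / n
    crit <- abs(est - gamma)
    hit <- crit <= min(crit) + 1e-12
    Qz <- hit / sum(hit)
    Q <- Q + Qz
    if (keep_replicates) reps[z, ] <- Qz
  }
  Q <- Q / Z
  K <- scenario$grid$K
  L <- scenario$grid$L
  new_benchmark_result(
    proportions = matrix(Q, K, L, byrow = TRUE),
    no_selection = 0,
    scenario = scenario, mode = "original_benchmark",
    n = n, Z = Z, seed = seed,
    settings = list(gamma = gamma),
    replicates = reps
  )
}

#' Proportion of correct selections
#'
#' Sums the selection proportions over the target combinations, expressed as
#' a percentage.
#'
#' @param result A `po_benchmark_result`.
#' @param targets Optional two-column (k, l) matrix overriding the
#'   scenario's target set.
#' @return PCS in percent.
#' @export
compute_pcs <- function(result, targets = NULL) {
  stopifnot(inherits(result, "po_benchmark_result"))
  if (is.null(targets)) targets <- result$targets
  if (is.null(targets) || nrow(targets) == 0) {
    stop("no target combinations available", call. = FALSE)
  }
  if (is.list(targets)) targets <- do.call(rbind, targets)
  100 * sum(result$proportions[matrix(as.integer(targets), ncol = 2)])
}

#' Ratio of a design's PCS to a benchmark's PCS
#'
#' Standardizes a design's proportion of correct selections against the
#' benchmark upper bound, in percent (e.g. 72.8 vs 73.8 gives 98.6).
#'
#' @param pcs_design,pcs_benchmark PCS values in percent.
#' @return The ratio in percent.
#' @export
pcs_ratio <- function(pcs_design, pcs_benchmark) {
  100 * pcs_design / pcs_benchmark
}
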