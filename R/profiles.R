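#' Normal endpoint family
#'
#' Endpoint distribution family with a location parameter per combination and
#' a fixed, known standard deviation. Used as the efficacy distribution in
#' Phase I/II benchmark runs (e.g. change in a log-transformed continuous
#' biomarker, N(mu_kl, 1)).
#'
#' @param sd Fixed standard deviation, default 1.
#' @return An `endpoint_family` with quantile and log-density functions of
#'   the location parameter.
#' @export
normal_family <- function(sd = 1) {
  stopifnot(is.numeric(sd), sd > 0)
  structure(
    list(
      name = "normal",
      sd = sd,
      qfun = function(u, theta) stats::qnorm(u, mean = theta, sd = sd),
      logdens = function(y, theta) stats::dnorm(y, mean = theta, sd = sd,
                                                log = TRUE)
    ),
    class = "endpoint_family"
  )
}

#' Look up an endpoint family by name
#'
#' @param name Family name; currently `"normal"`.
#' @param ... Fixed nuisance parameters passed to the family constructor.
#' @return An `endpoint_family`.
#' @export
endpoint_family <- function(name, ...) {
  switch(name,
    normal = normal_family(...),
    stop(sprintf("unsupported distribution family '%s'", name), call. = FALSE)
  )
}

#' Generate latent patient profiles
#'
#' The complete-information device: each patient i carries one latent profile
#' per endpoint, \eqn{u^{(i)} \in (0,1)}, drawn uniformly. The profile
#' determines the patient's outcome at every combination simultaneously
#' (binary: a DLT at any combination whose toxicity probability exceeds the
#' profile; continuous: the inverse-CDF transform). Cross-endpoint dependence
#' is induced by a Gaussian copula with correlation `rho` between the
#' endpoint-level latent normals.
#'
#' @param n Number of patients, >= 1.
#' @param endpoints Number of endpoints Q, >= 1.
#' @param rho Copula correlation in \[-1, 1\] between consecutive endpoint
#'   latents (all off-diagonal entries of the latent correlation matrix for
#'   Q > 2 share this value via a one-factor construction for Q = 2; only
#'   Q <= 2 uses `rho`).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `profile_set`: list with `u` (n x Q matrix of
#'   uniforms), `n`, `rho`, `seed`.
#' @examples
#' pr <- generate_profiles(10, seed = 1)
#' range(pr$u)
#' @export
generate_profiles <- function(n, endpoints = 1, rho = 0, seed = NULL) {
  stopifnot(n >= 1, endpoints >= 1)
  if (abs(rho) > 1) stop("|rho| must be at most 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (endpoints == 1 || rho == 0) {
    u <- matrix(stats::runif(n * endpoints), nrow = n, ncol = endpoints)
  } else {
    z <- matrix(stats::rnorm(n * endpoints), nrow = n, ncol = endpoints)
    for (q in 2:endpoints) {
      z[, q] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, q]
    }
    u <- stats::pnorm(z)
  }
  structure(list(u = u, n = as.integer(n), rho = rho, seed = seed),
            class = "profile_set")
}

#' Profiles from explicit latent values
#'
#' Wraps known latent uniforms (e.g. a printed worked example) as a
#' `profile_set`.
#'
#' @param u Vector or n x Q matrix of values in (0, 1).
#' @return A `profile_set`.
#' @export
as_profiles <- function(u) {
  u <- as.matrix(u)
  stopifnot(all(u > 0), all(u < 1))
  structure(list(u = u, n = nrow(u), rho = NA_real_, seed = NULL),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d patients x %d endpoint(s)\n",
              x$n, ncol(x$u)))
  invisible(x)
}

#' Complete-information binary responses
#'
#' Patient i experiences a DLT at combination \eqn{d_{kl}} iff
#' \eqn{u^{(i)} < p_{kl}} (strict). Returns per-combination DLT counts
#' \eqn{x_{kl} = \#\{i : u^{(i)} < p_{kl}\}}.
#'
#' @param profiles A [generate_profiles()] result.
#' @param prob_matrix K x L matrix of toxicity probabilities in (0, 1).
#' @param endpoint Which profile column to use.
#' @return A `response_set` with `counts` (K x L integer matrix), `n`, and
#'   `type = "binary"`.
#' @examples
#' u <- c(0.59, 0.01, 0.29, 0.28, 0.81, 0.26, 0.72, 0.31, 0.95, 0.11)
#' p <- matrix(c(0.10, 0.30, 0.20, 0.40), 2, 2, byrow = TRUE)
#' binary_responses(as_profiles(u), p)$counts # 1, 5 / 2, 6
#' @export
binary_responses <- function(profiles, prob_matrix, endpoint = 1) {
  stopifnot(inherits(profiles, "profile_set"))
  prob_matrix <- as.matrix(prob_matrix)
  if (any(prob_matrix <= 0) || any(prob_matrix >= 1)) {
    stop("prob_matrix entries must lie in (0, 1)", call. = FALSE)
  }
  u <- profiles$u[, endpoint]
  counts <- matrix(
    vapply(as.vector(prob_matrix), function(p) sum(u < p), integer(1)),
    nrow = nrow(prob_matrix), ncol = ncol(prob_matrix)
  )
  structure(list(counts = counts, n = profiles$n, type = "binary"),
            class = "response_set")
}

#' Complete-information continuous responses
#'
#' Quantile transform of the latent profiles: patient i's response at
#' combination \eqn{d_{kl}} is \eqn{F^{-1}_{kl}(u^{(i)})} where \eqn{F_{kl}}
#' is the endpoint CDF with location `param_matrix[k, l]`.
#'
#' @param profiles A [generate_profiles()] result.
#' @param param_matrix K x L matrix of location parameters.
#' @param family An endpoint family, see [normal_family()].
#' @param endpoint Which profile column to use.
#' @return A `response_set` with `y` (n x (K*L) matrix, row-major positions),
#'   `n`, `family`, and `type = "continuous"`.
#' @export
continuous_responses <- function(profiles, param_matrix,
                                 family = normal_family(), endpoint = 1) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(family, "endpoint_family"))
  param_matrix <- as.matrix(param_matrix)
  u <- profiles$u[, endpoint]
  pars <- as.vector(t(param_matrix)) # row-major positions
  y <- vapply(pars, function(th) family$qfun(u, th), numeric(length(u)))
  structure(list(y = y, n = profiles$n, family = family,
                 type = "continuous",
                 K = nrow(param_matrix), L = ncol(param_matrix)),
            class = "response_set")
}

#' Parameter estimates under each ordering
#'
#' Reuses the same latent profiles under every candidate ordering: for a
#' binary endpoint the estimate at position (k, l) under ordering s is the
#' fraction of profiles strictly below the assigned value
#' \eqn{\hat q^{(s)}_{kl} = \#\{i: u^{(i)} < q^{(s)}_{kl}\}/n}; for a
#' continuous endpoint it is the sample mean of the quantile-transformed
#' responses under the ordering-s parameters.
#'
#' @param profiles A [generate_profiles()] result.
#' @param assignments An [ordering_assignments()] result.
#' @param family Endpoint family for continuous endpoints.
#' @param endpoint Which profile column to use.
#' @return An S x (K*L) matrix of estimates (row-major positions).
#' @export
estimate_under_ordering <- function(profiles, assignments,
                                    family = normal_family(), endpoint = 1) {
  stopifnot(inherits(profiles, "profile_set"),
            inherits(assignments, "ordering_assignment"))
  u <- profiles$u[, endpoint]
  sv <- assignments$sorted_values
  est_by_rank <- if (assignments$endpoint == "toxicity") {
    vapply(sv, function(q) mean(u < q), numeric(1))
  } else {
    vapply(sv, function(th) mean(family$qfun(u, th)), numeric(1))
  }
  matrix(est_by_rank[assignments$ranks],
         nrow = assignments$n_orderings, ncol = length(sv))
}
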