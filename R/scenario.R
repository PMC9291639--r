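#' Define a combination-trial scenario
#'
#' A scenario fixes the true combination-level parameters of a dual-agent
#' trial: a K x L matrix of toxicity probabilities (nondecreasing within each
#' agent), optionally a K x L matrix of efficacy-distribution location
#' parameters, the selection target (either a target toxicity level `gamma`
#' for maximum-tolerated-combination search, or Phase I/II admissibility
#' bounds `phi` for toxicity and `psi` for efficacy), and the set of
#' combinations deemed "correct" selections.
#'
#' @param tox K x L numeric matrix of true DLT probabilities, all in (0, 1),
#'   nondecreasing along each row and each column.
#' @param eff Optional K x L numeric matrix of efficacy location parameters
#'   (e.g. normal means of a continuous biomarker change). When lower values
#'   are better (`eff_direction = "decreasing"`, the default) the matrix must
#'   be nonincreasing along rows and columns.
#' @param gamma Target toxicity probability for MTC search, in (0, 1).
#' @param phi,psi Phase I/II upper toxicity bound and upper efficacy bound.
#' @param targets Two-column matrix (or list of length-2 vectors) of 1-based
#'   (k, l) positions of the correct combinations. If `NULL` and `gamma` is
#'   given, derived via [derive_targets()].
#' @param n Default sample size for benchmark runs using this scenario.
#' @param eff_family An endpoint family for the efficacy endpoint, see
#'   [normal_family()].
#' @param eff_direction `"decreasing"` if lower efficacy responses are better
#'   (efficacy location falls with dose), `"increasing"` otherwise.
#' @param label Optional scenario label.
#' @return An object of class `combo_scenario`.
#' @examples
#' sc <- combo_scenario(
#'   tox = matrix(c(0.10, 0.30, 0.20, 0.40), 2, 2, byrow = TRUE),
#'   gamma = 0.20
#' )
#' sc$targets
#' @export
combo_scenario <- function(tox, eff = NULL, gamma = NULL, phi = NULL,
                           psi = NULL, targets = NULL, n = NULL,
                           eff_family = normal_family(),
                           eff_direction = c("decreasing", "increasing"),
                           label = NULL) {
  eff_direction <- match.arg(eff_direction)
  tox <- as.matrix(tox)
  if (!is.numeric(tox) || any(!is.finite(tox)) ||
      any(tox <= 0) || any(tox >= 1)) {
    stop("tox must be a numeric matrix with entries strictly in (0, 1)",
         call. = FALSE)
  }
  check_monotone(tox, increasing = TRUE, what = "toxicity probabilities")
  if (!is.null(eff)) {
    eff <- as.matrix(eff)
    if (!all(dim(eff) == dim(tox))) {
      stop("eff must have the same dimensions as tox", call. = FALSE)
    }
    check_monotone(eff, increasing = (eff_direction == "increasing"),
                   what = "efficacy parameters")
  }
  if (!is.null(gamma) && (gamma <= 0 || gamma >= 1)) {
    stop("gamma must be in (0, 1)", call. = FALSE)
  }
  if (is.null(targets) && !is.null(gamma)) {
    targets <- derive_targets(tox, gamma)
  }
  if (!is.null(targets)) {
    if (is.list(targets)) targets <- do.call(rbind, targets)
    targets <- matrix(as.integer(targets), ncol = 2,
                      dimnames = list(NULL, c("k", "l")))
    if (any(targets[, 1] < 1 | targets[, 1] > nrow(tox) |
            targets[, 2] < 1 | targets[, 2] > ncol(tox))) {
      stop("targets out of grid range", call. = FALSE)
    }
  }
  structure(
    list(
      tox = unname(tox), eff = if (!is.null(eff)) unname(eff),
      gamma = gamma, phi = phi, psi = psi,
      targets = targets, n = n,
      eff_family = eff_family, eff_direction = eff_direction,
      label = label,
      grid = dose_grid(nrow(tox), ncol(tox))
    ),
    class = "combo_scenario"
  )
}

check_monotone <- function(m, increasing, what) {
  ok <- TRUE
  if (ncol(m) > 1) {
    dr <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
    ok <- ok && (if (increasing) all(dr >= 0) else all(dr <= 0))
  }
  if (nrow(m) > 1) {
    dc <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    ok <- ok && (if (increasing) all(dc >= 0) else all(dc <= 0))
  }
  if (!ok) {
    stop(sprintf("%s must be monotone within each agent", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.combo_scenario <- function(x, ...) {
  cat(sprintf("<combo_scenario>%s %d x %d grid\n",
              if (!is.null(x$label)) paste0(" ", x$label) else "",
              x$grid$K, x$grid$L))
  cat("toxicity probabilities:\n")
  print(x$tox)
  if (!is.null(x$eff)) {
    cat("efficacy parameters:\n")
    print(x$eff)
  }
  if (!is.null(x$gamma)) cat(sprintf("target toxicity gamma = %g\n", x$gamma))
  if (!is.null(x$phi)) cat(sprintf("toxicity bound phi = %g\n", x$phi))
  if (!is.null(x$psi)) cat(sprintf("efficacy bound psi = %g\n", x$psi))
  if (!is.null(x$targets)) {
    cat("target combinations:",
        paste(sprintf("(%d,%d)", x$targets[, 1], x$targets[, 2]),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Derive target combinations from a toxicity matrix
#'
#' Convenience helper: the target (correct) combinations are those whose true
#' toxicity probability is closest to the target level `gamma`, with ties
#' within `tol` all included.
#'
#' @param tox K x L matrix of toxicity probabilities.
#' @param gamma Target toxicity level.
#' @param tol Tie tolerance on the absolute distance.
#' @return A two-column integer matrix of (k, l) positions.
#' @export
derive_targets <- function(tox, gamma, tol = 1e-9) {
  d <- abs(tox - gamma)
  hit <- which(d <= min(d) + tol, arr.ind = TRUE)
  matrix(as.integer(hit[order(hit[, 1], hit[, 2]), , drop = FALSE]),
         ncol = 2, dimnames = list(NULL, c("k", "l")))
}

#' Parameter assignments under each feasible ordering
#'
#' Given the true parameter values of a scenario and the set of feasible
#' complete orderings, construct for every ordering `s` the permuted
#' assignment \eqn{q^{(s)}}: the value placed at the position of rank r is
#' the r-th smallest true value (r-th largest for a decreasing-direction
#' endpoint). The assignment of the true ordering reproduces the true
#' parameter matrix, and every assignment is monotone along the grid partial
#' order by construction.
#'
#' Also computes, per position, the number `t_kl` of distinct values feasible
#' there across the orderings, and the prior mass `h` that the value at the
#' position equals the one assigned. Under the default
#' `prior_mode = "distinct_values"` all feasible values at a position are a
#' priori equally likely, `h = 1/t_kl`; under `"per_ordering"` `h = 1/S`.
#' Both are constant across orderings at a fixed position, so they cancel in
#' the posterior normalization over orderings: the posterior then treats all
#' orderings as equally likely a priori, and duplicated value matrices
#' receive their multiplicity automatically. The alternative
#' `"ordering_frequency"` instead takes `h` to be the fraction of orderings
#' assigning that value to the position (the induced position-level value
#' prior of a uniform prior over orderings); it does not cancel, and with
#' tied parameter values it multiplies the posterior by the value
#' multiplicities a second time, concentrating it on heavily duplicated
#' assignments. When every contested position sees each of its values under
#' equally many orderings (as in the 2x2 example) all modes coincide.
#'
#' @param scenario A [combo_scenario()].
#' @param orderings An [enumerate_orderings()] result on the same grid.
#' @param endpoint `"toxicity"` or `"efficacy"`.
#' @param prior_mode `"distinct_values"` (default), `"per_ordering"`, or
#'   `"ordering_frequency"`.
#' @return An object of class `ordering_assignment` with fields `values`
#'   (S x K*L matrix, row-major positions), `t` (K x L matrix of distinct
#'   value counts), `log_prior` (S x K*L), `sorted_values`, `direction`,
#'   `true_index` (index of the ordering whose assignment equals the truth),
#'   and the `grid`.
#' @examples
#' sc <- combo_scenario(matrix(c(0.10, 0.30, 0.20, 0.40), 2, 2, byrow = TRUE),
#'                      gamma = 0.20)
#' os <- enumerate_orderings(sc$grid)
#' a <- ordering_assignments(sc, os)
#' matrix(a$values[a$true_index, ], 2, 2, byrow = TRUE)
#' @export
ordering_assignments <- function(scenario, orderings,
                                 endpoint = c("toxicity", "efficacy"),
                                 prior_mode = c("distinct_values",
                                                "per_ordering",
                                                "ordering_frequency")) {
  endpoint <- match.arg(endpoint)
  prior_mode <- match.arg(prior_mode)
  stopifnot(inherits(scenario, "combo_scenario"),
            inherits(orderings, "ordering_set"))
  if (orderings$grid$K != scenario$grid$K ||
      orderings$grid$L != scenario$grid$L) {
    stop("orderings were enumerated on a different grid", call. = FALSE)
  }
  par_mat <- if (endpoint == "toxicity") scenario$tox else scenario$eff
  if (is.null(par_mat)) {
    stop("scenario has no efficacy parameters", call. = FALSE)
  }
  direction <- if (endpoint == "toxicity") "increasing"
               else scenario$eff_direction
  true_vec <- as.vector(t(par_mat)) # row-major position order

  decreasing <- direction == "decreasing"
  sorted_values <- sort(true_vec, decreasing = decreasing)

  # values[s, pos] = sorted_values[rank of pos under ordering s]
  values <- matrix(sorted_values[orderings$ranks],
                   nrow = orderings$S, ncol = length(true_vec))

  t_vec <- apply(values, 2, function(v) length(unique(v)))
  t_mat <- matrix(as.integer(t_vec), nrow = scenario$grid$K,
                  ncol = scenario$grid$L, byrow = TRUE)

  log_prior <- switch(prior_mode,
    ordering_frequency = {
      lp <- matrix(0, orderings$S, length(true_vec))
      for (pos in seq_along(true_vec)) {
        f <- factor(values[, pos])
        lp[, pos] <- log(tabulate(f)[as.integer(f)] / orderings$S)
      }
      lp
    },
    distinct_values =
      matrix(rep(-log(t_vec), each = orderings$S), nrow = orderings$S),
    per_ordering =
      matrix(-log(orderings$S), nrow = orderings$S,
             ncol = length(true_vec))
  )

  true_index <- which(apply(values, 1, function(v) {
    isTRUE(all.equal(v, true_vec, tolerance = 0))
  }))[1]

  structure(
    list(
      values = values,
      t = t_mat,
      log_prior = log_prior,
      sorted_values = sorted_values,
      direction = direction,
      endpoint = endpoint,
      prior_mode = prior_mode,
      true_index = true_index,
      ranks = orderings$ranks,
      grid = scenario$grid,
      n_orderings = orderings$S
    ),
    class = "ordering_assignment"
  )
}

#' Distinct candidate-value counts per position
#'
#' The number of distinct parameter values a position can take across the
#' feasible orderings. Corner positions of a rectangular grid have count 1
#' when the true values are distinct.
#'
#' @param assignments An [ordering_assignments()] result.
#' @return A K x L integer matrix.
#' @export
candidate_value_counts <- function(assignments) {
  stopifnot(inherits(assignments, "ordering_assignment"))
  assignments$t
}

#' @export
print.ordering_assignment <- function(x, ...) {
  cat(sprintf(
    "<ordering_assignment> %s endpoint, %d orderings on a %d x %d grid (%s prior)\n",
    x$endpoint, x$n_orderings, x$grid$K, x$grid$L, x$prior_mode
  ))
  invisible(x)
}
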