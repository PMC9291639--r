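#' Dual-agent dose grid
#'
#' A rectangular grid of `K` dose levels of agent A by `L` dose levels of
#' agent B. Combination \eqn{d_{kl}} pairs the k-th dose of A with the l-th
#' dose of B. Toxicity is assumed nondecreasing within each agent, which
#' induces the product partial order: \eqn{d_{kl} \le d_{k'l'}} iff
#' \eqn{k \le k'} and \eqn{l \le l'}. Combinations where one index increases
#' and the other decreases are incomparable.
#'
#' Positions are indexed row-major throughout the package:
#' `pos = (k - 1) * L + l`.
#'
#' @param K Number of dose levels of agent A (rows), integer >= 1.
#' @param L Number of dose levels of agent B (columns), integer >= 1.
#' @return An object of class `dose_grid`.
#' @examples
#' dose_grid(3, 5)
#' @export
dose_grid <- function(K, L) {
  if (length(K) != 1L || length(L) != 1L || is.na(K) || is.na(L) ||
      K < 1 || L < 1 || K != round(K) || L != round(L)) {
    stop("K and L must be single integers >= 1", call. = FALSE)
  }
  structure(list(K = as.integer(K), L = as.integer(L)), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d combinations\n", x$K, x$L))
  invisible(x)
}

#' Count the feasible complete orderings of a dose grid
#'
#' The complete orderings of a K x L grid consistent with within-agent
#' monotonicity are the linear extensions of the grid partial order, which
#' are in bijection with the standard Young tableaux of rectangular shape
#' K x L. Their number is given exactly by the hook-length formula
#' \deqn{S = (KL)! / \prod_{k,l} h(k,l), \quad h(k,l) = (K-k) + (L-l) + 1,}
#' evaluated here without enumeration.
#'
#' @param grid A [dose_grid()].
#' @return The number of feasible complete orderings (numeric; exact for all
#'   counts below 2^53).
#' @examples
#' count_orderings(dose_grid(3, 3)) # 42
#' count_orderings(dose_grid(3, 5)) # 6006
#' @export
count_orderings <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  K <- grid$K
  L <- grid$L
  hooks <- outer(seq_len(K), seq_len(L), function(k, l) (K - k) + (L - l) + 1)
  # factorial(KL) / prod(hooks) computed as an interleaved product of ratios
  # to stay in exact double range for moderate grids
  num <- seq_len(K * L)
  den <- sort(as.vector(hooks))
  res <- prod(num / den)
  round(res)
}

#' Per-position incomparability counts
#'
#' For each combination \eqn{d_{kl}}, the number of combinations that cannot
#' be ordered with respect to it under the product order, i.e. positions
#' \eqn{(k', l')} with \eqn{(k'-k)(l'-l) < 0}. In closed form this equals
#' `(k-1) * (L-l) + (K-k) * (l-1)`.
#'
#' @param grid A [dose_grid()].
#' @return A K x L integer matrix.
#' @export
incomparability_counts <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  K <- grid$K
  L <- grid$L
  outer(seq_len(K), seq_len(L), function(k, l) {
    as.integer((k - 1L) * (L - l) + (K - k) * (l - 1L))
  })
}

#' Power-likelihood weights for a dose grid
#'
#' The weight attached to combination \eqn{d_{kl}} in the power likelihood is
#' \deqn{w_{kl} = (1 + \#\{\text{combinations incomparable to } d_{kl}\})^{-1},}
#' so combinations comparable to every other combination (the corners of the
#' grid) get full weight 1, and combinations with many incomparable peers --
#' which carry less information about the complete ordering -- are
#' down-weighted.
#'
#' @param grid A [dose_grid()].
#' @return A K x L numeric matrix with entries in (0, 1].
#' @examples
#' ordering_weights(dose_grid(2, 2)) # 1 and 1/2
#' @export
ordering_weights <- function(grid) {
  1 / (1 + incomparability_counts(grid))
}

#' Enumerate the feasible complete orderings of a dose grid
#'
#' Enumerates every linear extension of the K x L grid partial order by
#' backtracking over row-fill states (equivalently, generating all standard
#' Young tableaux of shape K x L): the next rank may be placed in row k
#' whenever row k is not full and row k-1 is strictly fuller, which is
#' exactly the removal of a minimal element of the remaining poset. The
#' result is sorted lexicographically by row-major rank vector so ordering
#' indices are stable across runs.
#'
#' @param grid A [dose_grid()].
#' @param max_orderings Refuse to enumerate when the exact count (from
#'   [count_orderings()]) exceeds this limit. Default `1e6`.
#' @return An object of class `ordering_set` with fields:
#'   * `grid`: the input grid;
#'   * `S`: number of orderings;
#'   * `ranks`: an `S x (K*L)` integer matrix; row `s`, column `pos` holds the
#'     rank (1 = least toxic) of the position `pos = (k-1)*L + l` under
#'     ordering `s`;
#'   * `incomparability`, `weights`: the K x L matrices of
#'     [incomparability_counts()] and [ordering_weights()].
#' @examples
#' os <- enumerate_orderings(dose_grid(2, 2))
#' os$S # 2
#' @export
enumerate_orderings <- function(grid, max_orderings = 1e6) {
  stopifnot(inherits(grid, "dose_grid"))
  S <- count_orderings(grid)
  if (S > max_orderings) {
    stop(sprintf(
      "grid has %s feasible orderings, above the limit of %s",
      format(S, big.mark = ","), format(max_orderings, big.mark = ",")
    ), call. = FALSE)
  }
  K <- grid$K
  L <- grid$L
  n_pos <- K * L

  ranks <- matrix(0L, nrow = S, ncol = n_pos)
  out_row <- 0L
  fill <- integer(K)
  cur <- integer(n_pos)

  place <- function(step) {
    if (step > n_pos) {
      out_row <<- out_row + 1L
      ranks[out_row, ] <<- cur
      return(invisible(NULL))
    }
    for (k in seq_len(K)) {
      if (fill[k] < L && (k == 1L || fill[k - 1L] > fill[k])) {
        fill[k] <<- fill[k] + 1L
        pos <- (k - 1L) * L + fill[k]
        cur[pos] <<- step
        place(step + 1L)
        fill[k] <<- fill[k] - 1L
      }
    }
    invisible(NULL)
  }
  place(1L)
  stopifnot(out_row == S)

  ord <- do.call(order, as.data.frame(ranks))
  ranks <- ranks[ord, , drop = FALSE]

  structure(
    list(
      grid = grid,
      S = S,
      ranks = ranks,
      incomparability = incomparability_counts(grid),
      weights = ordering_weights(grid)
    ),
    class = "ordering_set"
  )
}

#' @export
print.ordering_set <- function(x, ...) {
  cat(sprintf(
    "<ordering_set> %d feasible complete orderings of a %d x %d grid\n",
    x$S, x$grid$K, x$grid$L
  ))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tabulate an ordering set
#'
#' One row per (ordering, position), with the dose indices and the rank of
#' the position under that ordering.
#'
#' @param x An `ordering_set`.
#' @param ... Unused.
#' @return A tibble with columns `ordering`, `k`, `l`, `rank`.
#' @export
as_tibble.ordering_set <- function(x, ...) {
  K <- x$grid$K
  L <- x$grid$L
  pos <- seq_len(K * L)
  tibble::tibble(
    ordering = rep(seq_len(x$S), each = K * L),
    k = rep((pos - 1L) %/% L + 1L, times = x$S),
    l = rep((pos - 1L) %% L + 1L, times = x$S),
    rank = as.integer(t(x$ranks))
  )
}

# row-major position index helpers (internal)
pos_index <- function(k, l, L) (k - 1L) * L + l

pos_to_kl <- function(pos, L) {
  cbind(k = (pos - 1L) %/% L + 1L, l = (pos - 1L) %% L + 1L)
}
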