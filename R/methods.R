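# Broom-style accessors and plotting for benchmark results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.po_benchmark_result <- function(x, ...) {
  cat(sprintf("<po_benchmark_result> %s%s\n", x$mode,
              if (!is.null(x$scenario$label)) {
                paste0(" on ", x$scenario$label)
              } else ""))
  cat(sprintf("n = %d patients, Z = %d replicates, seed = %s\n",
              x$n, x$Z, format(x$seed)))
  cat("selection proportions (%):\n")
  print(round(100 * x$proportions, 1))
  if (x$no_selection > 0) {
    cat(sprintf("no admissible selection: %.1f%%\n", 100 * x$no_selection))
  }
  if (!is.na(x$pcs)) cat(sprintf("PCS = %.1f%%\n", x$pcs))
  invisible(x)
}

#' Tidy a benchmark result
#'
#' @param x A `po_benchmark_result`.
#' @param ... Unused.
#' @return A tibble with one row per combination: dose indices `k`, `l`, the
#'   true toxicity probability, the selection `proportion`, and whether the
#'   combination is in the `target` set.
#' @export
tidy.po_benchmark_result <- function(x, ...) {
  K <- nrow(x$proportions)
  L <- ncol(x$proportions)
  tb <- tibble::tibble(
    k = rep(seq_len(K), each = L),
    l = rep(seq_len(L), times = K),
    tox_prob = as.vector(t(x$scenario$tox)),
    proportion = as.vector(t(x$proportions)),
    target = FALSE
  )
  if (!is.null(x$targets)) {
    tb$target <- paste(tb$k, tb$l) %in%
      paste(x$targets[, 1], x$targets[, 2])
  }
  tb
}

#' One-row summary of a benchmark result
#'
#' @param x A `po_benchmark_result`.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `pcs`, `no_selection`, `n`, `Z`,
#'   `seed`, `n_orderings`.
#' @export
glance.po_benchmark_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    pcs = x$pcs,
    no_selection = x$no_selection,
    n = x$n,
    Z = x$Z,
    seed = x$seed,
    n_orderings = x$settings$S %||% 1L
  )
}

#' Heat-map of selection proportions
#'
#' @param object A `po_benchmark_result`.
#' @param ... Unused.
#' @return A ggplot: agent-B dose on the x axis, agent-A dose on the y axis,
#'   tile fill and label giving each combination's selection percentage;
#'   target combinations outlined.
#' @export
autoplot.po_benchmark_result <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$l, y = .data$k,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_tile(data = tb[tb$target, , drop = FALSE],
                       fill = NA, color = "black", linewidth = 1.1) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$proportion)
    ), size = 3) +
    ggplot2::scale_y_reverse(breaks = seq_len(max(tb$k))) +
    ggplot2::scale_x_continuous(breaks = seq_len(max(tb$l)),
                                position = "top") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 labels = function(v) sprintf("%.0f%%",
                                                              100 * v)) +
    ggplot2::labs(x = "dose of agent B", y = "dose of agent A",
                  fill = "selection",
                  title = sprintf("Selection proportions (%s)",
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
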