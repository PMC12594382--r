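#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the error history of a fitted imputer
#'
#' One row per (iteration, variable) with out-of-bag and apparent NMSE,
#' MSE (Brier score for categorical variables), misclassification error
#' rate and F1, plus the weighted global NMSE of the iteration.
#'
#' @param x A `forest_imputer`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy forest_imputer
#' @export
tidy.forest_imputer <- function(x, ...) {
  dplyr::relocate(x$error_history, "iteration", "variable")
}

#' One-row summary of a fitted imputer
#'
#' @param x A `forest_imputer`.
#' @param ... Unused.
#' @return A tibble with variable count, iterations ran/selected,
#'   convergence flag and the final accepted global OOB NMSE.
#' @method glance forest_imputer
#' @export
glance.forest_imputer <- function(x, ...) {
  accepted <- x$error_history[x$error_history$iteration == x$n_iterations, ]
  tibble::tibble(
    n_variables = length(x$sequence),
    n_iterations = x$n_iterations,
    n_iterations_ran = x$n_iterations_ran,
    converged = x$converged,
    global_nmse_oob = if (x$n_iterations >= 1)
      accepted$global_nmse_oob[1] else 1
  )
}

#' Plot the convergence of a fitted imputer
#'
#' Per-variable out-of-bag NMSE across iterations, with the weighted
#' global NMSE overlaid; the dashed line at 1 is the reference
#' (initialization) error. Iterations beyond the selected count were
#' rejected by the convergence rule.
#'
#' @param object A `forest_imputer`.
#' @param metric Column of the error history to plot (default
#'   `"nmse_oob"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot forest_imputer
#' @export
autoplot.forest_imputer <- function(object, metric = "nmse_oob", ...) {
  h <- tidy(object)
  global_col <- if (metric == "nmse_apparent") "global_nmse_apparent" else "global_nmse_oob"
  g <- dplyr::distinct(h, .data$iteration, global = .data[[global_col]])
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data[[metric]],
                                  colour = .data$variable)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = g,
                       mapping = ggplot2::aes(x = .data$iteration, y = .data$global),
                       colour = "black", linewidth = 1, inherit.aes = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$n_iterations + 0.5, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = unique(h$iteration)) +
    ggplot2::labs(x = "iteration", y = metric,
                  title = "Imputation error by iteration") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot benchmark results
#'
#' Boxplots of the prediction metric (BSS or R-squared) per imputer and
#' prediction model across replicates.
#'
#' @param results Output of [run_scenario()].
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results) {
  metric <- if ("bss" %in% names(results)) "bss" else "r_squared"
  ok <- results[!is.na(results$imputer), ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$imputer, y = .data[[metric]],
                                   fill = .data$model)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}
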