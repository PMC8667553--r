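#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model into one row per coefficient
#'
#' @param x A `pathcox_fit`.
#' @param ... Unused.
#' @return Tibble with columns `pathway` (`NA` for gene-level lasso),
#'   `gene`, `coefficient` and `selected`.
#' @method tidy pathcox_fit
#' @export
tidy.pathcox_fit <- function(x, ...) {
  dplyr::mutate(x$origin, coefficient = x$beta,
                selected = x$beta != 0)
}

#' One-row summary of a fitted model
#'
#' @param x A `pathcox_fit`.
#' @param ... Unused.
#' @return Tibble with the penalty strengths, final loss, iteration count,
#'   convergence flag and sparsity summary.
#' @method glance pathcox_fit
#' @export
glance.pathcox_fit <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    lambda = x$penalty$lambda,
    mu = x$penalty$mu,
    final_loss = x$loss_trace[length(x$loss_trace)],
    n_iterations = x$n_iterations,
    converged = x$converged,
    n_nonzero = sum(x$beta != 0),
    n_selected_groups = if (x$mode == "group")
      length(x$selected_groups) else NA_integer_
  )
}

#' Per-split rows of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-split tibble (`split`, `c_value`, `n_selected_groups`).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$splits

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with the method, number of splits, mean/sd c-value and
#'   mean congruence.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_splits = nrow(x$splits),
    mean_c_value = mean(x$splits$c_value),
    sd_c_value = stats::sd(x$splits$c_value),
    congruence_mean = x$congruence_mean
  )
}

#' Plot the distribution of test c-values across splits
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- dplyr::mutate(object$splits, method = object$method)
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$method, y = .data$c_value)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA,
                          fill = "grey90") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = object$method, y = "test c-value",
                  title = "Concordance across random train-test splits") +
    ggplot2::theme_minimal()
}

#' Plot per-pathway coefficient blocks of a fitted model
#'
#' Box plot of the coefficients within each selected pathway group, the
#' usual way to inspect which pathways a group lasso fit retained.
#'
#' @param object A `pathcox_fit` in group mode.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathcox_fit
#' @export
autoplot.pathcox_fit <- function(object, ...) {
  td <- tidy(object)
  td <- dplyr::filter(td, .data$pathway %in% object$selected_groups)
  if (nrow(td) == 0) td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$pathway,
                                   y = .data$coefficient)) +
    ggplot2::geom_boxplot(fill = "grey90", outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "pathway group", y = "coefficient",
                  title = "Per-pathway coefficient blocks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a cross-validation curve over the lambda grid
#' @param object A `lambda_search` from [grid_search_lambda()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lambda_search
#' @export
autoplot.lambda_search <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$lambda,
                                          y = .data$mean_c_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lambda (log scale)", y = "mean CV c-value",
                  title = "Cross-validated grid search") +
    ggplot2::theme_minimal()
}

utils::globalVariables(".data")
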