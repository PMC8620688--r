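#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA model
#'
#' @param x A `pca_model`.
#' @param matrix `"scores"`, `"loadings"` or `"variance"`.
#' @param ... Unused.
#' @return A long tibble of the requested matrix.
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "variance"),
                           ...) {
  matrix <- match.arg(matrix)
  if (matrix == "variance") {
    return(tibble::tibble(component = seq_along(x$explained_variance),
                          fraction = x$explained_variance))
  }
  m <- x[[matrix]]
  id_col <- if (matrix == "scores") "sample" else "element"
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(!!id_col := ids, .before = 1) |>
    tidyr::pivot_longer(-dplyr::all_of(id_col),
                        names_to = "component", values_to = "value")
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_variables = x$n_variables,
                 n_components = x$n_components,
                 explained_fraction =
                   sum(x$explained_variance[seq_len(x$n_components)]))
}

#' Tidy a PLS-DA model
#'
#' @param x A `plsda_model`.
#' @param matrix `"vip"`, `"coefficients"`, `"weights"`, `"scores"` or
#'   `"loadings"` (X-loadings).
#' @param ... Unused.
#' @export
tidy.plsda_model <- function(x, matrix = c("vip", "coefficients", "weights",
                                           "scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "vip") return(vip_scores(x))
  m <- switch(matrix,
              coefficients = x$coefficients,
              weights = x$weights,
              scores = x$scores,
              loadings = x$x_loadings)
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("LV%d", seq_len(ncol(m)))
  id_col <- if (matrix == "scores") "sample" else "element"
  tibble::as_tibble(as.data.frame(m)) |>
    dplyr::mutate(!!id_col := ids, .before = 1) |>
    tidyr::pivot_longer(-dplyr::all_of(id_col),
                        names_to = "term", values_to = "value")
}

#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(n_samples = length(x$train_ids),
                 n_variables = length(x$elements),
                 n_components = x$n_components,
                 explained_x = sum(x$explained_x),
                 explained_y = sum(x$explained_y),
                 rule = if (is.null(x$rule)) NA_character_ else x$rule)
}

#' @export
tidy.classification_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion)) |>
    stats::setNames(c("true", "predicted", "n"))
}

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(total_accuracy = x$total_accuracy, n = x$n,
                 n_misclassified = length(x$misclassified_ids))
}

#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    n_samples = sum(x$data_summary$n),
    n_train = if (is.null(x$split)) sum(x$data_summary$n) else
      length(x$split$train_ids),
    n_test = if (is.null(x$split)) 0L else length(x$split$test_ids),
    a_selected = x$a_selected,
    explained_x = x$explained_x,
    explained_y = x$explained_y,
    cv_accuracy = x$cv_report$total_accuracy,
    test_accuracy = if (is.null(x$test_report)) NA_real_ else
      x$test_report$total_accuracy,
    n_selected = length(x$selected_elements))
}

#' Score plot of a PCA model
#'
#' @param object A `pca_model`.
#' @param components Two components to display.
#' @param labels Optional class labels for colouring, in score-row order.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_model <- function(object, components = c(1, 2), labels = NULL,
                               ...) {
  sc <- object$scores[, components, drop = FALSE]
  ev <- 100 * object$explained_variance[components]
  df <- tibble::tibble(x = sc[, 1], y = sc[, 2],
                       class = if (is.null(labels)) "sample" else
                         as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1], ev[1]),
      y = sprintf("PC%d (%.1f%%)", components[2], ev[2])) +
    ggplot2::theme_minimal()
}

#' Latent-variable score plot of a PLS-DA model
#' @param object A `plsda_model`.
#' @param components Two latent variables to display.
#' @param ... Unused.
#' @export
autoplot.plsda_model <- function(object, components = c(1, 2), ...) {
  a <- pmin(components, object$n_components)
  sc <- object$scores[, a, drop = FALSE]
  df <- tibble::tibble(x = sc[, 1], y = sc[, ncol(sc)],
                       class = object$train_labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("LV%d", a[1]), y = sprintf("LV%d", a[length(a)])) +
    ggplot2::theme_minimal()
}

#' Cross-validation error curve of a run
#' @param report A `run_report`.
#' @return A ggplot object.
#' @export
plot_error_curve <- function(report) {
  ggplot2::ggplot(report$error_curve,
                  ggplot2::aes(.data$n_components, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = report$a_selected, linetype = 2) +
    ggplot2::labs(x = "Latent variables",
                  y = "CV misclassification rate") +
    ggplot2::theme_minimal()
}

#' VIP bar chart with the greater-than-one line
#' @param vip A VIP tibble from [vip_scores()] or a `run_report`.
#' @return A ggplot object.
#' @export
plot_vip <- function(vip) {
  if (inherits(vip, "run_report")) vip <- vip$vip
  ggplot2::ggplot(vip, ggplot2::aes(stats::reorder(.data$element, -.data$vip),
                                    .data$vip, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "VIP score") +
    ggplot2::theme_minimal()
}
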