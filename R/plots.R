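#' Heatmap of class-conditional item failure frequencies
#'
#' @param cohort A cohort tibble.
#' @return A ggplot: items x diagnosis classes, fill = conditional
#'   failure frequency.
#' @export
plot_conditional_failures <- function(cohort) {
  conditional_failure_table(cohort) |>
    ggplot2::ggplot(ggplot2::aes(.data$diagnosis, .data$item,
      fill = .data$failure_prop
    )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(
      low = "white", high = "firebrick",
      limits = c(0, 1), name = "P(failure)"
    ) +
    ggplot2::labs(x = "Diagnosis", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Scree-style plot of permutation variable importance
#'
#' @param object A `dcd_perm_test` from [permutation_importance_test()].
#' @param ... Unused.
#' @return A ggplot of items ranked by importance, significant items
#'   filled.
#' @export
autoplot.dcd_perm_test <- function(object, ...) {
  object$pvalues |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(item = factor(.data$item, levels = rev(.data$item))) |>
    ggplot2::ggplot(ggplot2::aes(.data$importance, .data$item)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$item),
      colour = "grey70"
    ) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
      shape = 21, size = 2
    ) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "black", `FALSE` = "white"),
      name = sprintf("p <= %.2g", object$alpha)
    ) +
    ggplot2::labs(x = "Mean decrease in accuracy", y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
}

#' Subjects in a component-score space, coloured by cluster
#'
#' @param object A `dcd_clusters` solution.
#' @param labels Optional diagnosis labels to shape the points by.
#' @param ... Unused.
#' @return A ggplot of the first two score dimensions with medoids
#'   crossed.
#' @export
autoplot.dcd_clusters <- function(object, labels = NULL, ...) {
  df <- tibble::tibble(
    dim1 = object$points[, 1],
    dim2 = if (ncol(object$points) > 1) object$points[, 2] else 0,
    cluster = factor(object$assignments)
  )
  if (!is.null(labels)) df$diagnosis <- labels
  med <- df[object$medoid_indices, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
    colour = .data$cluster
  ))
  p <- if (is.null(labels)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(shape = .data$diagnosis), size = 2)
  }
  p +
    ggplot2::geom_point(
      data = med, shape = 4, size = 4, stroke = 1.5,
      show.legend = FALSE
    ) +
    ggplot2::labs(x = "Component 1", y = "Component 2") +
    ggplot2::theme_minimal(base_size = 10)
}
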