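#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors. `tidy()` returns one row per estimated
#' quantity (forest: per-item importance; PLS: per item x class
#' classification coefficient; clusters: per-subject assignment and
#' silhouette; tuning: the per-setting accuracy table). `glance()`
#' returns a one-row model summary.
#'
#' @param x A fitted `dcd_forest`, `dcd_pls`, `dcd_clusters` or
#'   `dcd_tuning` object.
#' @param seed Seed for the permutation pass behind forest importances.
#' @param ... Unused.
#' @return A tibble.
#' @name dcd-tidiers
NULL

#' @rdname dcd-tidiers
#' @export
tidy.dcd_forest <- function(x, seed = 1L, ...) {
  imp <- permutation_importance(x, seed = seed)
  per_class <- tibble::as_tibble(as.data.frame(t(imp$per_class)))
  dplyr::bind_cols(imp$overall, per_class)
}

#' @rdname dcd-tidiers
#' @export
glance.dcd_forest <- function(x, ...) {
  oob <- oob_error(x)
  tibble::tibble(
    ntree = x$ntree, mtry = x$mtry,
    n = nrow(x$X), p = length(x$items),
    oob_error = oob$overall, n_oob_skipped = oob$n_skipped
  )
}

#' @rdname dcd-tidiers
#' @export
tidy.dcd_pls <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$coefficients)) |>
    dplyr::mutate(item = x$items, .before = 1) |>
    tidyr::pivot_longer(-"item", names_to = "class", values_to = "coefficient") |>
    dplyr::mutate(selected = .data$item %in% x$selected_items)
}

#' @rdname dcd-tidiers
#' @export
glance.dcd_pls <- function(x, ...) {
  tibble::tibble(
    K = x$K, K_actual = x$K_actual, eta = x$eta,
    n = nrow(x$X), p = length(x$items),
    n_selected = length(x$selected_items),
    converged = all(x$converged),
    training_accuracy = mean(predict(x) == x$y)
  )
}

#' @rdname dcd-tidiers
#' @export
tidy.dcd_clusters <- function(x, ...) {
  tibble::tibble(
    subject = seq_along(x$assignments),
    cluster = x$assignments,
    silhouette = x$silhouettes,
    is_medoid = seq_along(x$assignments) %in% x$medoid_indices
  )
}

#' @rdname dcd-tidiers
#' @export
glance.dcd_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = length(x$assignments), asw = x$asw,
    min_cluster_size = min(tabulate(x$assignments, x$k))
  )
}

#' @rdname dcd-tidiers
#' @export
tidy.dcd_tuning <- function(x, ...) x$results

#' @rdname dcd-tidiers
#' @export
glance.dcd_tuning <- function(x, ...) {
  dplyr::bind_cols(
    x$best,
    tibble::tibble(
      n_settings = nrow(x$results),
      n_evaluations = ncol(x$accuracies)
    )
  )
}
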