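#' Dummy-code diagnosis labels into a class indicator matrix
#'
#' @param labels Factor (or character) vector of diagnosis labels.
#' @return A subjects x classes 0/1 matrix `Z` with `Z[i, c] = 1` iff
#'   subject i belongs to class c; each row sums to 1.
#' @export
dummy_code <- function(labels) {
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(y) < 2) abort("Need at least 2 classes.")
  Z <- matrix(0L, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  Z[cbind(seq_along(y), as.integer(y))] <- 1L
  Z
}

#' Soft-threshold a weight vector
#'
#' The sparsity rule applied within each NIPALS iteration: with
#' `t = eta * max|w|`, every entry is shrunk towards zero by `t`
#' (`sign(w) * max(0, |w| - t)`) and the result renormalised to unit
#' norm if nonzero. `eta = 0` leaves the (normalised) vector unchanged;
#' as `eta` grows the support shrinks monotonically, down to the single
#' largest-magnitude entry.
#'
#' @param w Numeric vector.
#' @param eta Thresholding fraction in `[0, 1)`.
#' @return A vector of the same length (unit norm unless all-zero).
#' @export
soft_threshold_weights <- function(w, eta) {
  if (eta < 0 || eta >= 1) abort("`eta` must lie in [0, 1).")
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(w)
  thr <- eta * max(abs(w))
  out <- sign(w) * pmax(0, abs(w) - thr)
  n2 <- sqrt(sum(out^2))
  if (n2 > 0) out / n2 else out
}

# Core NIPALS PLS2 fit on a centered X block against a centered class
# indicator block; eta > 0 applies soft thresholding to each weight
# vector inside the iteration loop (sparse variant).
fit_pls_core <- function(X, Z, K, eta = 0, tol = 1e-12, max_iter = 500) {
  n <- nrow(X)
  p <- ncol(X)
  C <- ncol(Z)
  x_mean <- colMeans(X)
  z_mean <- colMeans(Z)
  E <- sweep(X, 2, x_mean)
  F0 <- sweep(Z, 2, z_mean)

  W <- matrix(0, p, K)
  P <- matrix(0, p, K)
  Q <- matrix(0, C, K)
  Ti <- matrix(0, n, K)
  converged <- logical(K)
  k_actual <- 0L
  for (k in seq_len(K)) {
    if (sum(E^2) < 1e-12) break # X exhausted: return fewer components
    u_y <- F0[, which.max(colSums(F0^2))]
    w_old <- rep(Inf, p)
    w <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u_y))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      if (eta > 0) w <- soft_threshold_weights(w, eta)
      t_sc <- drop(E %*% w)
      q <- drop(crossprod(F0, t_sc)) / sum(t_sc^2)
      u_y <- drop(F0 %*% q) / sum(q^2)
      if (sqrt(sum((w - w_old)^2)) < tol) {
        converged[k] <- TRUE
        break
      }
      w_old <- w
    }
    if (is.null(w) || sum(w^2) == 0) break
    t_sc <- drop(E %*% w)
    p_load <- drop(crossprod(E, t_sc)) / sum(t_sc^2)
    E <- E - tcrossprod(t_sc, p_load)
    W[, k] <- w
    P[, k] <- p_load
    Q[, k] <- drop(crossprod(F0, t_sc)) / sum(t_sc^2)
    Ti[, k] <- t_sc
    k_actual <- k
  }
  if (k_actual == 0L) abort("No PLS component could be extracted (constant X?).")
  keep <- seq_len(k_actual)
  W <- W[, keep, drop = FALSE]
  P <- P[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]
  Ti <- Ti[, keep, drop = FALSE]
  W_star <- W %*% solve(crossprod(P, W))
  B <- W_star %*% t(Q) # p x C map from centered X to centered Z
  b0 <- z_mean - drop(x_mean %*% B)
  list(
    W = W, P = P, Q = Q, scores = Ti, W_star = W_star,
    coefficients = B, intercepts = b0, x_mean = x_mean,
    K_actual = k_actual, converged = converged[keep]
  )
}

#' Fit (sparse) PLS discriminant analysis
#'
#' Multiclass PLS-DA by NIPALS: the diagnosis labels are dummy-coded
#' into an indicator matrix `Z`; for each component `k` a unit-norm
#' weight vector maximising the covariance between the deflated item
#' block and the centered `Z` is found by iterating to convergence
#' (tolerance 1e-12, at most 500 iterations), the component score is the
#' weighted item combination, and the item block is deflated by
#' regression on the score. Classification functions map raw
#' (uncentered) item values to per-class scores; intercepts absorb the
#' centering. `fit_splsda()` additionally soft-thresholds each weight
#' vector inside the iteration loop ([soft_threshold_weights()]),
#' zeroing small loadings; `selected_items` collects items with any
#' nonzero weight. Items are centered but not variance-scaled by default
#' (all items share the same 0/1 scale; scaling would inflate rare
#' items), switchable via `scale`.
#'
#' @param cohort A cohort tibble.
#' @param K Number of components, `K <= min(n - 1, p)`.
#' @param eta Sparsity fraction in `[0, 1)`; 0 is the unpenalised fit.
#' @param scale If `TRUE`, items are also scaled to unit variance.
#' @return A `dcd_pls` object.
#' @examples
#' cohort <- generate_cohort(dcd_spec_paperlike(63, seed = 7))
#' fit <- fit_splsda(cohort, K = 2, eta = 0.7)
#' fit$selected_items
#' @export
fit_plsda <- function(cohort, K, scale = FALSE) {
  fit_splsda(cohort, K, eta = 0, scale = scale)
}

#' @rdname fit_plsda
#' @export
fit_splsda <- function(cohort, K, eta = 0, scale = FALSE) {
  X <- cohort_matrix(cohort)
  y <- cohort_labels(cohort)
  if (K < 1 || K > min(nrow(X) - 1, ncol(X))) {
    abort("`K` must lie in [1, min(n - 1, p)].")
  }
  if (eta < 0 || eta >= 1) abort("`eta` must lie in [0, 1).")
  Xd <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
  x_scale <- rep(1, ncol(Xd))
  if (scale) {
    x_scale <- apply(Xd, 2, sd)
    x_scale[x_scale == 0] <- 1
    Xd <- sweep(Xd, 2, x_scale, "/")
  }
  Z <- dummy_code(y)
  core <- fit_pls_core(Xd, Z, K, eta = eta)
  rownames(core$W) <- rownames(core$P) <- rownames(core$coefficients) <- colnames(X)
  rownames(core$Q) <- colnames(core$coefficients) <- names(core$intercepts) <- colnames(Z)
  sel <- colnames(X)[rowSums(abs(core$W)) > 0]
  structure(
    c(core, list(
      K = as.integer(K), eta = eta, scale = scale, x_scale = x_scale,
      classes = colnames(Z), items = colnames(X),
      selected_items = sel, X = X, y = y
    )),
    class = "dcd_pls"
  )
}

#' @export
print.dcd_pls <- function(x, ...) {
  cat("<dcd_pls> K = ", x$K_actual, if (x$K_actual < x$K) " (truncated)",
    ", eta = ", x$eta, ", ", length(x$selected_items), "/", length(x$items),
    " items selected\n",
    sep = ""
  )
  invisible(x)
}

pls_new_X <- function(model, new_data) {
  X <- if (is.matrix(new_data)) new_data else cohort_matrix(new_data)
  if (ncol(X) != length(model$items)) {
    abort("`new_data` must carry the same items as the training cohort.")
  }
  sweep(matrix(as.numeric(X), nrow(X), ncol(X)), 2, model$x_scale, "/")
}

#' Component scores for new subjects
#'
#' Projects (new) subjects into the fitted latent space: items are
#' centered with the training means and multiplied by the accumulated
#' weight matrix.
#'
#' @param model A `dcd_pls` model.
#' @param new_data Cohort tibble or item matrix; defaults to the
#'   training cohort (returning the fitted scores).
#' @return A subjects x components score matrix.
#' @export
pls_scores <- function(model, new_data = NULL) {
  if (is.null(new_data)) {
    out <- model$scores
    rownames(out) <- rownames(model$X)
    return(out)
  }
  Xc <- sweep(pls_new_X(model, new_data), 2, model$x_mean)
  Xc %*% model$W_star
}

#' Softmax class prediction from a fitted PLS-DA model
#'
#' Raw per-class scores from the classification functions are mapped
#' onto the unit simplex by the exponential softmax and the predicted
#' class is the argmax, ties broken by the fixed class order. (The
#' argmax is invariant to adding a constant to all raw scores; a linear
#' rescaling variant is available via `transform = "linear"` and yields
#' the same argmax whenever raw scores are distinct.)
#'
#' @param model A `dcd_pls` model.
#' @param new_data Cohort tibble or item matrix; defaults to training.
#' @param transform `"softmax"` (default) or `"linear"` min-max
#'   rescaling to the simplex.
#' @return A list with `class` (factor) and `probabilities` (tibble on
#'   the unit simplex).
#' @export
predict_softmax <- function(model, new_data = NULL, transform = c("softmax", "linear")) {
  transform <- match.arg(transform)
  X <- if (is.null(new_data)) {
    sweep(matrix(as.numeric(model$X), nrow(model$X), ncol(model$X)), 2,
      model$x_scale, "/"
    )
  } else {
    pls_new_X(model, new_data)
  }
  raw <- sweep(X %*% model$coefficients, 2, model$intercepts, "+")
  if (transform == "softmax") {
    ex <- exp(sweep(raw, 1, apply(raw, 1, max))) # shift-invariant, overflow-safe
    prob <- ex / rowSums(ex)
  } else {
    lo <- apply(raw, 1, min)
    rng <- apply(raw, 1, max) - lo
    prob <- sweep(sweep(raw, 1, lo), 1, ifelse(rng == 0, 1, rng), "/")
    prob[rng == 0, ] <- 1 # all-equal raw scores: uniform simplex weights
    prob <- prob / rowSums(prob)
  }
  colnames(prob) <- model$classes
  list(
    class = factor(model$classes[apply(prob, 1, which_max_first)],
      levels = model$classes
    ),
    probabilities = tibble::as_tibble(as.data.frame(prob))
  )
}

#' @export
predict.dcd_pls <- function(object, new_data = NULL, ...) {
  predict_softmax(object, new_data)$class
}

#' Loading-based variable importance for (s)PLS-DA
#'
#' Overall importance per component is the absolute weight `|u_k|` of
#' each item; class-specific importance is the absolute classification
#' coefficient `|b_{i,c}|` rescaled within each class so the maximum is
#' 1. Items with zero weight on every component (sparse fits) have
#' exactly zero entries.
#'
#' @param model A `dcd_pls` model.
#' @return A list with `per_component` (tibble: item, component,
#'   loading) and `per_class` (tibble: item, class, importance).
#' @export
loadings_importance <- function(model) {
  W <- abs(model$W)
  per_component <- tibble::as_tibble(as.data.frame(W)) |>
    rlang::set_names(paste0("C", seq_len(ncol(W)))) |>
    dplyr::mutate(item = model$items, .before = 1) |>
    tidyr::pivot_longer(-"item", names_to = "component", values_to = "loading")
  Bc <- abs(model$coefficients)
  mx <- apply(Bc, 2, max)
  Bc <- sweep(Bc, 2, ifelse(mx == 0, 1, mx), "/")
  per_class <- tibble::as_tibble(as.data.frame(Bc)) |>
    dplyr::mutate(item = model$items, .before = 1) |>
    tidyr::pivot_longer(-"item", names_to = "class", values_to = "importance")
  list(per_component = per_component, per_class = per_class)
}

#' Bootstrap confidence intervals for sPLS-DA coefficients
#'
#' Refits the model on `B` stratified (per-class) bootstrap resamples and
#' reports percentile 2.5%/97.5% bounds for every (item, class)
#' classification coefficient. Refits in which any retained component
#' failed to converge are skipped and counted; more than 10% skips
#' triggers a warning recorded in the report.
#'
#' @param cohort A cohort tibble.
#' @param K,eta Model hyperparameters as in [fit_splsda()].
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return A `dcd_boot_ci` object: tibble with item, class, estimate,
#'   lower, upper; attributes `B`, `n_skipped`, `warning`.
#' @export
bootstrap_coefficient_ci <- function(cohort, K, eta, B = 1000, seed = 1L,
                                     conf_level = 0.95) {
  if (B < 100) abort("`B` must be at least 100.")
  fit0 <- fit_splsda(cohort, K, eta)
  y <- cohort_labels(cohort)
  idx_by_class <- split(seq_along(y), y)
  alpha <- (1 - conf_level) / 2

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- array(NA_real_, c(length(fit0$items), length(fit0$classes), B))
  n_skipped <- 0L
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_class, function(ii) {
      sample(ii, length(ii), replace = TRUE)
    }), use.names = FALSE)
    fit_b <- tryCatch(fit_splsda(cohort[take, , drop = FALSE], K, eta),
      error = function(e) NULL
    )
    if (is.null(fit_b) || !all(fit_b$converged) || fit_b$K_actual < K) {
      n_skipped <- n_skipped + 1L
      next
    }
    draws[, , b] <- fit_b$coefficients
  }
  warn_flag <- n_skipped > 0.1 * B
  if (warn_flag) {
    warn(sprintf("%d of %d bootstrap refits skipped (non-convergence).", n_skipped, B))
  }
  out <- tidyr::expand_grid(
    item = fit0$items,
    class = fit0$classes
  ) |>
    dplyr::mutate(
      estimate = as.numeric(fit0$coefficients[cbind(.data$item, .data$class)]),
      lower = purrr::map2_dbl(.data$item, .data$class, function(it, cl) {
        v <- draws[match(it, fit0$items), match(cl, fit0$classes), ]
        quantile(v, alpha, na.rm = TRUE, names = FALSE)
      }),
      upper = purrr::map2_dbl(.data$item, .data$class, function(it, cl) {
        v <- draws[match(it, fit0$items), match(cl, fit0$classes), ]
        quantile(v, 1 - alpha, na.rm = TRUE, names = FALSE)
      })
    )
  structure(out,
    class = c("dcd_boot_ci", class(out)),
    B = B, n_skipped = n_skipped, warning = warn_flag
  )
}
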