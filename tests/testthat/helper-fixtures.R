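# Shared fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

cohort_labels_of <- function(cohort) cohort$diagnosis

# item block of a cohort tibble as an integer matrix
cohort_matrix_of <- function(cohort) {
  X <- as.matrix(cohort[setdiff(names(cohort), c("subject_id", "diagnosis"))])
  storage.mode(X) <- "integer"
  X
}

# A null spec: identical failure probabilities in every class, independent
# items — no class structure at all.
null_spec <- function(n, p = 12, seed = 1L, prob = 0.4) {
  dcd_spec(
    n_subjects = n,
    class_names = dcd_class_levels(),
    class_priors = c(0.34, 0.33, 0.33),
    item_codes = sprintf("I%02d", seq_len(p)),
    failure_probs = matrix(prob, 3, p),
    latent_correlation = 0,
    seed = seed
  )
}

# Hand-sized cohort tibble from an explicit matrix + labels.
make_cohort <- function(X, labels, items = NULL) {
  items <- items %||% sprintf("I%02d", seq_len(ncol(X)))
  colnames(X) <- items
  tibble::as_tibble(as.data.frame(X)) |>
    dplyr::mutate(
      subject_id = sprintf("S%03d", seq_len(nrow(X))),
      diagnosis = factor(labels, levels = intersect(dcd_class_levels(), labels)),
      .before = 1
    )
}

# Three tight, well-separated Gaussian blobs in the plane.
blob_points <- function(sizes = c(20, 20, 15), sd = 0.5, seed = 9) {
  centers <- rbind(c(0, 0), c(8, 0), c(4, 7))
  set.seed(seed)
  do.call(rbind, lapply(seq_along(sizes), function(i) {
    cbind(
      rnorm(sizes[i], centers[i, 1], sd),
      rnorm(sizes[i], centers[i, 2], sd)
    )
  }))
}

# Per-item RF permutation importance as an importance_fn callback.
rf_importance_fn <- function(ntree = 100, seed = 1L) {
  function(cohort) {
    fit <- fit_forest(cohort, ntree = ntree, seed = seed)
    v <- permutation_importance(fit, seed = seed)$overall
    rlang::set_names(v$importance, v$item)
  }
}

# Exhaustive Gini search over all items on given rows (oracle for the
# tree-growing split rule).
brute_force_best_gini <- function(X, y, rows) {
  gini <- function(yy) {
    if (!length(yy)) return(0)
    1 - sum((table(yy) / length(yy))^2)
  }
  best <- Inf
  for (v in seq_len(ncol(X))) {
    left <- rows[X[rows, v] == 0]
    right <- rows[X[rows, v] == 1]
    if (!length(left) || !length(right)) next
    w <- (length(left) * gini(y[left]) + length(right) * gini(y[right])) /
      length(rows)
    if (w < best) best <- w
  }
  best
}

# Exhaustive k-medoid search (oracle for PAM on tiny point sets).
brute_force_pam_cost <- function(points, k) {
  D <- as.matrix(dist(points))
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

pam_cost <- function(solution) {
  D <- as.matrix(dist(solution$points))
  sum(D[cbind(
    seq_along(solution$assignments),
    solution$medoid_indices[solution$assignments]
  )])
}
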