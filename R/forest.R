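#' Default number of candidate items per split
#'
#' The usual random-forest heuristic for classification,
#' `floor(sqrt(p))`: 7 for the 49-item battery.
#'
#' @param p Number of predictors.
#' @return An integer.
#' @export
default_mtry <- function(p) {
  stopifnot(p >= 1)
  as.integer(floor(sqrt(p)))
}

#' Fit a random forest of unpruned binary-split trees
#'
#' Each tree is grown on an n-sized bootstrap sample of the cohort; at
#' every node `mtry` items are sampled without replacement and the split
#' minimising the weighted Gini impurity of the two children is taken.
#' Binary items admit exactly one split (0 vs 1). Growth stops only at
#' purity, when no sampled split strictly reduces impurity, or when a
#' child would be empty — trees are never pruned.
#'
#' @param cohort A cohort tibble (`subject_id`, `diagnosis`, item
#'   columns); see [generate_cohort()].
#' @param mtry Candidate items per split; defaults to
#'   [default_mtry()] of the item count.
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return A `dcd_forest` object carrying the trees, per-tree bootstrap
#'   index multisets, and the training data.
#' @examples
#' cohort <- generate_cohort(dcd_spec_paperlike(63, seed = 7))
#' fit <- fit_forest(cohort, ntree = 100, seed = 7)
#' glance(fit)
#' @export
fit_forest <- function(cohort, mtry = NULL, ntree = 500, seed = 1L) {
  X <- cohort_matrix(cohort)
  assert_binary_matrix(X, "cohort")
  y <- cohort_labels(cohort)
  if (nrow(X) < 2) abort("Need at least 2 subjects.")
  if (nlevels(y) < 2) abort("Need at least 2 diagnosis classes.")
  if (ntree < 1) abort("`ntree` must be at least 1.")
  mtry <- mtry %||% default_mtry(ncol(X))
  if (mtry < 1 || mtry > ncol(X)) abort("`mtry` must lie in [1, p].")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  grown <- grow_forest_cpp(X, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
    as.integer(mtry)
  )
  structure(
    list(
      trees = grown$trees,
      bootstrap = grown$bootstrap,
      mtry = as.integer(mtry), ntree = as.integer(ntree),
      seed = as.integer(seed),
      classes = levels(y), items = colnames(X),
      X = X, y = y
    ),
    class = "dcd_forest"
  )
}

#' @export
print.dcd_forest <- function(x, ...) {
  cat("<dcd_forest> ", x$ntree, " trees, mtry = ", x$mtry, ", ",
    nrow(x$X), " subjects x ", length(x$items), " items\n",
    sep = ""
  )
  invisible(x)
}

# n x ntree logical: is row i out-of-bag for tree t?
oob_matrix <- function(forest, n = nrow(forest$X)) {
  out <- matrix(TRUE, n, forest$ntree)
  for (t in seq_len(forest$ntree)) {
    out[unique(forest$bootstrap[[t]]), t] <- FALSE
  }
  out
}

forest_new_X <- function(forest, new_data) {
  X <- if (is.matrix(new_data)) new_data else cohort_matrix(new_data)
  if (ncol(X) != length(forest$items)) {
    abort("`new_data` must carry the same items as the training cohort.")
  }
  storage.mode(X) <- "integer"
  X
}

#' Predict diagnosis classes by majority vote
#'
#' Every tree votes its terminal node's majority class; a subject's
#' prediction is the modal vote, with ties broken by the fixed class
#' order (IM < VSC < MX).
#'
#' @param object A [fit_forest()] model.
#' @param new_data Cohort tibble or 0/1 item matrix; defaults to the
#'   training cohort.
#' @param type `"class"` for a factor of predictions, `"votes"` for a
#'   tibble of vote fractions per class.
#' @param ... Unused.
#' @return A factor, or a tibble of vote fractions.
#' @export
predict.dcd_forest <- function(object, new_data = NULL, type = c("class", "votes"),
                               ...) {
  type <- match.arg(type)
  X <- if (is.null(new_data)) object$X else forest_new_X(object, new_data)
  use <- matrix(TRUE, nrow(X), object$ntree)
  votes <- forest_votes_cpp(object$trees, X, length(object$classes), use)
  frac <- votes / rowSums(votes)
  colnames(frac) <- object$classes
  if (type == "votes") {
    return(tibble::as_tibble(as.data.frame(frac)))
  }
  factor(object$classes[apply(frac, 1, which_max_first)],
    levels = object$classes
  )
}

#' Out-of-bag error of a fitted forest
#'
#' Each training subject is predicted by majority vote over only the
#' trees whose bootstrap sample excluded it. Subjects that were in-bag
#' for every tree receive no OOB vote; they are skipped and counted in
#' `n_skipped`.
#'
#' @param forest A [fit_forest()] model.
#' @return A list with `overall` error rate, a `per_class` tibble
#'   (class, n, n_misclassified, error), and `n_skipped`.
#' @export
oob_error <- function(forest) {
  n <- nrow(forest$X)
  oob <- oob_matrix(forest)
  votes <- forest_votes_cpp(forest$trees, forest$X, length(forest$classes), oob)
  voted <- rowSums(votes) > 0
  if (!any(voted)) {
    abort("No subject received an out-of-bag vote; increase `ntree`.")
  }
  pred <- factor(forest$classes[apply(votes, 1, which_max_first)],
    levels = forest$classes
  )
  wrong <- voted & (pred != forest$y)
  per_class <- tibble::tibble(class = factor(forest$classes, levels = forest$classes)) |>
    dplyr::mutate(
      n = as.integer(table(forest$y[voted])[.data$class]),
      n_misclassified = as.integer(table(forest$y[wrong])[.data$class]),
      n_misclassified = dplyr::coalesce(.data$n_misclassified, 0L),
      error = .data$n_misclassified / .data$n
    )
  list(
    overall = sum(wrong) / sum(voted),
    per_class = per_class,
    n_skipped = sum(!voted)
  )
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' For each tree and item, out-of-bag accuracy is compared with the
#' accuracy after permuting that item's values among the tree's OOB
#' subjects; the decrease is averaged over trees. The class-specific
#' version restricts accuracy to the subjects of each true class.
#'
#' @param forest A [fit_forest()] model.
#' @param seed Integer seed driving the OOB permutations.
#' @return A `dcd_importance` object: list with `overall` (tibble item,
#'   importance) and `per_class` (class x item matrix).
#' @export
permutation_importance <- function(forest, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- perm_importance_cpp(
    forest$trees, forest$X, as.integer(forest$y) - 1L,
    length(forest$classes), oob_matrix(forest)
  )
  per_class <- res$per_class
  dimnames(per_class) <- list(forest$classes, forest$items)
  structure(
    list(
      overall = tibble::tibble(
        item = forest$items,
        importance = as.numeric(res$overall)
      ),
      per_class = per_class
    ),
    class = "dcd_importance"
  )
}

#' Random-forest proximity matrix
#'
#' Entry (i, j) is the fraction of trees in which subjects i and j land
#' in the same terminal node — a similarity in `[0, 1]` with unit
#' diagonal.
#'
#' @param forest A [fit_forest()] model.
#' @param new_data Optional cohort tibble / item matrix; defaults to the
#'   training cohort.
#' @return A symmetric numeric matrix.
#' @export
proximity_matrix <- function(forest, new_data = NULL) {
  X <- if (is.null(new_data)) forest$X else forest_new_X(forest, new_data)
  prox <- proximity_cpp(forest$trees, X)
  dimnames(prox) <- list(rownames(X), rownames(X))
  prox
}

#' Classical (Torgerson) MDS embedding of a proximity matrix
#'
#' The dissimilarity `1 - proximity` is squared, double-centered and
#' eigendecomposed; the top-`k` coordinates are scaled by the square
#' roots of the (nonnegative-truncated) eigenvalues. Each column's sign
#' is fixed so that its largest-magnitude coordinate is positive.
#'
#' @param prox Proximity (similarity) matrix from [proximity_matrix()].
#' @param k Number of dimensions, `1 <= k <= n - 1`.
#' @return A `dcd_mds` object: list with `points` (n x k), `eigenvalues`,
#'   `degenerate` flag, and the pieces needed by [mds_project()].
#' @export
mds_embed <- function(prox, k = 3) {
  n <- nrow(prox)
  if (k < 1 || k > n - 1) abort("`k` must lie in [1, n - 1].")
  D2 <- (1 - prox)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values, 0) # negative eigenvalues truncated at zero
  degenerate <- all(lambda < 1e-10)
  if (degenerate) {
    warn("All proximities equal: returning zero coordinates.")
    pts <- matrix(0, n, k)
  } else {
    pts <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(lambda[seq_len(k)]), k)
    for (j in seq_len(k)) { # deterministic eigenvector sign
      i_max <- which.max(abs(pts[, j]))
      if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
    }
  }
  rownames(pts) <- rownames(prox)
  structure(
    list(
      points = pts,
      eigenvalues = lambda,
      k = as.integer(k),
      degenerate = degenerate,
      sq_norms = diag(B) # for Gower add-a-point projection
    ),
    class = "dcd_mds"
  )
}

#' Project new subjects into a fitted MDS space
#'
#' Gower's add-a-point formula: given squared dissimilarities `d2` from a
#' new subject to every training subject,
#' `x_new = 0.5 * diag(1/lambda) %*% t(points) %*% (sq_norms - d2)`.
#'
#' @param embedding A [mds_embed()] result.
#' @param d2_new Matrix (new subjects x training subjects) of squared
#'   dissimilarities, e.g. `(1 - cross_proximity)^2`.
#' @return Coordinates of the new subjects (new subjects x k).
#' @export
mds_project <- function(embedding, d2_new) {
  if (ncol(d2_new) != nrow(embedding$points)) {
    abort("`d2_new` must have one column per training subject.")
  }
  k <- embedding$k
  lambda <- embedding$eigenvalues[seq_len(k)]
  keep <- lambda > 1e-10
  out <- matrix(0, nrow(d2_new), k)
  if (any(keep)) {
    diffs <- sweep(-d2_new, 2, -embedding$sq_norms) # sq_norms - d2 per row
    out[, keep] <- 0.5 * diffs %*% embedding$points[, keep, drop = FALSE] %*%
      diag(1 / lambda[keep], sum(keep))
  }
  out
}
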