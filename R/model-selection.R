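#' Repeated stratified k-fold resampling plan
#'
#' Within each repeat, subjects of every class are shuffled and dealt
#' round-robin into the folds, so each fold preserves the class
#' proportions up to rounding and the held-out sets partition the
#' sample. If the smallest class has fewer members than `n_folds`, the
#' fold count is reduced to that size with a warning.
#'
#' @param labels Diagnosis labels (factor or character).
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Repeats (default 10).
#' @param seed Integer seed.
#' @return A `dcd_plan` object: list with `folds` (list of lists with
#'   `train` / `heldout` index vectors), `n_folds`, `n_repeats`, `seed`.
#' @export
repeated_stratified_kfold <- function(labels, n_folds = 5, n_repeats = 10,
                                      seed = 1L) {
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  sizes <- table(y)
  if (any(sizes == 0)) abort("Every class must have at least one member.")
  if (min(sizes) < n_folds) {
    n_folds <- as.integer(min(sizes))
    warn(sprintf("Smallest class has %d members; reducing to %d folds.",
      min(sizes), n_folds
    ))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(y)
  folds <- list()
  for (r in seq_len(n_repeats)) {
    fold_of <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    for (f in seq_len(n_folds)) {
      held <- which(fold_of == f)
      folds[[length(folds) + 1L]] <- list(
        train = setdiff(seq_len(n), held), heldout = held,
        repeat_id = r, fold_id = f
      )
    }
  }
  structure(
    list(folds = folds, n_folds = n_folds, n_repeats = as.integer(n_repeats),
      stratified = TRUE, seed = as.integer(seed)
    ),
    class = "dcd_plan"
  )
}

#' Hyperparameter grids used for tuning
#'
#' `grid_rf()` gives 10 `mtry` values evenly spaced over `[2, p]`
#' (`ntree` is held constant during tuning); `grid_pls()` gives
#' `K = 1..10`; `grid_spls()` crosses `K = 1..10` with 10 uniformly
#' spaced `eta` values strictly inside (0.3, 0.9). Rows are ordered from
#' least to most complex so ties in tuning resolve to the simplest
#' setting.
#'
#' @param p Number of items (for the mtry grid).
#' @param K_max Largest number of components.
#' @return A tibble, one row per candidate setting.
#' @export
grid_rf <- function(p) {
  tibble::tibble(mtry = unique(as.integer(round(seq(2, p, length.out = 10)))))
}

#' @rdname grid_rf
#' @export
grid_pls <- function(K_max = 10) tibble::tibble(K = seq_len(K_max))

#' @rdname grid_rf
#' @export
grid_spls <- function(K_max = 10) {
  etas <- seq(0.3, 0.9, length.out = 12)[2:11] # 10 values inside (0.3, 0.9)
  tidyr::expand_grid(K = seq_len(K_max), eta = etas)
}

#' Grid tuning over a resampling plan
#'
#' For every candidate setting, `fit_predict` is trained on each fold's
#' training rows and asked to predict the held-out rows; the selection
#' criterion is the mean held-out classification accuracy across all
#' fold x repeat evaluations. Ties are broken towards the earliest
#' (least complex) grid row. Evaluations whose callback fails are
#' recorded as missing, excluded from the mean, and counted.
#'
#' @param cohort A cohort tibble.
#' @param fit_predict Callback `function(setting, train_cohort,
#'   heldout_cohort)` returning predicted labels for the held-out rows;
#'   `setting` is a one-row list of hyperparameters.
#' @param grid Tibble of candidate settings (see [grid_rf()] etc.).
#' @param plan A [repeated_stratified_kfold()] plan built on `cohort`'s
#'   labels.
#' @return A `dcd_tuning` object: list with `results` (grid + mean/sd
#'   accuracy + failure count), `best` (one-row tibble), and
#'   `accuracies` (settings x evaluations matrix).
#' @export
tune_grid <- function(cohort, fit_predict, grid, plan) {
  if (nrow(grid) == 0) abort("`grid` must be non-empty.")
  y <- cohort_labels(cohort)
  n_eval <- length(plan$folds)
  acc <- matrix(NA_real_, nrow(grid), n_eval)
  for (g in seq_len(nrow(grid))) {
    setting <- as.list(grid[g, ])
    for (e in seq_len(n_eval)) {
      fold <- plan$folds[[e]]
      pred <- tryCatch(
        fit_predict(
          setting,
          cohort[fold$train, , drop = FALSE],
          cohort[fold$heldout, , drop = FALSE]
        ),
        error = function(err) NULL
      )
      if (!is.null(pred)) {
        acc[g, e] <- mean(as.character(pred) == as.character(y[fold$heldout]))
      }
    }
  }
  results <- grid |>
    dplyr::mutate(
      mean_accuracy = rowMeans(acc, na.rm = TRUE),
      sd_accuracy = apply(acc, 1, sd, na.rm = TRUE),
      n_failed = rowSums(is.na(acc))
    )
  best_idx <- which_max_first(results$mean_accuracy)
  structure(
    list(
      results = results,
      best = results[best_idx, ],
      best_index = best_idx,
      accuracies = acc,
      plan_seed = plan$seed
    ),
    class = "dcd_tuning"
  )
}

#' @export
print.dcd_tuning <- function(x, ...) {
  cat("<dcd_tuning> ", nrow(x$results), " settings x ", ncol(x$accuracies),
    " evaluations; best mean accuracy ",
    sprintf("%.3f", x$best$mean_accuracy), "\n",
    sep = ""
  )
  print(x$best)
  invisible(x)
}

#' Ready-made tuning callbacks for the three classifiers
#'
#' Callbacks for [tune_grid()] wrapping [fit_forest()] (setting:
#' `mtry`), [fit_plsda()] (setting: `K`) and [fit_splsda()] (settings:
#' `K`, `eta`).
#'
#' @param ntree Trees per forest during tuning (held constant).
#' @param seed Seed forwarded to each forest fit.
#' @return A function usable as `fit_predict` in [tune_grid()].
#' @export
fit_predict_rf <- function(ntree = 500, seed = 1L) {
  function(setting, train, heldout) {
    fit <- fit_forest(train, mtry = setting$mtry, ntree = ntree, seed = seed)
    predict(fit, heldout)
  }
}

#' @rdname fit_predict_rf
#' @export
fit_predict_pls <- function() {
  function(setting, train, heldout) {
    fit <- fit_plsda(train, K = min(setting$K, nrow(train) - 1))
    predict(fit, heldout)
  }
}

#' @rdname fit_predict_rf
#' @export
fit_predict_spls <- function() {
  function(setting, train, heldout) {
    fit <- fit_splsda(train, K = min(setting$K, nrow(train) - 1), eta = setting$eta)
    predict(fit, heldout)
  }
}

#' Paired comparison of resampled accuracies between models
#'
#' Both tunings must have been run on the same resampling plan, so the
#' per-evaluation accuracies of their best settings are paired. The
#' difference is tested with a paired t-test; with `n_comparisons > 1`
#' the p-value is Bonferroni-multiplied. Identical accuracy vectors give
#' p = 1 by convention. (Fold-level accuracies are correlated, so this
#' test is anti-conservative; it mirrors the usual resampled-comparison
#' practice rather than correcting for it.)
#'
#' @param tuning_a,tuning_b [tune_grid()] results on the same plan.
#' @param n_comparisons Number of model pairs tested (Bonferroni factor).
#' @return A tibble with the mean accuracy difference and corrected p.
#' @export
compare_accuracies <- function(tuning_a, tuning_b, n_comparisons = 1) {
  a <- tuning_a$accuracies[tuning_a$best_index, ]
  b <- tuning_b$accuracies[tuning_b$best_index, ]
  if (length(a) != length(b) ||
    !identical(tuning_a$plan_seed, tuning_b$plan_seed)) {
    abort("Tunings must come from the same resampling plan.")
  }
  keep <- !is.na(a) & !is.na(b)
  d <- a[keep] - b[keep]
  p <- if (sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) 1 else 0 # constant difference: sd is 0
  } else {
    min(1, t.test(d)$p.value * n_comparisons)
  }
  tibble::tibble(
    mean_diff = mean(d),
    p_value = p,
    n_evaluations = sum(keep)
  )
}

#' One-vs-rest sensitivity and specificity per diagnosis class
#'
#' Summarises validation predictions the way clustering-fitness reports
#' are laid out: for each class, sensitivity is the fraction of its true
#' members predicted as it, and specificity the fraction of non-members
#' not predicted as it.
#'
#' @param predicted,truth Aligned label vectors (factor or character).
#' @return A tibble with `class`, `n`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must be aligned.")
  }
  y <- if (is.factor(truth)) truth else factor(truth)
  p <- factor(as.character(predicted), levels = levels(y))
  purrr::map_dfr(levels(y), function(cl) {
    is_cl <- y == cl
    tibble::tibble(
      class = cl,
      n = sum(is_cl),
      sensitivity = if (any(is_cl)) mean(p[is_cl] == cl) else NA_real_,
      specificity = if (any(!is_cl)) mean(p[!is_cl] != cl) else NA_real_
    )
  })
}

#' Permutation significance test for variable importance
#'
#' Class labels are randomly exchanged `B` times and the per-item
#' importance recomputed on each permuted cohort; the one-sided p-value
#' is `(1 + #\{null >= observed\}) / (B + 1)` (importance is only
#' meaningfully large). With `B = 999` the smallest attainable p is
#' 0.001.
#'
#' @param cohort A cohort tibble.
#' @param importance_fn Callback `function(cohort)` returning a numeric
#'   vector of per-item importances (names taken from the first call).
#' @param B Number of permutations (>= 99; default 999).
#' @param alpha Significance level for the reported significant set.
#' @param seed Integer seed.
#' @return A `dcd_perm_test` object: list with `observed`, `pvalues`
#'   tibble (item, importance, p_value, significant), `null_samples`
#'   (B x items), `alpha`, `B`.
#' @export
permutation_importance_test <- function(cohort, importance_fn, B = 999,
                                        alpha = 0.05, seed = 1L) {
  if (B < 99) abort("`B` must be at least 99.")
  observed <- importance_fn(cohort)
  p <- length(observed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  null_samples <- matrix(NA_real_, B, p)
  perm <- cohort
  for (b in seq_len(B)) {
    perm$diagnosis <- cohort$diagnosis[sample(nrow(cohort))]
    null_samples[b, ] <- importance_fn(perm)
  }
  pvals <- (1 + colSums(sweep(null_samples, 2, observed, ">=") + 0)) / (B + 1)
  items <- names(observed) %||% cohort_item_cols(cohort)
  tab <- tibble::tibble(
    item = items,
    importance = unname(observed),
    p_value = pvals,
    significant = pvals <= alpha
  )
  structure(
    list(
      observed = observed, pvalues = tab, null_samples = null_samples,
      alpha = alpha, B = as.integer(B),
      significant_items = items[tab$significant]
    ),
    class = "dcd_perm_test"
  )
}

#' @export
print.dcd_perm_test <- function(x, ...) {
  cat("<dcd_perm_test> B = ", x$B, ", alpha = ", x$alpha, "; ",
    length(x$significant_items), " significant item(s)\n",
    sep = ""
  )
  if (length(x$significant_items)) {
    cat(" ", paste(x$significant_items, collapse = ", "), "\n")
  }
  invisible(x)
}
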