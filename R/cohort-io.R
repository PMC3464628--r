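#' Read and write cohort CSV files
#'
#' The on-disk dialect is a comma-separated UTF-8 file with header
#' `subject_id,diagnosis,<ITEM1>,...,<ITEMp>`; item cells are 0 (success)
#' or 1 (failure) and diagnosis is one of IM, VSC, MX. `write_cohort_csv()`
#' then `read_cohort_csv()` is an exact round trip.
#'
#' @param path File path.
#' @param cohort A cohort tibble as produced by [generate_cohort()].
#' @param classes Allowed diagnosis values, in their fixed order.
#' @return `read_cohort_csv()` returns a cohort tibble; malformed cells
#'   raise an error naming the offending row and column.
#' @export
read_cohort_csv <- function(path, classes = dcd_class_levels()) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      diagnosis = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  if (!all(c("subject_id", "diagnosis") %in% names(raw))) {
    abort("Cohort file must have `subject_id` and `diagnosis` columns.")
  }
  dup <- raw$subject_id[duplicated(raw$subject_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate subject id(s): %s.", paste(unique(dup), collapse = ", ")))
  }
  bad_dx <- which(!raw$diagnosis %in% classes)
  if (length(bad_dx)) {
    abort(sprintf(
      "Unknown diagnosis %s at row %d.", raw$diagnosis[bad_dx[1]], bad_dx[1]
    ))
  }
  items <- setdiff(names(raw), c("subject_id", "diagnosis"))
  if (anyDuplicated(items)) abort("Duplicate item columns in header.")
  for (it in items) {
    v <- raw[[it]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad)) {
      abort(sprintf(
        "Non-binary value in item column %s at row %d.", it, bad[1]
      ))
    }
  }
  raw |>
    dplyr::mutate(
      diagnosis = factor(.data$diagnosis,
        levels = intersect(classes, unique(.data$diagnosis))
      ),
      dplyr::across(dplyr::all_of(items), as.integer)
    )
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort |>
    dplyr::mutate(diagnosis = as.character(.data$diagnosis))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Stratified training/validation split
#'
#' Within each diagnosis class, `ceiling(fraction * class size)` subjects
#' are drawn uniformly without replacement into the training set; the
#' remainder form the validation set. Per-class ceiling rounding
#' reproduces a 46/17 split from class sizes 5/33/25 at fraction 0.7.
#'
#' @param cohort A cohort tibble (only `diagnosis` is used).
#' @param fraction Training fraction in (0, 1); default 0.7.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `dcd_split`: list with integer vectors
#'   `training` and `validation` (row indices into `cohort`) and the
#'   `fraction` used.
#' @export
stratified_split <- function(cohort, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  y <- cohort_labels(cohort)
  if (any(table(y) == 0)) abort("Every class must have at least one subject.")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- ceiling(fraction * length(idx))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  valid <- setdiff(seq_len(nrow(cohort)), train)
  if (length(valid) == 0) {
    abort("Split leaves the validation set empty; lower `fraction`.")
  }
  structure(
    list(training = train, validation = valid, fraction = fraction),
    class = "dcd_split"
  )
}

#' @export
print.dcd_split <- function(x, ...) {
  cat("<dcd_split> training n =", length(x$training),
    "/ validation n =", length(x$validation),
    sprintf("(fraction %.2f)\n", x$fraction)
  )
  invisible(x)
}

#' Per-item marginal failure rates and inter-item correlations
#'
#' @param cohort A cohort tibble.
#' @return A list with `proportions` (tibble: item, failure proportion),
#'   `correlations` (items x items Pearson phi matrix; `NA` for
#'   zero-variance items), and `correlation_summary` (tibble with the
#'   range and median of the off-diagonal correlations, zero-variance
#'   items excluded).
#' @export
item_summary <- function(cohort) {
  X <- cohort_matrix(cohort)
  if (nrow(X) < 2) abort("Need at least 2 subjects.")
  prop <- colMeans(X)
  sds <- apply(X, 2, sd)
  R <- suppressWarnings(cor(X))
  diag(R) <- 1
  R[sds == 0, ] <- NA_real_
  R[, sds == 0] <- NA_real_
  diag(R) <- ifelse(sds == 0, NA_real_, 1)
  off <- R[upper.tri(R)]
  off <- off[!is.na(off)]
  list(
    proportions = tibble::tibble(item = colnames(X), failure_prop = unname(prop)),
    correlations = R,
    correlation_summary = tibble::tibble(
      min = min(off), median = stats::median(off), max = max(off)
    )
  )
}

#' Class-conditional item failure frequencies
#'
#' The numeric content of a conditional impairment heatmap: entry (c, j)
#' is the proportion of class-c subjects failing item j. Classes absent
#' from the cohort are omitted.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `diagnosis`, `item`, `failure_prop`.
#' @export
conditional_failure_table <- function(cohort) {
  items <- cohort_item_cols(cohort)
  cohort |>
    dplyr::mutate(diagnosis = droplevels(cohort_labels(cohort))) |>
    tidyr::pivot_longer(dplyr::all_of(items),
      names_to = "item", values_to = "failed"
    ) |>
    dplyr::group_by(.data$diagnosis, .data$item) |>
    dplyr::summarise(failure_prop = mean(.data$failed), .groups = "drop") |>
    dplyr::mutate(item = factor(.data$item, levels = items))
}

#' Monte-Carlo chi-squared comparison of split halves
#'
#' For each item, the 2x2 table (training/validation x success/failure)
#' is tested with a Monte-Carlo chi-squared statistic: null tables are
#' generated by randomly permuting split membership with all margins
#' fixed, and `p = (1 + #\{simulated chi2 >= observed\}) / (n_mc + 1)`.
#' Items constant across the whole cohort get p = 1 by convention.
#'
#' @param cohort A cohort tibble.
#' @param split A [stratified_split()] result.
#' @param n_mc Number of Monte-Carlo tables (>= 99).
#' @param seed Integer seed.
#' @return A tibble with columns `item` and `p_value`.
#' @export
compare_samples_mc_chi2 <- function(cohort, split, n_mc = 999, seed = 1L) {
  if (n_mc < 99) abort("`n_mc` must be at least 99.")
  if (!length(split$training) || !length(split$validation)) {
    abort("Both split halves must be non-empty.")
  }
  X <- cohort_matrix(cohort)
  n1 <- length(split$training)
  n2 <- length(split$validation)
  n <- n1 + n2
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  chi2_2x2 <- function(a, m1, m2, k) {
    # a = failures in half 1 (vectorized); margins: halves (m1, m2),
    # failures k out of n
    n <- m1 + m2
    e11 <- m1 * k / n
    e12 <- m1 * (n - k) / n
    e21 <- m2 * k / n
    e22 <- m2 * (n - k) / n
    (a - e11)^2 / e11 + (m1 - a - e12)^2 / e12 +
      (k - a - e21)^2 / e21 + (m2 - k + a - e22)^2 / e22
  }
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    k <- sum(X[, j])
    if (k == 0 || k == n) return(1) # degenerate: constant item
    a_obs <- sum(X[split$training, j])
    obs <- chi2_2x2(a_obs, n1, n2, k)
    # permuting membership with fixed margins <=> hypergeometric draw of
    # the half-1 failure count
    a_sim <- rhyper(n_mc, k, n - k, n1)
    sim <- chi2_2x2(a_sim, n1, n2, k)
    (1 + sum(sim >= obs - 1e-12)) / (n_mc + 1)
  }, numeric(1))
  tibble::tibble(item = colnames(X), p_value = pvals)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Familywise error rate in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 11) # 0.0045
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (!is.numeric(m) || m < 1) abort("`m` must be a positive integer.")
  alpha / m
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Thin wrapper over [stats::binom.test()] used to attach exact
#' confidence bounds to validation accuracies.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level.
#' @return A tibble with `estimate`, `lower`, `upper`.
#' @export
exact_binomial_ci <- function(x, n, conf_level = 0.95) {
  bt <- binom.test(x, n, conf.level = conf_level)
  tibble::tibble(
    estimate = unname(bt$estimate),
    lower = bt$conf.int[1],
    upper = bt$conf.int[2]
  )
}
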