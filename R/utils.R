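# Internal helpers shared across modules. A "cohort" is a tibble with a
# subject_id column, a diagnosis factor, and one 0/1 column per item.

cohort_item_cols <- function(cohort) {
  setdiff(names(cohort), c("subject_id", "diagnosis"))
}

# subjects x items integer matrix, rownames = subject ids
cohort_matrix <- function(cohort) {
  items <- cohort_item_cols(cohort)
  X <- as.matrix(cohort[items])
  storage.mode(X) <- "integer"
  rownames(X) <- cohort$subject_id
  X
}

cohort_labels <- function(cohort) {
  y <- cohort$diagnosis
  if (!is.factor(y)) y <- factor(y, levels = intersect(DCD_CLASSES, unique(y)))
  droplevels(y)
}

assert_binary_matrix <- function(X, arg = "X") {
  if (!all(X %in% c(0L, 1L))) {
    abort(sprintf("`%s` must contain only 0/1 item outcomes.", arg))
  }
  invisible(X)
}

# Largest-remainder (Hamilton) apportionment of n among priors.
# Guarantees counts sum to n; ties on remainders broken by class order.
largest_remainder <- function(priors, n) {
  quota <- priors * n
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# argmax with ties broken by the first (lowest) index; NAs ignored
which_max_first <- function(x) which.max(x)

new_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}
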