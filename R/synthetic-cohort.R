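#' Specify a synthetic dyspraxia cohort
#'
#' A cohort specification bundles everything needed to simulate a subjects
#' x items binary outcome matrix with a three-subtype class structure:
#' class priors, per-class Bernoulli failure probabilities for every item,
#' and a single shared latent factor (Gaussian copula) inducing
#' within-subject dependence between items.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param class_names Ordered character vector of class labels.
#' @param class_priors Probability vector over classes (sums to 1).
#' @param item_codes Character vector of item codes (length p).
#' @param failure_probs class x item matrix of failure probabilities in
#'   `[0, 1]`; rows named by class, columns by item.
#' @param latent_correlation Scalar in `[0, 1)`: the weight of the shared
#'   per-subject latent normal factor mixed into each item's latent normal
#'   (0 gives conditionally independent items).
#' @param seed Integer seed making [generate_cohort()] deterministic.
#'
#' @return An object of class `dcd_spec`.
#' @seealso [dcd_spec_paperlike()] for the calibrated three-subtype design.
#' @export
dcd_spec <- function(n_subjects, class_names, class_priors, item_codes,
                     failure_probs, latent_correlation = 0, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1) abort("`n_subjects` must be positive.")
  if (length(class_names) != length(class_priors)) {
    abort("`class_priors` must have one entry per class.")
  }
  if (abs(sum(class_priors) - 1) > 1e-12) {
    abort("`class_priors` must sum to 1 (within 1e-12).")
  }
  if (any(class_priors < 0)) abort("`class_priors` must be non-negative.")
  failure_probs <- as.matrix(failure_probs)
  if (ncol(failure_probs) != length(item_codes)) {
    abort("`failure_probs` must have one column per item code.")
  }
  if (nrow(failure_probs) != length(class_names)) {
    abort("`failure_probs` must have one row per class.")
  }
  if (any(failure_probs < 0 | failure_probs > 1)) {
    abort("All `failure_probs` must lie in [0, 1].")
  }
  if (anyDuplicated(item_codes)) abort("`item_codes` must be unique.")
  if (latent_correlation < 0 || latent_correlation >= 1) {
    abort("`latent_correlation` must lie in [0, 1).")
  }
  dimnames(failure_probs) <- list(class_names, item_codes)
  structure(
    list(
      n_subjects = n_subjects,
      class_names = as.character(class_names),
      class_priors = as.numeric(class_priors),
      item_codes = as.character(item_codes),
      failure_probs = failure_probs,
      latent_correlation = as.numeric(latent_correlation),
      seed = as.integer(seed)
    ),
    class = "dcd_spec"
  )
}

#' @export
print.dcd_spec <- function(x, ...) {
  cat("<dcd_spec> ", x$n_subjects, " subjects, ",
    length(x$item_codes), " items, classes: ",
    paste(sprintf("%s (%.0f%%)", x$class_names, 100 * x$class_priors),
      collapse = ", "
    ),
    ", latent correlation ", x$latent_correlation, "\n",
    sep = ""
  )
  invisible(x)
}

#' Calibrated three-subtype cohort specification
#'
#' Builds a [dcd_spec()] emulating a 63-child dyspraxia cohort: 49 binary
#' clinical items, class priors 8% ideomotor (IM) / 52% visual-spatial and
#' constructional (VSC) / 40% mixt (MX), and class-conditional impairment
#' patterns. The discriminative items fail with probability
#' `p_impaired` in the classes they characterise (IM: DIPE, IMOG, DIPR,
#' SYNK; VSC: LEBL, PUZL, VISS, VISC, VIMI; MX: the union of both plus
#' CULL and MAND) and with probability `p_unimpaired` elsewhere. The
#' remaining 38 background items get class-independent failure
#' probabilities drawn once (from `seed`) uniformly over
#' `[0.08, 0.92]`, matching the span of marginal failure rates seen on
#' real batteries.
#'
#' @param n_subjects Cohort size; must be at least 3 x 3 so every class
#'   can be represented.
#' @param seed Integer seed (fixes both the background probabilities and
#'   downstream cohort generation).
#' @param p_impaired,p_unimpaired Failure probabilities of discriminative
#'   items in impaired / unimpaired classes.
#' @param latent_correlation Shared-factor weight passed to [dcd_spec()].
#'
#' @return A `dcd_spec` with 49 items and classes IM, VSC, MX.
#' @export
dcd_spec_paperlike <- function(n_subjects = 63, seed = 1L,
                               p_impaired = 0.9, p_unimpaired = 0.1,
                               latent_correlation = 0.3) {
  n_classes <- length(DCD_CLASSES)
  if (n_subjects < 3 * n_classes) {
    abort("`n_subjects` must be at least 3 subjects per class (9).")
  }
  stopifnot(p_impaired >= 0.8, p_unimpaired <= 0.15)
  impaired <- list(
    IM  = c("DIPE", "IMOG", "DIPR", "SYNK"),
    VSC = c("LEBL", "PUZL", "VISS", "VISC", "VIMI"),
    MX  = c(
      "DIPE", "IMOG", "DIPR", "SYNK", "LEBL", "PUZL", "VISS", "VISC",
      "VIMI", "CULL", "MAND"
    )
  )
  discriminative <- unique(unlist(impaired))
  background <- setdiff(DCD_ITEMS, discriminative)

  probs <- matrix(NA_real_, n_classes, length(DCD_ITEMS),
    dimnames = list(DCD_CLASSES, DCD_ITEMS)
  )
  withr_seed <- function(expr) { # local RNG so callers' streams are untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  bg <- withr_seed(runif(length(background), 0.08, 0.92))
  for (cl in DCD_CLASSES) {
    probs[cl, discriminative] <- ifelse(
      discriminative %in% impaired[[cl]], p_impaired, p_unimpaired
    )
    probs[cl, background] <- bg
  }

  spec <- dcd_spec(
    n_subjects = n_subjects,
    class_names = DCD_CLASSES,
    class_priors = c(IM = 0.08, VSC = 0.52, MX = 0.40),
    item_codes = DCD_ITEMS,
    failure_probs = probs,
    latent_correlation = latent_correlation,
    seed = seed
  )
  spec$planted_items <- impaired$MX # the 11 truly discriminative items
  spec
}

#' Serialize a cohort specification to JSON
#'
#' Round-trip safe: `read_spec_json(write_spec_json(spec, f))` reproduces
#' the specification exactly (probabilities at full double precision).
#'
#' @param spec A [dcd_spec()].
#' @param path File path.
#' @return `write_spec_json()` returns `path` invisibly;
#'   `read_spec_json()` returns a `dcd_spec`.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "dcd_spec"))
  out <- spec
  out$failure_probs <- unname(as.matrix(out$failure_probs))
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp <- raw$failure_probs
  fp <- if (is.list(fp)) do.call(rbind, lapply(fp, unlist)) else as.matrix(fp)
  spec <- dcd_spec(
    n_subjects = raw$n_subjects,
    class_names = raw$class_names,
    class_priors = raw$class_priors,
    item_codes = raw$item_codes,
    failure_probs = fp,
    latent_correlation = raw$latent_correlation,
    seed = raw$seed
  )
  if (!is.null(raw$planted_items)) spec$planted_items <- raw$planted_items
  spec
}

#' Simulate a cohort from a specification
#'
#' Class sizes are apportioned from the priors by the largest-remainder
#' rule (so small classes never vanish from small cohorts). Given a
#' subject's class, item outcomes are correlated Bernoullis drawn through
#' a Gaussian copula: each subject gets one shared latent standard normal
#' `g` and independent per-item normals `e_j`; the item latent is
#' `sqrt(rho) * g + sqrt(1 - rho) * e_j` and the item fails when that
#' latent falls below the normal quantile of its failure probability.
#' The draw is bit-for-bit reproducible from `spec$seed`.
#'
#' @param spec A [dcd_spec()].
#' @return A cohort tibble with columns `subject_id`, `diagnosis` (factor
#'   in class order) and one 0/1 integer column per item.
#' @examples
#' cohort <- generate_cohort(dcd_spec_paperlike(63, seed = 42))
#' dplyr::count(cohort, diagnosis)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "dcd_spec"))
  n <- spec$n_subjects
  p <- length(spec$item_codes)
  counts <- largest_remainder(spec$class_priors, n)
  labels <- factor(rep(spec$class_names, counts), levels = spec$class_names)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  rho <- spec$latent_correlation
  g <- rnorm(n)
  E <- matrix(rnorm(n * p), n, p)
  latent <- sqrt(rho) * g + sqrt(1 - rho) * E
  thresh <- qnorm(spec$failure_probs[as.integer(labels), , drop = FALSE])
  X <- ifelse(latent < thresh, 1L, 0L)
  # qnorm(0) = -Inf so p = 0 yields all successes; p = 1 all failures
  colnames(X) <- spec$item_codes

  tibble::as_tibble(as.data.frame(X)) |>
    dplyr::mutate(
      subject_id = sprintf("S%03d", seq_len(n)),
      diagnosis = labels,
      .before = 1
    )
}
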