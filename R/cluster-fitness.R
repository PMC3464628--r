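#' Partition subjects around medoids (PAM)
#'
#' k-medoids clustering of subjects in a component-score space
#' (Euclidean distance), via the classical BUILD + SWAP algorithm of
#' [cluster::pam()]. Assignments go to the nearest medoid, ties to the
#' lowest medoid index. Per-observation silhouettes are recomputed with
#' [silhouette_widths()] (singleton clusters get silhouette 0).
#'
#' @param points Numeric n x d matrix of scores (PLS components or
#'   RF-proximity MDS coordinates).
#' @param k Number of clusters, `2 <= k < n`.
#' @return A `dcd_clusters` object: list with `k`, `medoid_indices`,
#'   `assignments`, `silhouettes`, `asw`, `per_cluster_asw`, `points`.
#' @export
pam_clusters <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 2 || k >= n) abort("`k` must lie in [2, n - 1].")
  fit <- cluster::pam(points, k, metric = "euclidean", keep.diss = FALSE,
    keep.data = FALSE
  )
  medoids <- as.integer(fit$id.med)
  assignments <- as.integer(fit$clustering) # nearest medoid; clusters non-empty
  sil <- silhouette_widths(points, assignments)
  structure(
    list(
      k = as.integer(k),
      medoid_indices = medoids,
      assignments = as.integer(assignments),
      silhouettes = sil$silhouettes,
      asw = sil$asw,
      per_cluster_asw = sil$per_cluster_asw,
      points = points
    ),
    class = "dcd_clusters"
  )
}

#' @export
print.dcd_clusters <- function(x, ...) {
  cat("<dcd_clusters> k = ", x$k, ", sizes ",
    paste(tabulate(x$assignments, x$k), collapse = "/"),
    sprintf(", ASW %.3f\n", x$asw),
    sep = ""
  )
  invisible(x)
}

#' Silhouette widths of a partition
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)` the mean
#' distance of i to its own cluster (excluding i) and `b(i)` the
#' smallest mean distance to any other cluster; members of singleton
#' clusters get `s(i) = 0` by convention.
#'
#' @param points Numeric n x d score matrix.
#' @param assignments Integer cluster ids per subject (>= 2 clusters,
#'   all non-empty).
#' @return A list with `silhouettes` (per subject), `asw` (their mean)
#'   and `per_cluster_asw`.
#' @export
silhouette_widths <- function(points, assignments) {
  assignments <- as.integer(assignments)
  ids <- sort(unique(assignments))
  if (length(ids) < 2) abort("Silhouettes need at least 2 clusters.")
  D <- as.matrix(dist(as.matrix(points)))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assignments == assignments[i])
    if (length(own) == 1) next # singleton convention: s = 0
    a_i <- mean(D[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(ids, assignments[i]), function(cl) {
      mean(D[i, assignments == cl])
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  per_cluster <- vapply(ids, function(cl) mean(s[assignments == cl]), numeric(1))
  list(
    silhouettes = s,
    asw = mean(s),
    per_cluster_asw = rlang::set_names(per_cluster, ids)
  )
}

#' Choose the number of clusters by average silhouette width
#'
#' Fits PAM for each candidate `k` and returns the solution maximising
#' the overall average silhouette width; ties go to the smaller `k`.
#'
#' @param points Numeric n x d score matrix.
#' @param k_range Candidate cluster counts (default 2..7, clipped to
#'   `n - 1`).
#' @return A list with `best_k`, the winning `dcd_clusters` solution,
#'   and an `asw_by_k` tibble.
#' @export
choose_k <- function(points, k_range = 2:7) {
  points <- as.matrix(points)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(points) - 1]
  if (length(k_range) == 0) abort("`k_range` is empty after clipping to [2, n - 1].")
  fits <- lapply(sort(k_range), function(k) pam_clusters(points, k))
  asw <- vapply(fits, function(f) f$asw, numeric(1))
  best <- which(asw == max(asw))[1L] # ties: smaller k (range is sorted)
  list(
    best_k = fits[[best]]$k,
    solution = fits[[best]],
    asw_by_k = tibble::tibble(k = vapply(fits, `[[`, integer(1), "k"), asw = asw)
  )
}

#' Bootstrap cluster stability (clusterwise Jaccard)
#'
#' For each of `B` bootstrap resamples (subjects drawn with
#' replacement), PAM is re-run with the original `k` on the resampled
#' points; each original cluster is matched to the new cluster
#' maximising the Jaccard similarity of their subject-identity sets
#' (duplicates deduplicated), and these maxima are averaged clusterwise
#' over resamples.
#'
#' @param solution A [pam_clusters()] result (carries its points).
#' @param B Number of bootstrap resamples (default 500).
#' @param seed Integer seed.
#' @return A tibble with `cluster`, `mean_jaccard`, `B`.
#' @export
bootstrap_stability <- function(solution, B = 500, seed = 1L) {
  points <- solution$points
  n <- nrow(points)
  k <- solution$k
  orig <- split(seq_len(n), solution$assignments)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  jac <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    take <- sample(n, n, replace = TRUE)
    refit <- tryCatch(pam_clusters(points[take, , drop = FALSE], k),
      error = function(e) NULL
    )
    if (is.null(refit)) next
    new_sets <- lapply(split(seq_len(n), refit$assignments), function(rows) {
      unique(take[rows]) # set semantics on original subject identities
    })
    sampled <- unique(take)
    for (cl in seq_len(k)) {
      # restrict the original cluster to subjects present in the resample
      A <- intersect(orig[[cl]], sampled)
      if (length(A) == 0) next
      jac[b, cl] <- max(vapply(new_sets, function(Bset) {
        length(intersect(A, Bset)) / length(union(A, Bset))
      }, numeric(1)))
    }
  }
  tibble::tibble(
    cluster = seq_len(k),
    mean_jaccard = colMeans(jac, na.rm = TRUE),
    B = as.integer(B)
  )
}

#' Cluster isolation (L and L* labels)
#'
#' A cluster's diameter is its largest within-cluster distance and its
#' separation the smallest distance from any member to any non-member.
#' It is an L*-cluster iff diameter < separation; it is an L-cluster iff
#' every member's farthest within-cluster neighbour is nearer than any
#' outside observation (L* implies L).
#'
#' @param solution A [pam_clusters()] result.
#' @return A tibble with `cluster`, `diameter`, `separation`, `label`
#'   (`"L*"`, `"L"` or `"none"`).
#' @export
isolation_classify <- function(solution) {
  D <- as.matrix(dist(solution$points))
  a <- solution$assignments
  purrr::map_dfr(seq_len(solution$k), function(cl) {
    inside <- which(a == cl)
    outside <- which(a != cl)
    Din <- D[inside, inside, drop = FALSE]
    diameter <- if (length(inside) > 1) max(Din) else 0
    separation <- min(D[inside, outside, drop = FALSE])
    l_star <- diameter < separation
    l_cond <- all(vapply(seq_along(inside), function(ii) {
      max_in <- if (length(inside) > 1) max(Din[ii, -ii]) else 0
      max_in < min(D[inside[ii], outside])
    }, logical(1)))
    tibble::tibble(
      cluster = cl, diameter = diameter, separation = separation,
      label = if (l_star) "L*" else if (l_cond) "L" else "none"
    )
  })
}

#' Validation-sample affinity to training cluster medoids
#'
#' Euclidean distance from every validation subject (projected into the
#' training score space) to each cluster medoid, plus the mean distance
#' from each expected cluster to every medoid and a flag for whether the
#' expected cluster's own medoid is the nearest on average.
#'
#' @param medoid_points k x d matrix of medoid coordinates.
#' @param validation_points m x d matrix of projected validation
#'   subjects.
#' @param expected_clusters Integer (or factor) vector of length m: the
#'   cluster each validation subject is expected to join.
#' @return A list with `distances` (tibble subject x medoid) and
#'   `by_cluster` (tibble: expected_cluster, medoid, mean_distance,
#'   own_is_nearest).
#' @export
validation_affinity <- function(medoid_points, validation_points,
                                expected_clusters) {
  medoid_points <- as.matrix(medoid_points)
  validation_points <- as.matrix(validation_points)
  if (ncol(medoid_points) != ncol(validation_points)) {
    abort("Medoid and validation points must share dimensions.")
  }
  k <- nrow(medoid_points)
  m <- nrow(validation_points)
  Dm <- vapply(seq_len(k), function(j) {
    sqrt(rowSums(sweep(validation_points, 2, medoid_points[j, ])^2))
  }, numeric(m))
  Dm <- matrix(Dm, nrow = m)
  distances <- tibble::as_tibble(as.data.frame(Dm)) |>
    rlang::set_names(paste0("C", seq_len(k))) |>
    dplyr::mutate(
      subject = seq_len(m),
      expected_cluster = as.integer(expected_clusters),
      .before = 1
    )
  by_cluster <- distances |>
    tidyr::pivot_longer(dplyr::starts_with("C"),
      names_to = "medoid", values_to = "distance"
    ) |>
    dplyr::group_by(.data$expected_cluster, .data$medoid) |>
    dplyr::summarise(mean_distance = mean(.data$distance), .groups = "drop_last") |>
    dplyr::mutate(own_is_nearest = .data$mean_distance[
      .data$medoid == paste0("C", .data$expected_cluster[1])
    ] == min(.data$mean_distance)) |>
    dplyr::ungroup()
  list(distances = distances, by_cluster = by_cluster)
}

#' Cross-classification of clusters and diagnosis classes
#'
#' The contingency table behind a cluster-vs-diagnosis ribbon display:
#' counts of subjects per (cluster, class) cell with row and column
#' margins.
#'
#' @param assignments Cluster ids per subject.
#' @param labels Diagnosis labels aligned to `assignments`.
#' @return A tibble with `cluster`, one column per class, and a `total`
#'   column; attribute `"col_totals"` holds the class margins.
#' @export
cross_classification <- function(assignments, labels) {
  if (length(assignments) != length(labels)) {
    abort("`assignments` and `labels` must be aligned.")
  }
  y <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  tab <- table(cluster = assignments, class = y)
  out <- tibble::as_tibble(as.data.frame.matrix(tab)) |>
    dplyr::mutate(cluster = rownames(tab), .before = 1) |>
    dplyr::mutate(total = rowSums(tab))
  attr(out, "col_totals") <- colSums(tab)
  out
}
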