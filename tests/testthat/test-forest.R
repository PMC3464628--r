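test_that("default mtry is the floored square root", {
  expect_identical(default_mtry(49), 7L)
  expect_identical(default_mtry(1), 1L)
  expect_identical(default_mtry(10), 3L)
})

test_that("a single perfectly separating item yields a perfect stump", {
  co <- make_cohort(matrix(rep(c(0L, 1L), each = 5)), rep(c("IM", "VSC"), each = 5))
  fit <- fit_forest(co, mtry = 1, ntree = 1, seed = 1)
  tree <- fit$trees[[1]]
  expect_equal(sum(tree$var >= 0), 1) # one internal node: depth-1 tree
  expect_equal(mean(predict(fit) == co$diagnosis), 1)
})

test_that("constant predictors give single-leaf trees", {
  co <- make_cohort(matrix(1L, 10, 3), rep(c("IM", "VSC"), 5))
  fit <- fit_forest(co, ntree = 5, seed = 1)
  for (tree in fit$trees) expect_equal(tree$var, -1L)
})

test_that("every split matches the exhaustive Gini oracle", {
  set.seed(31)
  for (rep in 1:10) {
    X <- matrix(rbinom(8 * 5, 1, 0.5), 8, 5)
    y <- factor(sample(c("IM", "VSC", "MX"), 8, TRUE),
      levels = c("IM", "VSC", "MX")
    )
    if (nlevels(droplevels(y)) < 2) next
    co <- make_cohort(X, as.character(y))
    fit <- fit_forest(co, mtry = 5, ntree = 3, seed = rep) # mtry = p
    yy <- cohort_labels_of(co)
    for (t in seq_along(fit$trees)) {
      tree <- fit$trees[[t]]
      rows <- fit$bootstrap[[t]]
      root_var <- tree$var[1] + 1L
      oracle <- brute_force_best_gini(X, yy, rows)
      if (root_var == 0L) { # leaf: no split can strictly reduce impurity
        gini <- 1 - sum((table(yy[rows]) / length(rows))^2)
        expect_gte(oracle + 1e-12, gini)
      } else {
        left <- rows[X[rows, root_var] == 0]
        right <- rows[X[rows, root_var] == 1]
        gini <- function(v) if (!length(v)) 0 else 1 - sum((table(v) / length(v))^2)
        achieved <- (length(left) * gini(yy[left]) +
          length(right) * gini(yy[right])) / length(rows)
        expect_equal(achieved, oracle)
      }
    }
  }
})

test_that("majority voting is deterministic with class-order tie-breaks", {
  co <- make_cohort(matrix(0L, 4, 2), c("IM", "IM", "VSC", "VSC"))
  fit <- fit_forest(co, ntree = 7, seed = 2)
  # all trees are leaves on constant X; votes are unanimous
  v <- predict(fit, type = "votes")
  expect_true(all(as.matrix(v) %in% c(0, 1)))

  # engineered 2-tree tie: one tree votes IM, the other VSC
  stub <- function(cls) list(
    var = -1L, kid0 = -1L, kid1 = -1L,
    leaf_class = cls
  )
  fit$trees <- list(stub(0L), stub(1L))
  fit$bootstrap <- list(1:4, 1:4)
  fit$ntree <- 2L
  pred <- predict(fit)
  expect_true(all(pred == "IM")) # first class in fixed order wins ties
})

test_that("out-of-bag error approximates hold-out error", {
  diffs <- vapply(1:5, function(r) {
    co <- generate_cohort(dcd_spec_paperlike(300, seed = 20 + r))
    sp <- stratified_split(co, 0.5, seed = r)
    fit <- fit_forest(co[sp$training, ], ntree = 500, seed = r)
    holdout <- mean(predict(fit, co[sp$validation, ]) !=
      co$diagnosis[sp$validation])
    abs(oob_error(fit)$overall - holdout)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)

  co <- generate_cohort(dcd_spec_paperlike(100, seed = 21))
  oob <- oob_error(fit_forest(co, ntree = 300, seed = 3))
  expect_equal(
    oob$overall,
    sum(oob$per_class$n_misclassified) / sum(oob$per_class$n)
  )

  # perfectly separable data: OOB error 0
  sep <- make_cohort(
    cbind(rep(c(0L, 1L), each = 10), rep(c(1L, 0L), each = 10)),
    rep(c("IM", "VSC"), each = 10)
  )
  expect_equal(oob_error(fit_forest(sep, ntree = 200, seed = 1))$overall, 0)
})

test_that("permutation importance isolates predictive items", {
  # an item never used by any tree has exactly zero importance
  co <- make_cohort(
    cbind(rep(c(0L, 1L), each = 8), rep(1L, 16)),
    rep(c("IM", "VSC"), each = 8),
    items = c("GOOD", "CONS")
  )
  fit <- fit_forest(co, mtry = 2, ntree = 50, seed = 4)
  imp <- permutation_importance(fit, seed = 1)$overall
  expect_equal(imp$importance[imp$item == "CONS"], 0)
  # the perfectly predictive item is strictly positive and maximal
  expect_gt(imp$importance[imp$item == "GOOD"], 0)
  expect_equal(which.max(imp$importance), which(imp$item == "GOOD"))

  # pure-noise items on a null cohort: importances centred at zero
  co0 <- generate_cohort(null_spec(63, p = 20, seed = 5))
  fit0 <- fit_forest(co0, ntree = 200, seed = 5)
  imp0 <- permutation_importance(fit0, seed = 5)$overall
  expect_lt(mean(abs(imp0$importance)), 0.02)
})

test_that("per-class importance has one row per class", {
  co <- generate_cohort(dcd_spec_paperlike(63, seed = 6))
  fit <- fit_forest(co, ntree = 100, seed = 6)
  imp <- permutation_importance(fit, seed = 6)
  expect_equal(rownames(imp$per_class), c("IM", "VSC", "MX"))
  expect_equal(colnames(imp$per_class), dcd_item_codes())
})

test_that("proximity is a unit-diagonal similarity with expected extremes", {
  co <- generate_cohort(dcd_spec_paperlike(30, seed = 7))
  fit <- fit_forest(co, ntree = 100, seed = 7)
  # duplicate a subject: identical rows share every terminal node
  X <- cohort_matrix_of(co)
  X2 <- rbind(X, X[1, , drop = FALSE])
  prox <- proximity_matrix(fit, X2)
  expect_equal(prox[1, 31], 1)
  expect_true(all(diag(prox) == 1))
  expect_equal(prox, t(prox))
  expect_true(all(prox >= 0 & prox <= 1))

  # single-leaf forest: everything maximally proximate
  cst <- make_cohort(matrix(1L, 6, 2), rep(c("IM", "VSC"), 3))
  fitc <- fit_forest(cst, ntree = 10, seed = 1)
  expect_true(all(proximity_matrix(fitc) == 1))
})

test_that("training accuracy dominates OOB accuracy across replicates", {
  wins <- 0
  for (r in 1:100) {
    co <- generate_cohort(dcd_spec_paperlike(40 + (r %% 3), seed = 300 + r))
    fit <- fit_forest(co, ntree = 60, seed = r)
    train_acc <- mean(predict(fit) == co$diagnosis)
    oob_acc <- 1 - oob_error(fit)$overall
    if (train_acc >= oob_acc) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("OOB error agrees with the reference forest implementation", {
  skip_if_not_installed("randomForest")
  co <- generate_cohort(dcd_spec_paperlike(100, seed = 8))
  fit <- fit_forest(co, mtry = 7, ntree = 500, seed = 8)
  X <- as.data.frame(lapply(
    as.data.frame(cohort_matrix_of(co)), factor,
    levels = 0:1
  ))
  set.seed(8)
  ref <- randomForest::randomForest(X, co$diagnosis, mtry = 7, ntree = 500)
  ref_err <- mean(ref$predicted != co$diagnosis)
  expect_lt(abs(oob_error(fit)$overall - ref_err), 0.05)
})

test_that("classical MDS reproduces embeddable geometry", {
  # identity-like proximity on 3 points: an equilateral configuration
  prox <- diag(3)
  emb <- mds_embed(prox, k = 2)
  d <- dist(emb$points)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-9)

  # Euclidean-embeddable dissimilarity is reproduced exactly at k = n - 1
  set.seed(41)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  D <- D / max(D) # dissimilarity in [0, 1] so 1 - D is a similarity
  emb2 <- mds_embed(1 - D, k = 5)
  expect_equal(as.matrix(dist(emb2$points)), D, tolerance = 1e-8)

  # Gower projection of the original points recovers their coordinates
  proj <- mds_project(emb2, D^2)
  expect_equal(proj, unname(emb2$points), tolerance = 1e-6)

  # agrees with the stats oracle up to sign
  ref <- cmdscale(as.dist(D), k = 2)
  expect_equal(abs(emb2$points[, 1:2]), abs(ref), tolerance = 1e-8,
    ignore_attr = TRUE
  )

  # sign convention: the largest-magnitude coordinate is positive
  expect_true(all(apply(emb2$points, 2, function(c) c[which.max(abs(c))] >= 0)))

  # all-equal proximities degrade to zero coordinates with a warning
  expect_warning(emb0 <- mds_embed(matrix(1, 4, 4), k = 2), "equal")
  expect_true(emb0$degenerate)
  expect_true(all(emb0$points == 0))
})

test_that("MDS of forest proximities separates synthetic classes", {
  co <- generate_cohort(dcd_spec_paperlike(80, seed = 9))
  fit <- fit_forest(co, ntree = 300, seed = 9)
  emb <- mds_embed(proximity_matrix(fit), k = 2)
  sil <- silhouette_widths(emb$points, as.integer(co$diagnosis))
  expect_gt(sil$asw, 0.3)
})
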