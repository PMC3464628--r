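test_that("dummy coding builds a proper indicator matrix", {
  Z <- dummy_code(factor(c("IM", "VSC", "MX"), levels = c("IM", "VSC", "MX")))
  expect_equal(unname(Z), diag(3), ignore_attr = TRUE)

  co <- generate_cohort(dcd_spec_paperlike(63, seed = 1))
  Z2 <- dummy_code(co$diagnosis)
  expect_true(all(rowSums(Z2) == 1))
  expect_equal(unname(colSums(Z2)), c(5, 33, 25))
})

test_that("full-rank PLS with maximal K reproduces least squares", {
  set.seed(11)
  X <- matrix(rbinom(18, 1, 0.5), 6, 3)
  while (qr(scale(X, scale = FALSE))$rank < 3) X <- matrix(rbinom(18, 1, 0.5), 6, 3)
  y <- factor(c("IM", "IM", "VSC", "VSC", "MX", "MX"), levels = c("IM", "VSC", "MX"))
  co <- make_cohort(X, as.character(y))
  fit <- fit_plsda(co, K = 3)
  raw <- sweep(X %*% fit$coefficients, 2, fit$intercepts, "+")
  Z <- dummy_code(y)
  ols <- lm.fit(cbind(1, X), Z) # normal-equations oracle
  expect_equal(unname(raw), unname(cbind(1, X) %*% ols$coefficients),
    tolerance = 1e-8
  )
})

test_that("the first weight vector has the known closed form", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  core <- dcdtype:::fit_pls_core(X, matrix(y, 10, 1), K = 1)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  w_ref <- drop(crossprod(Xc, yc))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(drop(core$W), w_ref * sign(sum(core$W * w_ref)), tolerance = 1e-10)
})

test_that("the first component matches the covariance eigen-oracle", {
  co <- generate_cohort(dcd_spec_paperlike(40, seed = 13))
  fit <- fit_plsda(co, K = 2)
  X <- scale(cohort_matrix_of(co), scale = FALSE)
  Z <- scale(dummy_code(co$diagnosis), scale = FALSE)
  M <- crossprod(X, Z) %*% crossprod(Z, X)
  w_ref <- eigen(M, symmetric = TRUE)$vectors[, 1]
  agree <- abs(sum(fit$W[, 1] * w_ref))
  expect_equal(agree, 1, tolerance = 1e-6)
})

test_that("component scores are mutually orthogonal", {
  co <- generate_cohort(dcd_spec_paperlike(63, seed = 14))
  fit <- fit_plsda(co, K = 6)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_true(all(abs(colSums(fit$W^2) - 1) < 1e-10))
})

test_that("soft thresholding shrinks, selects and renormalises", {
  w <- c(1, 0.1, 0.1)
  expect_equal(soft_threshold_weights(w, 0), w / sqrt(sum(w^2)))
  expect_equal(soft_threshold_weights(w, 0.5), c(1, 0, 0))
  expect_equal(soft_threshold_weights(rep(0, 3), 0.7), rep(0, 3))

  set.seed(15)
  for (r in 1:5) {
    v <- rnorm(20)
    supports <- vapply(seq(0, 0.95, by = 0.05), function(eta) {
      sum(soft_threshold_weights(v, eta) != 0)
    }, numeric(1))
    expect_true(all(diff(supports) <= 0)) # support shrinks monotonically
  }
})

test_that("eta = 0 sparse fit coincides with the unpenalised fit", {
  co <- generate_cohort(dcd_spec_paperlike(50, seed = 16))
  a <- fit_plsda(co, K = 3)
  b <- fit_splsda(co, K = 3, eta = 0)
  expect_equal(a$W, b$W, tolerance = 1e-8)
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-8)
})

test_that("extreme sparsity keeps a single item per component", {
  co <- generate_cohort(dcd_spec_paperlike(80, seed = 17))
  fit <- fit_splsda(co, K = 2, eta = 0.98)
  expect_true(all(colSums(fit$W != 0) == 1))
})

test_that("strong planted signal is recovered with few false positives", {
  spec <- dcd_spec_paperlike(200, seed = 18)
  co <- generate_cohort(spec)
  fit <- fit_splsda(co, K = 2, eta = 0.7)
  expect_true(all(spec$planted_items %in% fit$selected_items))
  expect_lte(length(setdiff(fit$selected_items, spec$planted_items)), 3)
})

test_that("softmax prediction lives on the simplex and breaks ties by order", {
  co <- generate_cohort(dcd_spec_paperlike(63, seed = 19))
  fit <- fit_plsda(co, K = 4)
  pr <- predict_softmax(fit)
  expect_equal(unname(rowSums(as.matrix(pr$probabilities))), rep(1, 63))
  expect_true(all(as.matrix(pr$probabilities) >= 0))

  # argmax of the raw scores is preserved by the softmax transform
  raw <- sweep(
    sweep(cohort_matrix_of(co) %*% fit$coefficients, 2, fit$intercepts, "+"),
    2, 0
  )
  expect_equal(
    as.integer(pr$class),
    apply(raw, 1, function(r) which(r == max(r))[1])
  )
  # linear rescaling picks the same classes when raw scores are distinct
  expect_equal(pr$class, predict_softmax(fit, transform = "linear")$class)

  # degenerate model: equal raw scores everywhere -> first class, weights 1/C
  stub <- fit
  stub$coefficients[] <- 0
  stub$intercepts[] <- 0.5
  pr0 <- predict_softmax(stub)
  expect_true(all(pr0$class == "IM"))
  expect_true(all(abs(as.matrix(pr0$probabilities) - 1 / 3) < 1e-12))
})

test_that("a separable cohort is classified perfectly in training", {
  X <- rbind(
    matrix(c(1L, 0L, 0L), 4, 3, byrow = TRUE),
    matrix(c(0L, 1L, 0L), 4, 3, byrow = TRUE),
    matrix(c(0L, 0L, 1L), 4, 3, byrow = TRUE)
  )
  co <- make_cohort(X, rep(c("IM", "VSC", "MX"), each = 4))
  fit <- fit_plsda(co, K = 2)
  expect_equal(mean(predict(fit) == co$diagnosis), 1)
})

test_that("loading importances follow the documented conventions", {
  co <- generate_cohort(dcd_spec_paperlike(100, seed = 20))
  fit <- fit_splsda(co, K = 2, eta = 0.7)
  li <- loadings_importance(fit)
  # per-component importance is |u_k|
  c1 <- li$per_component[li$per_component$component == "C1", ]
  expect_equal(c1$loading, unname(abs(fit$W[, 1])))
  # only selected items carry nonzero entries
  zero_items <- setdiff(fit$items, fit$selected_items)
  expect_true(all(li$per_class$importance[li$per_class$item %in% zero_items] == 0))
  # class columns are rescaled to a maximum of 1
  mx <- tapply(li$per_class$importance, li$per_class$class, max)
  expect_true(all(abs(mx - 1) < 1e-12))
})

test_that("single-component ranking equals the weight ranking", {
  co <- generate_cohort(dcd_spec_paperlike(63, seed = 22))
  fit <- fit_plsda(co, K = 1)
  li <- loadings_importance(fit)$per_component
  expect_equal(order(li$loading), order(abs(fit$W[, 1])))
})

test_that("bootstrap CIs straddle zero for null items and pin constants", {
  set.seed(23)
  straddle <- 0
  for (r in 1:10) {
    co <- generate_cohort(null_spec(40, p = 6, seed = 100 + r))
    ci <- bootstrap_coefficient_ci(co, K = 2, eta = 0, B = 100, seed = r)
    row <- ci[ci$item == "I01" & ci$class == "IM", ]
    if (row$lower <= 0 && row$upper >= 0) straddle <- straddle + 1
  }
  expect_gte(straddle, 9)

  # a constant item has coefficient 0 with a [0, 0] interval
  co <- generate_cohort(dcd_spec_paperlike(40, seed = 24))
  co$SITA <- 1L
  ci <- bootstrap_coefficient_ci(co, K = 2, eta = 0.5, B = 100, seed = 1)
  cst <- ci[ci$item == "SITA", ]
  expect_true(all(cst$estimate == 0 & cst$lower == 0 & cst$upper == 0))
  expect_true(all(ci$lower <= ci$upper))
})

test_that("percentile bounds stabilise as B grows", {
  co <- generate_cohort(dcd_spec_paperlike(80, seed = 25))
  ci_small <- bootstrap_coefficient_ci(co, K = 2, eta = 0.7, B = 100, seed = 2)
  ci_big <- bootstrap_coefficient_ci(co, K = 2, eta = 0.7, B = 1000, seed = 2)
  j <- ci_big$item == "IMOG"
  coef_sd <- (ci_big$upper[j] - ci_big$lower[j]) / (2 * 1.96)
  # Monte-Carlo error of a 2.5% percentile at B = 100 is about
  # sqrt(.025*.975/100) / dnorm(qnorm(.025)) ~= 0.27 sd; allow 3 of those
  expect_true(all(abs(ci_small$lower[j] - ci_big$lower[j]) < 0.8 * coef_sd))
  expect_true(all(abs(ci_small$upper[j] - ci_big$upper[j]) < 0.8 * coef_sd))
})

test_that("exhausted deflation returns fewer components than requested", {
  X <- cbind(rep(c(0L, 1L), 4), rep(c(0L, 1L), 4)) # rank-1 item block
  co <- make_cohort(X, rep(c("IM", "VSC"), 4))
  fit <- fit_plsda(co, K = 2)
  expect_lt(fit$K_actual, 2)
  expect_equal(ncol(fit$W), fit$K_actual)
})
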