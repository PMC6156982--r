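sim_tree_data <- function(n = 400, p = 6, signal = 2, seed = 1) {
  set.seed(seed)
  X <- as.data.frame(matrix(rnorm(n * p), n, p,
                            dimnames = list(NULL, paste0("x", 1:p))))
  y <- signal * X$x1 + 0.5 * signal * X$x2 + rnorm(n)
  list(X = X, y = y)
}

test_that("every leaf respects the minimum leaf size", {
  d <- sim_tree_data(n = 500, seed = 2)
  for (ml in c(5, 10, 40)) {
    fit <- fit_regression_tree(d$X, d$y, min_leaf = ml)
    leaf_sizes <- fit$tree$n[fit$tree$var < 0]
    expect_gte(min(leaf_sizes), ml)
  }
  expect_error(fit_regression_tree(d$X, d$y, min_leaf = 1), "at least 2")
})

test_that("a response equal to one feature gives that feature importance 1", {
  d <- sim_tree_data(seed = 3)
  fit <- fit_regression_tree(d$X, d$X$x3, min_leaf = 5)
  imp <- fit$importance
  expect_equal(imp$score[imp$predictor == "x3"], 1)
  expect_equal(imp$rank[imp$predictor == "x3"], 1L)
  expect_lt(max(imp$score[imp$predictor != "x3"]), 0.01)
})

test_that("a constant response yields a single leaf with zero importances", {
  d <- sim_tree_data(seed = 4)
  fit <- fit_regression_tree(d$X, rep(1.5, nrow(d$X)), min_leaf = 10)
  expect_equal(length(fit$tree$var), 1L)
  expect_equal(fit$tree$var[1], -1L)
  expect_true(all(fit$importance$raw == 0))
  expect_equal(sort(fit$importance$rank), seq_len(ncol(d$X)))
})

test_that("pure-noise responses do not fabricate validation importance", {
  set.seed(6)
  X <- as.data.frame(matrix(rnorm(500 * 6), 500, 6,
                            dimnames = list(NULL, paste0("x", 1:6))))
  y <- rnorm(500)
  fit <- fit_regression_tree(X, y, min_leaf = 10,
                             partition = c(0.4, 0.3, 0.3), seed = 7)
  val <- dplyr::filter(fit$importance, partition == "validation")
  train <- dplyr::filter(fit$importance, partition == "training")
  # validation impurity reduction collapses relative to training
  expect_lt(max(val$raw) / max(train$raw), 0.2)
})

test_that("training MSE is non-increasing as min_leaf shrinks", {
  d <- sim_tree_data(n = 300, seed = 8)
  mse <- vapply(c(80, 40, 20, 10, 5), function(ml) {
    fit <- fit_regression_tree(d$X, d$y, min_leaf = ml, seed = 9)
    mean((predict(fit, d$X) - d$y)^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 1e-9))
})

test_that("a one-tree forest without bootstrap equals the single tree", {
  d <- sim_tree_data(seed = 10)
  tree <- fit_regression_tree(d$X, d$y, min_leaf = 10, seed = 123)
  forest <- fit_random_forest(d$X, d$y, n_trees = 1, bootstrap = FALSE,
                              mtry = ncol(d$X), min_leaf = 10, seed = 99)
  expect_equal(forest$importance$raw, tree$importance$raw)
  expect_equal(forest$importance$rank, tree$importance$rank)
  expect_equal(predict(forest, d$X), predict(tree, d$X))
})

test_that("forests are deterministic and conserve total impurity reduction", {
  d <- sim_tree_data(seed = 11)
  f1 <- fit_random_forest(d$X, d$y, n_trees = 60, seed = 5)
  f2 <- fit_random_forest(d$X, d$y, n_trees = 60, seed = 5)
  expect_identical(f1$importance, f2$importance)
  f3 <- fit_random_forest(d$X, d$y, n_trees = 60, seed = 6)
  expect_false(identical(f1$importance$raw, f3$importance$raw))
  # per-feature importances account for every split's gain
  expect_lt(abs(sum(f1$per_tree) - f1$total_gain), 1e-9)
  expect_equal(sum(colMeans(f1$per_tree)), sum(f1$importance$raw),
               tolerance = 1e-12)
})

test_that("forest importance agrees with an independent implementation", {
  library(ranger)
  d <- sim_tree_data(n = 500, p = 8, seed = 12)
  ours <- fit_random_forest(d$X, d$y, n_trees = 300, seed = 13)
  theirs <- ranger::ranger(y = d$y, x = d$X, num.trees = 300,
                           importance = "impurity", seed = 13,
                           num.threads = 1)
  ref <- theirs$variable.importance
  ref <- ref[ours$importance$predictor]
  expect_gt(cor(ours$importance$raw, ref, method = "spearman"), 0.9)
  expect_equal(ours$importance$predictor[ours$importance$rank == 1],
               names(which.max(ref)))
})

test_that("importance ranks stabilize as the forest grows", {
  # three correlated-strength predictors among noise: with few trees their
  # ranks shuffle between seeds; with many trees the ordering settles
  set.seed(14)
  n <- 250
  X <- as.data.frame(matrix(rnorm(n * 8), n, 8,
                            dimnames = list(NULL, paste0("x", 1:8))))
  y <- 0.5 * X$x1 + 0.3 * X$x2 + 0.25 * X$x3 + 0.2 * X$x4 + rnorm(n)
  ranks_at <- function(n_trees) {
    vapply(1:10, function(s) {
      fit <- fit_random_forest(X, y, n_trees = n_trees, seed = 100 + s)
      fit$importance$rank[fit$importance$predictor %in%
                            c("x2", "x3", "x4")]
    }, integer(3))
  }
  spread <- vapply(c(10, 50, 600), function(nt) {
    r <- ranks_at(nt)
    mean(apply(r, 1, var))
  }, numeric(1))
  expect_lte(spread[3], spread[2])
  expect_lte(spread[2], spread[1])
  expect_lt(spread[3], spread[1])
})

test_that("forest rank summaries aggregate replicate tables", {
  t1 <- tibble::tibble(predictor = c("a", "b"), score = c(1, 0.5),
                       raw = c(2, 1), rank = c(1L, 2L),
                       partition = "full", model = "forest")
  t2 <- dplyr::mutate(t1, rank = c(3L, 1L))
  same <- summarize_forest_ranks(list(t1, t1))
  expect_equal(same$sd_rank, c(0, 0))
  mix <- summarize_forest_ranks(list(t1, t2))
  a <- mix[mix$predictor == "a", ]
  expect_equal(a$mean_rank, 2)
  expect_equal(a$median_rank, 2)
  expect_error(summarize_forest_ranks(list(t1)), "two replicate")
  t3 <- dplyr::mutate(t1, predictor = c("a", "zz"))
  expect_error(summarize_forest_ranks(list(t1, t3)), "same predictor")
})
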