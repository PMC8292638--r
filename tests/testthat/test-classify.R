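# Split construction, standardization, KNN, SVM, cross-validation.

make_labels <- function(n_vte, n_non) {
  data.frame(trial_id = seq_len(n_vte + n_non),
             consensus = rep(c("VTE", "nonVTE"), c(n_vte, n_non)))
}

test_that("split columns are balanced, reproducible, and correctly sized", {
  sm <- build_split_matrix(make_labels(20, 80), n_splits = 25, seed = 3)
  vte_ids <- 1:20
  for (j in 1:25) {
    col <- sm$trials[, j]
    expect_length(col, 40L)
    expect_setequal(intersect(col, vte_ids), vte_ids)  # every VTE, once
    expect_equal(sum(col > 20), 20L)                   # equal non-VTE count
    expect_false(anyDuplicated(col) > 0)
  }
  sm2 <- build_split_matrix(make_labels(20, 80), n_splits = 25, seed = 3)
  expect_identical(sm$trials, sm2$trials)
  sm3 <- build_split_matrix(make_labels(20, 80), n_splits = 25, seed = 4)
  expect_false(identical(sm$trials, sm3$trials))
  expect_error(build_split_matrix(make_labels(30, 10)), "at least as many")
})

test_that("train/test boundary is floor(0.67 n) and splits are disjoint", {
  sm <- build_split_matrix(make_labels(21, 60), n_splits = 5)
  expect_identical(sm$n_train, 28L)
  col <- sm$trials[, 1]
  expect_length(intersect(col[seq_len(sm$n_train)],
                          col[(sm$n_train + 1):length(col)]), 0L)
})

test_that("standardization transforms test data with training parameters", {
  set.seed(6)
  tr <- matrix(rnorm(200, 5, 2), ncol = 2,
               dimnames = list(NULL, c("a", "b")))
  sc <- standardize(tr, tr)
  expect_equal(colMeans(sc$train), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(sc$train, 2, function(v) sqrt(mean(v^2))),
               c(a = 1, b = 1), tolerance = 1e-12)
  shifted <- tr + 10
  sc2 <- standardize(tr, shifted)
  expect_equal(colMeans(sc2$test), 10 / sc2$scale, tolerance = 1e-10)
  const <- cbind(tr, c = 7)
  expect_warning(sc3 <- standardize(const), "zero-spread")
  expect_identical(colnames(sc3$train), c("a", "b"))
})

test_that("KNN scores are neighbor-vote fractions", {
  X <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  y <- rep(c("VTE", "nonVTE"), each = 5)
  m <- train_knn(X, y, k = 5)
  expect_equal(predict(m, matrix(0, 1, 2)), 1)
  expect_equal(predict(m, matrix(10, 1, 2)), 0)
  # 3 VTE + 2 nonVTE among the 5 nearest
  X2 <- rbind(matrix(0, 3, 2), matrix(0.1, 2, 2), matrix(50, 5, 2))
  y2 <- rep(c("VTE", "nonVTE", "nonVTE"), c(3, 2, 5))
  expect_equal(predict(train_knn(X2, y2, k = 5), matrix(0, 1, 2)), 0.6)
  m1 <- train_knn(matrix(c(0, 0, 1, 1), 2, byrow = TRUE),
                  c("VTE", "nonVTE"), k = 1)
  expect_equal(predict(m1, matrix(c(0.1, 0.1), 1)), 1)
  expect_error(train_knn(X, y, k = 11), "exceeds")
})

test_that("the RBF SVM separates what a linear threshold cannot", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60, 2, 0.5), ncol = 2),
             matrix(rnorm(60, -2, 0.5), ncol = 2))
  y <- rep(c("VTE", "nonVTE"), each = 30)
  m <- train_svm(X, y, gamma = 0.5, cost = 1)
  expect_equal(mean(ifelse(predict(m, X) > 0, "VTE", "nonVTE") == y), 1)

  xor_x <- rbind(matrix(rnorm(40, 2, 0.3), 20), matrix(rnorm(40, -2, 0.3), 20),
                 cbind(rnorm(20, 2, 0.3), rnorm(20, -2, 0.3)),
                 cbind(rnorm(20, -2, 0.3), rnorm(20, 2, 0.3)))
  xor_y <- rep(c("VTE", "nonVTE"), each = 40)
  mx <- train_svm(xor_x, xor_y, gamma = 1, cost = 10)
  expect_equal(mean(ifelse(predict(mx, xor_x) > 0, "VTE", "nonVTE") == xor_y), 1)
  # no threshold on a single feature can reach that accuracy
  best_lin <- max(vapply(1:2, function(j) {
    s <- xor_x[, j]
    max(vapply(sort(s), function(th)
      max(mean((s > th) == (xor_y == "VTE")),
          mean((s <= th) == (xor_y == "VTE"))), numeric(1)))
  }, numeric(1)))
  expect_lt(best_lin, 0.8)
  expect_error(train_svm(X, rep("VTE", 60), gamma = 1, cost = 1), "classes")
})

test_that("raising C never lowers training accuracy on a noisy fixture", {
  set.seed(14)
  X <- rbind(matrix(rnorm(80, 1), ncol = 2), matrix(rnorm(80, -1), ncol = 2))
  y <- rep(c("VTE", "nonVTE"), each = 40)
  accs <- vapply(c(0.1, 1, 10), function(C) {
    m <- train_svm(X, y, gamma = 0.5, cost = C)
    mean(ifelse(predict(m, X) > 0, "VTE", "nonVTE") == y)
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))
})

test_that("the hyperparameter grid enumerates 361 pairs with the tie rule", {
  g <- svm_grid()
  expect_length(g$gammas, 19L)
  expect_length(g$costs, 19L)
  expect_identical(length(g$gammas) * length(g$costs), 361L)
  # trivially separable data ties every pair -> smallest C, then smallest gamma
  set.seed(15)
  X <- rbind(matrix(rnorm(40, 5, 0.1), ncol = 2),
             matrix(rnorm(40, -5, 0.1), ncol = 2))
  y <- rep(c("VTE", "nonVTE"), each = 20)
  small <- list(gammas = c(0.01, 0.1, 1), costs = c(0.1, 1, 10))
  gs <- grid_search_svm(X, y, grid = small, seed = 1)
  expect_equal(gs$cost, 0.1)
  expect_equal(gs$gamma, 0.01)
  expect_equal(gs$auc, 1)
})

test_that("cross-validation is deterministic and leak-free by design", {
  ft <- simulate_gaussian_features(30, 5, effect = 2, seed = 2)
  sm <- build_split_matrix(ft, n_splits = 15, seed = 1)
  a <- run_cv(ft, sm, model = "knn")
  b <- run_cv(ft, sm, model = "knn")
  expect_identical(lapply(a, `[[`, "scores"), lapply(b, `[[`, "scores"))
  # strong separation -> high test AUC
  expect_gte(mean(evaluate_cv(a)$auc), 0.95)
  # paired design: another feature table on the same splits sees the same
  # test trials
  ft2 <- simulate_gaussian_features(30, 3, effect = 0, seed = 9)
  c2 <- run_cv(ft2, sm, model = "knn")
  expect_identical(lapply(a, `[[`, "trial_ids"), lapply(c2, `[[`, "trial_ids"))
})

test_that("shuffled training labels collapse performance to chance", {
  ft <- simulate_gaussian_features(40, 5, effect = 2, seed = 3)
  sm <- build_split_matrix(ft, n_splits = 40, seed = 1)
  base <- random_label_baseline(ft, sm, model = "knn", seed = 5)
  expect_equal(mean(evaluate_cv(base)$auc), 0.5, tolerance = 0.05)
  base2 <- random_label_baseline(ft, sm, model = "knn", seed = 5)
  expect_identical(lapply(base, `[[`, "scores"), lapply(base2, `[[`, "scores"))
})
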