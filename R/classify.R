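# Balanced seeded cross-validation and the two classifier models.
#
# Class balance: VTEs are ~20% of trials, so every split column contains
# every consensus-VTE trial plus an equal number of non-VTE trials sampled
# without replacement; the first 67% of the shuffled column trains, the rest
# tests.  The same seeded split matrix is reused for every model and feature
# modality so comparisons are paired split-by-split.
#
# No SVM implementation ships with this stack, so the soft-margin RBF SVM is
# implemented here with its dual quadratic program handed to quadprog;
# k-nearest-neighbors is implemented directly because its score is defined
# as the VTE-vote fraction among the k nearest training points.

#' Build the seeded matrix of balanced train/test splits
#'
#' @param labels Data frame with `trial_id` and `consensus` (from
#'   [curate_labels()]), or a `feature_table` (its `label` column is used).
#'   `"excluded"` trials are ignored.
#' @param n_splits Number of split columns (default 100).
#' @param seed RNG seed (default 1).
#' @param train_fraction Fraction of each column used for training
#'   (default 0.67; boundary at `floor(train_fraction * n)`).
#' @return A `split_matrix`: `trials` (n x n_splits matrix of trial ids,
#'   each column shuffled), `n_train`, plus the generating parameters.
#' @export
build_split_matrix <- function(labels, n_splits = 100, seed = 1,
                               train_fraction = 0.67) {
  if (inherits(labels, "feature_table"))
    labels <- data.frame(trial_id = labels$trial_id, consensus = labels$label)
  keep <- labels$consensus != "excluded"
  vte <- labels$trial_id[keep & labels$consensus == "VTE"]
  non <- labels$trial_id[keep & labels$consensus == "nonVTE"]
  if (length(non) < length(vte))
    stop("need at least as many non-VTE as VTE trials to balance")
  if (!length(vte)) stop("no VTE trials")
  n <- 2L * length(vte)
  cols <- with_seed(seed, {
    vapply(seq_len(n_splits), function(j)
      sample(c(vte, sample(non, length(vte)))), numeric(n))
  })
  structure(list(trials = cols, n_train = as.integer(floor(train_fraction * n)),
                 n_splits = n_splits, seed = seed,
                 train_fraction = train_fraction),
            class = "split_matrix")
}

#' @export
print.split_matrix <- function(x, ...) {
  cat(sprintf("<split_matrix> %d balanced trials x %d splits (%d train / %d test), seed %d\n",
              nrow(x$trials), x$n_splits, x$n_train,
              nrow(x$trials) - x$n_train, x$seed))
  invisible(x)
}

#' Standardize features on training statistics
#'
#' Training columns are centered and scaled to mean 0 / SD 1; test columns
#' are transformed with the training parameters (never their own), so no
#' test information leaks into the scaling.  Zero-spread training features
#' are dropped with a warning.
#'
#' @param train,test Numeric matrices (rows = trials).
#' @return List with scaled `train` and `test`, the `center` and `scale`
#'   used, and `dropped` feature names.
#' @export
standardize <- function(train, test = NULL) {
  train <- as.matrix(train)
  center <- colMeans(train)
  scl <- apply(train, 2, pop_sd)
  dead <- scl == 0
  if (any(dead)) {
    warning("dropping zero-spread features: ",
            paste(colnames(train)[dead], collapse = ", "))
    train <- train[, !dead, drop = FALSE]
    center <- center[!dead]; scl <- scl[!dead]
  }
  tr <- sweep(sweep(train, 2, center), 2, scl, "/")
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)[, colnames(train), drop = FALSE]
    te <- sweep(sweep(test, 2, center), 2, scl, "/")
  }
  list(train = tr, test = te, center = center, scale = scl,
       dropped = names(dead)[dead])
}

# ------------------------------------------------------------------- KNN --

#' Train a k-nearest-neighbors VTE classifier
#'
#' The model scores a query as the fraction of its k nearest training
#' neighbors (Euclidean distance on standardized features) labeled VTE, so
#' a continuous ROC-able score exists.
#'
#' @param features Numeric training matrix (standardized).
#' @param labels `"VTE"`/`"nonVTE"` training labels.
#' @param k Number of neighbors (default 5).
#' @return A `vte_knn` model.
#' @export
train_knn <- function(features, labels, k = 5) {
  features <- as.matrix(features)
  if (k > nrow(features)) stop("k exceeds the number of training points")
  structure(list(X = features, y = as.character(labels), k = k),
            class = "vte_knn")
}

#' @export
#' @rdname train_knn
#' @param object A `vte_knn` model.
#' @param newdata Numeric query matrix.
#' @param ... Unused.
predict.vte_knn <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  # squared Euclidean distances, vectorized
  d2 <- outer(rowSums(newdata^2), rowSums(object$X^2), "+") -
    2 * newdata %*% t(object$X)
  apply(d2, 1, function(row) {
    nb <- order(row)[seq_len(object$k)]
    mean(object$y[nb] == "VTE")
  })
}

# ------------------------------------------------------------------- SVM --

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

#' Train a soft-margin RBF-kernel support vector machine
#'
#' Maximal-margin classifier with a radial basis function kernel
#' `K(u, v) = exp(-gamma * ||u - v||^2)`; `gamma` sets the kernel width
#' (higher = narrower) and `cost` the margin/accuracy trade-off (higher =
#' more complex decision function).  The dual quadratic program is solved
#' with `quadprog::solve.QP`.  The model exposes a continuous decision
#' score (signed distance from the separating surface; positive = VTE).
#'
#' @param features Numeric training matrix (standardized).
#' @param labels `"VTE"`/`"nonVTE"` training labels (both classes required).
#' @param gamma RBF kernel width parameter.
#' @param cost Soft-margin penalty C.
#' @return A `vte_svm` model.
#' @export
train_svm <- function(features, labels, gamma = 0.1, cost = 1) {
  X <- as.matrix(features)
  yy <- ifelse(as.character(labels) == "VTE", 1, -1)
  if (length(unique(yy)) < 2L) stop("both classes required to train an SVM")
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  D <- (yy %o% yy) * K
  diag(D) <- diag(D) + 1e-8          # ridge for numerical positive-definiteness
  A <- cbind(yy, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-8
  coef <- alpha * yy
  # intercept from margin vectors (0 < alpha < C); fall back to KKT bounds
  on_margin <- sv & alpha < cost - 1e-8
  f_no_b <- as.numeric(K %*% coef)
  if (any(on_margin)) {
    b <- mean(yy[on_margin] - f_no_b[on_margin])
  } else {
    up <- min(yy[yy == 1] - f_no_b[yy == 1])
    lo <- max(yy[yy == -1] - f_no_b[yy == -1])
    b <- (up + lo) / 2
  }
  structure(list(X = X[sv, , drop = FALSE], coef = coef[sv], b = b,
                 gamma = gamma, cost = cost, n_sv = sum(sv)),
            class = "vte_svm")
}

#' @export
#' @rdname train_svm
#' @param object A `vte_svm` model.
#' @param newdata Numeric query matrix.
#' @param ... Unused.
predict.vte_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(rbf_kernel(newdata, object$X, object$gamma) %*% object$coef +
               object$b)
}

#' The SVM hyperparameter grid
#'
#' Gamma from 0.01 to 0.1 in steps of 0.01 and 0.2 to 1 in steps of 0.1;
#' C from 0.1 to 1 in steps of 0.1 and 2 to 10 in steps of 1: 19 x 19 = 361
#' pairs.
#'
#' @return List with `gammas` and `costs`.
#' @export
svm_grid <- function() {
  list(gammas = c(seq(0.01, 0.10, by = 0.01), seq(0.2, 1.0, by = 0.1)),
       costs = c(seq(0.1, 1.0, by = 0.1), seq(2, 10, by = 1)))
}

#' Grid-search SVM hyperparameters by internal cross-validated AUC
#'
#' Evaluates every (gamma, C) pair of the grid by k-fold cross-validation
#' on the training data only (nothing from the test portion enters the
#' selection) and returns the pair maximizing mean AUC; ties break to the
#' smallest C, then the smallest gamma.
#'
#' @param features Numeric training matrix (standardized).
#' @param labels Training labels.
#' @param grid A grid from [svm_grid()].
#' @param folds Number of internal folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `gamma`, `cost`, and the selection `auc`.
#' @export
grid_search_svm <- function(features, labels, grid = svm_grid(), folds = 5,
                            seed = 0) {
  X <- as.matrix(features)
  y <- as.character(labels)
  n <- nrow(X)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  pairs <- expand.grid(cost = sort(grid$costs), gamma = sort(grid$gammas))
  pairs <- pairs[order(pairs$cost, pairs$gamma), ]
  aucs <- vapply(seq_len(nrow(pairs)), function(i) {
    fold_aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
        return(NA_real_)
      m <- train_svm(X[tr, , drop = FALSE], y[tr],
                     gamma = pairs$gamma[i], cost = pairs$cost[i])
      roc_and_auc(predict(m, X[!tr, , drop = FALSE]), y[!tr])$auc
    }, numeric(1))
    mean(fold_aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which(aucs >= max(aucs) - 1e-12)[1]
  list(gamma = pairs$gamma[best], cost = pairs$cost[best], auc = aucs[best])
}

# ------------------------------------------------------------------- CV ---

# fit + score one split; labels can be overridden for the chance baseline
fit_score_split <- function(X_train, y_train, X_test, model, k, gamma, cost) {
  if (model == "knn") {
    m <- train_knn(X_train, y_train, k = k)
    scores <- predict(m, X_test)
    pred <- ifelse(scores >= 0.5, "VTE", "nonVTE")
  } else {
    m <- train_svm(X_train, y_train, gamma = gamma, cost = cost)
    scores <- predict(m, X_test)
    pred <- ifelse(scores > 0, "VTE", "nonVTE")
  }
  list(scores = scores, predicted = pred)
}

#' Run seeded balanced cross-validation
#'
#' For each split column: standardize on the training portion, optionally
#' select features on the training portion, fit the model, and score the
#' held-out test trials.  Reusing one `split_matrix` across configurations
#' makes every comparison paired split-by-split.  For `model = "svm"` with
#' `gamma`/`cost` unset, hyperparameters are grid-searched once on the first
#' split's training portion (internal CV, see [grid_search_svm()]) and
#' reused for all splits.
#'
#' @param features A [feature_table()] covering every trial in `splits`.
#' @param splits A [build_split_matrix()] result.
#' @param model `"knn"` or `"svm"`.
#' @param k Neighbors for KNN (default 5).
#' @param gamma,cost SVM hyperparameters; `NULL` triggers the grid search.
#' @param grid Grid for the search (default [svm_grid()]).
#' @param feature_selector Optional `function(train_table)` returning the
#'   feature names to use (e.g. wrapping [select_psd_features()]); called on
#'   training data only, per split.
#' @param shuffle_labels Replace each split's training labels with balanced
#'   random labels (the chance baseline); use
#'   [random_label_baseline()] instead of setting this directly.
#' @param seed Seed for the internal grid-search folds and any label
#'   shuffling.
#' @return A `cv_predictions` list of per-split prediction sets
#'   (`split_id`, `trial_ids`, `scores`, `predicted`, `truth`), with the
#'   chosen hyperparameters in `attr(, "config")`.
#' @export
run_cv <- function(features, splits, model = c("knn", "svm"), k = 5,
                   gamma = NULL, cost = NULL, grid = svm_grid(),
                   feature_selector = NULL, shuffle_labels = FALSE,
                   seed = 0) {
  model <- match.arg(model)
  ids_all <- splits$trials
  missing_ids <- setdiff(as.vector(ids_all), features$trial_id)
  if (length(missing_ids))
    stop("features missing for trials: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  fnames <- feature_names(features)
  rows <- match(as.vector(ids_all), features$trial_id)
  labs <- features$label[rows]
  dim(labs) <- dim(ids_all)
  n_train <- splits$n_train

  # hyperparameters chosen once per feature table, leak-free
  if (model == "svm" && (is.null(gamma) || is.null(cost))) {
    tr1 <- match(ids_all[seq_len(n_train), 1], features$trial_id)
    sel1 <- if (is.null(feature_selector)) fnames
            else feature_selector(features[tr1, , drop = FALSE])
    sc1 <- standardize(as.matrix(features[tr1, sel1, drop = FALSE]))
    gs <- grid_search_svm(sc1$train, features$label[tr1], grid = grid,
                          seed = seed)
    gamma <- gs$gamma; cost <- gs$cost
  }

  shuffled_labels <- NULL
  if (shuffle_labels) {
    shuffled_labels <- with_seed(seed + 1L, {
      lapply(seq_len(splits$n_splits), function(j)
        sample(rep(c("VTE", "nonVTE"), length.out = n_train)))
    })
  }

  out <- lapply(seq_len(splits$n_splits), function(j) {
    col_ids <- ids_all[, j]
    tr_rows <- match(col_ids[seq_len(n_train)], features$trial_id)
    te_rows <- match(col_ids[(n_train + 1):length(col_ids)], features$trial_id)
    sel <- if (is.null(feature_selector)) fnames
           else feature_selector(features[tr_rows, , drop = FALSE])
    if (!length(sel)) stop("feature selector returned no features for split ", j)
    sc <- standardize(as.matrix(features[tr_rows, sel, drop = FALSE]),
                      as.matrix(features[te_rows, sel, drop = FALSE]))
    y_train <- if (shuffle_labels) shuffled_labels[[j]]
               else features$label[tr_rows]
    fs <- fit_score_split(sc$train, y_train, sc$test, model, k, gamma, cost)
    list(split_id = j,
         trial_ids = col_ids[(n_train + 1):length(col_ids)],
         scores = fs$scores, predicted = fs$predicted,
         truth = features$label[te_rows])
  })
  structure(out, class = "cv_predictions",
            config = list(model = model, k = k, gamma = gamma, cost = cost,
                          seed = seed, shuffled = shuffle_labels))
}

#' Chance reference: cross-validation with random training labels
#'
#' Identical pipeline to [run_cv()] but each split's training labels are
#' replaced by balanced uniform random labels, yielding the chance
#' distribution that the delta scores are measured against.
#'
#' @inheritParams run_cv
#' @param ... Passed to [run_cv()].
#' @return A `cv_predictions` object.
#' @export
random_label_baseline <- function(features, splits, model = c("knn", "svm"),
                                  seed = 0, ...) {
  run_cv(features, splits, model = model, shuffle_labels = TRUE,
         seed = seed, ...)
}
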