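# End-to-end experiments: simulate -> curate -> extract -> classify ->
# evaluate, all sharing one split matrix per run so that feature modalities
# and models are compared on identical test trials.

#' Two-point ROC area of hard predictions
#'
#' A thresholded binary predictor yields a single ROC point; its natural
#' area is `(TPR + TNR) / 2`, the balanced accuracy.
#'
#' @param predicted,truth `"VTE"`/`"nonVTE"` vectors.
#' @return Area in `[0, 1]`.
#' @export
two_point_area <- function(predicted, truth) {
  cc <- confusion_counts(predicted, truth)
  tpr <- cc$tp / (cc$tp + cc$fn)
  tnr <- cc$tn / (cc$tn + cc$fp)
  (tpr + tnr) / 2
}

#' Cross-validated zIdPhi threshold baseline
#'
#' For each split, the threshold is placed on the training portion only
#' (50th-80th percentile scan maximizing the two-point area, see
#' [zidphi_threshold_classifier()]) and applied to the held-out test trials.
#'
#' @param features A [feature_table()] containing a `zidphi` column.
#' @param splits A [build_split_matrix()] result.
#' @return A `cv_predictions` object (scores are the raw zIdPhi values;
#'   `area2` per split is in `attr(, "area2")`).
#' @export
zidphi_baseline_cv <- function(features, splits) {
  if (!"zidphi" %in% feature_names(features))
    stop("feature table has no zidphi column")
  n_train <- splits$n_train
  out <- lapply(seq_len(splits$n_splits), function(j) {
    col_ids <- splits$trials[, j]
    tr <- match(col_ids[seq_len(n_train)], features$trial_id)
    te <- match(col_ids[(n_train + 1):length(col_ids)], features$trial_id)
    fit <- zidphi_threshold_classifier(features$zidphi[tr], features$label[tr])
    z <- features$zidphi[te]
    list(split_id = j, trial_ids = col_ids[(n_train + 1):length(col_ids)],
         scores = z, predicted = ifelse(z > fit$threshold, "VTE", "nonVTE"),
         truth = features$label[te])
  })
  structure(out, class = "cv_predictions",
            config = list(model = "zidphi_threshold"),
            area2 = vapply(out, function(ps)
              two_point_area(ps$predicted, ps$truth), numeric(1)))
}

# light checksum so reports can assert they came from the same configuration
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% .Machine$integer.max)
}

#' Run one named experiment on a simulated session
#'
#' Simulates a session, curates labels (rater consensus plus 4 SD noise
#' exclusion on the analyzed epoch), extracts the experiment's feature set,
#' and evaluates the classifier against its random-label baseline on a
#' shared seeded split matrix.
#'
#' Experiments: `traj_only` (trajectory features), `osc_choice` /
#' `osc_delay` (12-variable oscillation features from the choice or delay
#' epoch), `psd` (periodogram features, KS+BH-selected on training data
#' within each split), `combined` (trajectory + choice-epoch oscillation),
#' `zidphi_baseline` (single-metric threshold).
#'
#' @param experiment Experiment name (see above).
#' @param cfg A [sim_config()].
#' @param seed Seed for the session, split matrix, and baseline labels.
#' @param n_splits Number of balanced splits (default 100).
#' @param model `"svm"` or `"knn"` (ignored for `zidphi_baseline`).
#' @param gamma,cost Optional fixed SVM hyperparameters (grid-searched on
#'   the first split's training data when `NULL`).
#' @param session Optionally, a pre-simulated `sim_session` to reuse (so
#'   several experiments share one session and split matrix).
#' @param splits Optionally, a pre-built [build_split_matrix()] to reuse.
#' @return An `experiment_report` list: per-split `report` and
#'   `baseline_report` (`eval_report` data frames), `delta` scores, the
#'   predictions, labels, splits, seed and config hash.
#' @export
run_experiment <- function(experiment = c("traj_only", "osc_choice",
                                          "osc_delay", "psd", "combined",
                                          "zidphi_baseline"),
                           cfg = sim_config(), seed = 1, n_splits = 100,
                           model = c("svm", "knn"), gamma = NULL, cost = NULL,
                           session = NULL, splits = NULL) {
  experiment <- match.arg(experiment)
  model <- match.arg(model)
  if (is.null(session)) session <- simulate_session(cfg, seed = seed)

  noisy <- noise_exclusion(session$lfp, session$trials, "choice")
  labels <- curate_labels(session$votes, noise_excluded = noisy)
  features <- experiment_features(experiment, session, labels)
  if (is.null(splits))
    splits <- build_split_matrix(
      labels[labels$trial_id %in% features$trial_id, ],
      n_splits = n_splits, seed = seed)

  selector <- NULL
  if (experiment == "psd")
    selector <- function(train_table) select_psd_features(train_table)

  if (experiment == "zidphi_baseline") {
    preds <- zidphi_baseline_cv(features, splits)
    base <- NULL
  } else {
    preds <- run_cv(features, splits, model = model, gamma = gamma,
                    cost = cost, feature_selector = selector, seed = seed)
    base <- random_label_baseline(features, splits, model = model,
                                  gamma = attr(preds, "config")$gamma,
                                  cost = attr(preds, "config")$cost,
                                  feature_selector = selector, seed = seed)
  }
  report <- evaluate_cv(preds)
  base_report <- if (!is.null(base)) evaluate_cv(base)
  structure(list(experiment = experiment, model = model, seed = seed,
                 config_hash = config_hash(cfg),
                 labels = labels, splits = splits, features = features,
                 predictions = preds, baseline_predictions = base,
                 report = report, baseline_report = base_report,
                 delta = if (!is.null(base_report))
                   delta_scores(report, base_report),
                 session = session),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s (%s), seed %d: mean AUC %.3f",
              x$experiment, x$model, x$seed, mean(x$report$auc)))
  if (!is.null(x$delta))
    cat(sprintf(", mean dAUC %+.3f", mean(x$delta$delta_auc)))
  cat("\n")
  invisible(x)
}

# feature extraction per experiment, consensus labels attached
experiment_features <- function(experiment, session, labels) {
  keep <- labels$consensus != "excluded"
  ids <- labels$trial_id[keep]
  lab <- labels$consensus[keep]

  traj_features <- function() {
    traces <- lapply(ids, function(id)
      slice_epoch(session$positions, session$trials, id, "choice"))
    half <- session$config$center_half_width
    session_trajectory_features(traces, trial_id = ids, label = lab,
                                choice_region = default_choice_region(half))
  }
  osc_features <- function(epoch) {
    ep <- session$trials[session$trials$trial_id %in% ids, , drop = FALSE]
    session_osc_features(session$lfp, ep, epoch, label = lab)
  }
  switch(experiment,
    traj_only = ,
    zidphi_baseline = traj_features(),
    osc_choice = osc_features("choice"),
    osc_delay = osc_features("delay"),
    psd = {
      ep <- session$trials[session$trials$trial_id %in% ids, , drop = FALSE]
      session_psd_features(session$lfp, ep, "choice", label = lab)
    },
    combined = {
      tf <- traj_features()
      of <- osc_features("choice")
      common <- intersect(tf$trial_id, of$trial_id)
      ti <- match(common, tf$trial_id)
      oi <- match(common, of$trial_id)
      feature_table(common, tf$label[ti],
                    cbind(tf[ti, feature_names(tf), drop = FALSE],
                          of[oi, feature_names(of), drop = FALSE]))
    })
}
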