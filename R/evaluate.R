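# Evaluation metrics, ROC/AUC, chance-referenced delta scores, and the
# statistical tests used to compare metric distributions.

#' Confusion counts for binary VTE predictions
#'
#' @param predicted,truth Character vectors (`"VTE"`/`"nonVTE"`).
#' @return List with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  p <- predicted == "VTE"; t <- truth == "VTE"
  list(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' and false negative rate `FN/(TP+FN)`.  A metric with a zero denominator
#' is reported as `NA` (undefined), never as 0.
#'
#' @param counts List from [confusion_counts()] (or with fields
#'   `tp,tn,fp,fn`).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `fnr`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    total <- tp + tn + fp + fn
    c(accuracy = if (total > 0) (tp + tn) / total else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_)
  })
}

#' ROC curve and AUC of continuous scores
#'
#' Sweeps thresholds over the unique score values (prediction positive when
#' `score >= threshold`), plotting true positive rate against false
#' positive rate, and integrates the area with the trapezoid rule.  The
#' result equals the Mann-Whitney concordance probability with ties counted
#' one half.
#'
#' @param scores Numeric scores, higher = more VTE-like.
#' @param truth `"VTE"`/`"nonVTE"` labels (both classes required).
#' @return A `roc_curve` list: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_and_auc <- function(scores, truth) {
  truth <- as.character(truth)
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- truth == "VTE"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # accumulate at distinct score values so ties move diagonally
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last]; fp <- cumsum(!p)[last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr,
                 auc = auc),
            class = "roc_curve")
}

#' Per-split evaluation report
#'
#' Computes accuracy, precision, recall, FNR and AUC for every split of a
#' cross-validation run.
#'
#' @param predictions A `cv_predictions` object from [run_cv()].
#' @return An `eval_report` data frame, one row per split.
#' @export
evaluate_cv <- function(predictions) {
  rows <- lapply(predictions, function(ps) {
    m <- classification_metrics(confusion_counts(ps$predicted, ps$truth))
    auc <- roc_and_auc(ps$scores, ps$truth)$auc
    data.frame(split_id = ps$split_id, accuracy = m[["accuracy"]],
               precision = m[["precision"]], recall = m[["recall"]],
               fnr = m[["fnr"]], auc = auc)
  })
  structure(do.call(rbind, rows), class = c("eval_report", "data.frame"))
}

#' Delta scores against the chance baseline
#'
#' Per split and metric, the difference between a report and the
#' random-label baseline evaluated on the same split matrix; zero means the
#' classifier performed at chance for that split.
#'
#' @param report,baseline `eval_report` data frames sharing split ids.
#' @return Data frame of per-split `delta_*` columns.
#' @export
delta_scores <- function(report, baseline) {
  if (!identical(report$split_id, baseline$split_id))
    stop("reports come from different split matrices")
  out <- data.frame(split_id = report$split_id)
  for (m in c("accuracy", "precision", "recall", "auc"))
    out[[paste0("delta_", m)]] <- report[[m]] - baseline[[m]]
  out
}

#' Two-sample two-tailed Kolmogorov-Smirnov test
#'
#' D is the maximum gap between the two empirical CDFs; the p-value is
#' asymptotic by default (appropriate for the sample sizes here), exact on
#' request.
#'
#' @param a,b Numeric samples (>= 2 each).
#' @param exact Use the exact small-sample distribution.
#' @return List with `D` and `p`.
#' @export
ks_test_2samp <- function(a, b, exact = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}

#' One-sample two-tailed Wilcoxon signed-rank test
#'
#' Tests whether a distribution of differences is symmetric about zero.
#' Zeros are dropped; ties are mid-ranked; the exact distribution is used
#' when the (nonzero) sample is small and untied.
#'
#' @param diffs Numeric differences.
#' @return List with `statistic` (V), `p`, and `n_nonzero`.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  nz <- diffs[diffs != 0]
  if (!length(nz)) stop("all differences are zero: test degenerate")
  res <- suppressWarnings(stats::wilcox.test(diffs, mu = 0,
                                             alternative = "two.sided"))
  list(statistic = unname(res$statistic), p = res$p.value,
       n_nonzero = length(nz))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values with enforced monotonicity; rejections at
#' `alpha` are adjusted values `<= alpha`.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `adjusted` and logical `rejected`.
#' @export
bh_correct <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= alpha)
}

#' Cohen's d effect size
#'
#' Standardized mean difference with the pooled (n-1 weighted) SD;
#' conventionally 0.2 is small, 0.5 medium, above 0.8 large.
#'
#' @param a,b Numeric samples (>= 2 each).
#' @return d (positive when `mean(a) > mean(b)`; `NA` when the pooled SD
#'   is zero).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need >= 2 values per sample")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) {
    warning("zero pooled SD: d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}
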