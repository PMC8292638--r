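# Label consensus, inter-rater reliability, and quality gates.
#
# Four trained raters vote VTE/nonVTE per trial.  A majority (3-1 or 4-0)
# defines the consensus label; 2-2 ties are excluded from analysis.  Session
# gates: average pairwise percent agreement above 90% and average pairwise
# Cohen's kappa above 0.7; trials whose analyzed epoch exceeds a 4 SD noise
# threshold (SD of the entire session timeseries) are excluded, and a session
# loses all its data when more than 20% of trials are excluded or its
# theta-asymmetry distribution is skewed opposite the dataset's direction.

#' Consensus label from four rater votes
#'
#' Majority rules; a 2-2 tie is `"excluded"`.
#'
#' @param votes Character vector of exactly 4 votes (`"VTE"`/`"nonVTE"`), or
#'   a matrix/data frame with one row per trial and 4 vote columns.
#' @return `"VTE"`, `"nonVTE"`, or `"excluded"` (vector for matrix input).
#' @export
consensus_label <- function(votes) {
  if (is.data.frame(votes)) votes <- as.matrix(votes)
  if (is.matrix(votes)) {
    if (ncol(votes) != 4L) stop("exactly 4 rater votes are required")
    return(apply(votes, 1, consensus_label))
  }
  if (length(votes) != 4L) stop("exactly 4 rater votes are required")
  if (!all(votes %in% c("VTE", "nonVTE"))) stop("votes must be VTE or nonVTE")
  n_vte <- sum(votes == "VTE")
  if (n_vte > 2L) "VTE" else if (n_vte < 2L) "nonVTE" else "excluded"
}

# Cohen's kappa for two raters over the same trials
cohen_kappa <- function(a, b) {
  lev <- c("VTE", "nonVTE")
  if (length(unique(a)) < 2L && length(unique(b)) < 2L && a[1] == b[1])
    return(NA_real_)  # both constant: chance agreement is 1, kappa undefined
  po <- mean(a == b)
  pe <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Inter-rater reliability report
#'
#' Pairwise percent agreement and Cohen's kappa over the 6 rater pairs,
#' plus their averages.  Kappa is undefined (NA) for a pair whose chance
#' agreement is 1 (both raters constant and identical).
#'
#' @param votes Data frame or matrix of votes, one row per trial, columns
#'   `rater1..rater4` (a `trial_id` column is ignored).
#' @return A `rater_report` list: `pairs` (data frame with per-pair
#'   agreement and kappa), `mean_agreement` (percent), `mean_kappa`.
#' @export
interrater_stats <- function(votes) {
  if (is.data.frame(votes) && "trial_id" %in% names(votes))
    votes <- votes[setdiff(names(votes), "trial_id")]
  votes <- as.matrix(votes)
  if (nrow(votes) < 2L) stop("need at least 2 trials")
  nr <- ncol(votes)
  pairs <- utils::combn(nr, 2)
  out <- data.frame(rater_a = pairs[1, ], rater_b = pairs[2, ])
  out$agreement <- apply(pairs, 2, function(p)
    100 * mean(votes[, p[1]] == votes[, p[2]]))
  out$kappa <- apply(pairs, 2, function(p)
    cohen_kappa(votes[, p[1]], votes[, p[2]]))
  structure(list(pairs = out,
                 mean_agreement = mean(out$agreement),
                 mean_kappa = mean(out$kappa, na.rm = TRUE)),
            class = "rater_report")
}

#' @export
print.rater_report <- function(x, ...) {
  cat(sprintf("<rater_report> mean agreement %.1f%%, mean kappa %.3f\n",
              x$mean_agreement, x$mean_kappa))
  invisible(x)
}

#' Artifact-based trial exclusion
#'
#' A trial is excluded when any sample of its analyzed epoch exceeds 4 SD in
#' magnitude.  The threshold is in units of the SD of the entire session
#' timeseries, so `lfp` must be the session-z-scored trace (as produced by
#' [preprocess_lfp()]).
#'
#' @param lfp A session [lfp_trace()] (z-scored over the full session).
#' @param epochs A [trial_epochs()] table.
#' @param epoch Epoch to scan (`"choice"` or `"delay"`).
#' @param threshold Magnitude threshold in SD units (default 4).
#' @return Integer vector of excluded trial ids.
#' @export
noise_exclusion <- function(lfp, epochs, epoch = c("choice", "delay"),
                            threshold = 4) {
  epoch <- match.arg(epoch)
  bad <- vapply(epochs$trial_id, function(id) {
    seg <- slice_epoch(lfp, epochs, id, epoch)
    any(abs(seg$samples) > threshold)
  }, logical(1))
  epochs$trial_id[bad]
}

#' Session-level quality gate
#'
#' A session is kept when at most 20% of its trials are excluded (strictly
#' more than 20% drops it) and the central tendency (median) of its
#' theta-asymmetry distribution points in the required direction.  This
#' dataset's convention is positive asymmetry (longer ascending phases);
#' recording locations along other hippocampal axes can legitimately skew
#' negative, so the required sign is configurable.
#'
#' @param n_trials Number of trials in the session.
#' @param excluded Trial ids excluded (noise and/or 2-2 rater ties).
#' @param ai_values Per-cycle (or per-trial) asymmetry-index values for the
#'   session.
#' @param required_sign `+1` to require a positive median AI, `-1` negative.
#' @param max_excluded_fraction Exclusion fraction above which the session
#'   is dropped (default 0.20, strict inequality).
#' @return A `session_qc` list: `excluded_trials`, `excluded_fraction`,
#'   `ai_median`, `keep`.
#' @export
session_qc <- function(n_trials, excluded, ai_values, required_sign = 1,
                       max_excluded_fraction = 0.20) {
  if (!length(ai_values)) stop("AI values required for the skew check")
  frac <- length(unique(excluded)) / n_trials
  med <- stats::median(ai_values)
  keep <- frac <= max_excluded_fraction && sign(med) == sign(required_sign)
  structure(list(excluded_trials = sort(unique(excluded)),
                 excluded_fraction = frac, ai_median = med, keep = keep),
            class = "session_qc")
}

#' @export
print.session_qc <- function(x, ...) {
  cat(sprintf("<session_qc> %.1f%% trials excluded, median AI %+.3f -> %s\n",
              100 * x$excluded_fraction, x$ai_median,
              if (x$keep) "keep" else "drop"))
  invisible(x)
}

#' Curate a session's labels
#'
#' Applies the consensus rule to the vote table and merges noise exclusions:
#' the result is the per-trial label set the classifiers consume, with 2-2
#' ties and noisy trials marked `"excluded"`.
#'
#' @param votes Vote data frame (`trial_id`, `rater1..rater4`).
#' @param noise_excluded Trial ids excluded by [noise_exclusion()].
#' @return Data frame `trial_id`, `consensus` (`"VTE"`, `"nonVTE"`,
#'   `"excluded"`).
#' @export
curate_labels <- function(votes, noise_excluded = integer(0)) {
  cons <- consensus_label(votes[paste0("rater", 1:4)])
  cons[votes$trial_id %in% noise_excluded] <- "excluded"
  data.frame(trial_id = votes$trial_id, consensus = cons)
}
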