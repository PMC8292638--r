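# Trajectory-based VTE features.
#
# A VTE (vicarious trial and error) shows up as a choice-point trajectory with
# reorientations toward the unchosen arm.  The features quantify that:
# IdPhi integrates the absolute change in heading angle phi = atan2(dy, dx)
# over the choice trajectory (z-scored per session to zIdPhi); positional
# SDs and choice-point dwell time capture spatial spread and hesitation; a
# sixth-degree polynomial fit of y on x captures smoothness (VTEs fit
# poorly); and the number of Fourier coefficients needed to describe the fit
# captures its oscillatory character.

#' Heading-angle series of a trajectory
#'
#' Computes the heading angle `phi = atan2(dy, dx)` of successive
#' displacements and the absolute heading change between steps.  By default
#' angular differences are wrapped to the shortest circular distance in
#' `[0, pi]`, so crossings of the +/-pi discontinuity do not spuriously count
#' as full turns; the raw absolute difference is selectable.
#'
#' @param trace A [position_trace()] (>= 3 samples, not all coincident).
#' @param wrap Wrap angular differences to `[0, pi]` (default `TRUE`).
#' @param smooth Optional centered moving-average half-width (samples)
#'   applied to x and y before differencing; 0 disables smoothing.
#' @return A `heading_series` list with `phi` and `dphi_abs`.
#' @export
compute_heading <- function(trace, wrap = TRUE, smooth = 0) {
  x <- trace$x; y <- trace$y
  if (smooth > 0) {
    k <- 2 * smooth + 1
    w <- rep(1 / k, k)
    x <- as.numeric(stats::filter(x, w, sides = 2))
    y <- as.numeric(stats::filter(y, w, sides = 2))
    keep <- !is.na(x)
    x <- x[keep]; y <- y[keep]
  }
  dx <- diff(x); dy <- diff(y)
  if (all(dx == 0 & dy == 0))
    stop("degenerate trajectory: all samples coincident")
  phi <- atan2(dy, dx)
  d <- abs(diff(phi))
  if (wrap) d <- pmin(d, 2 * pi - d)
  structure(list(phi = phi, dphi_abs = d), class = "heading_series")
}

#' Integrated change in heading angle (IdPhi)
#'
#' Sum of the absolute heading-angle changes along a trajectory.  Zero for
#' constant-heading motion, invariant under rotation and translation of the
#' trajectory, and increased by every reorientation (head sweep).
#'
#' @param heading A `heading_series` from [compute_heading()].
#' @return IdPhi in radians (non-negative).
#' @export
compute_idphi <- function(heading) {
  sum(heading$dphi_abs)
}

#' Z-score values within a session
#'
#' Centering and scaling use the population SD (divisor N).  IdPhi is
#' converted to zIdPhi this way, session by session, because absolute IdPhi
#' scales vary with camera geometry and running speed.
#'
#' @param values Numeric vector of per-trial values for one session.
#' @return Z-scored vector (mean 0, population SD 1).
#' @export
zscore_by_session <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to z-score a session")
  pop_z(values)
}

#' Positional standard deviations of a trajectory
#'
#' @param trace A [position_trace()].
#' @return Named vector `c(x_sd, y_sd)` (population SD).
#' @export
position_sds <- function(trace) {
  if (length(trace$x) < 2L) stop("need at least 2 samples")
  c(x_sd = pop_sd(trace$x), y_sd = pop_sd(trace$y))
}

#' The simulator's choice-point region
#'
#' Bounding box of the plus maze's center platform in the simulator's
#' coordinates (arms of length 100 units meeting at the origin).
#'
#' @param half_width Half-width of the platform in maze units.
#' @return A 4x2 vertex matrix (closed implicitly).
#' @export
default_choice_region <- function(half_width = 15) {
  cbind(x = c(-1, 1, 1, -1) * half_width,
        y = c(-1, -1, 1, 1) * half_width)
}

#' Dwell time within the choice-point region
#'
#' Total time (sum of inter-frame intervals) during which the head position
#' lies inside an experimenter-defined polygon around the decision point.
#'
#' @param trace A [position_trace()].
#' @param region Polygon vertex matrix (2 columns), e.g.
#'   [default_choice_region()].
#' @return Duration in seconds (0 with a warning if the trace never enters).
#' @export
choice_duration <- function(trace, region = default_choice_region()) {
  region <- as.matrix(region)
  if (ncol(region) != 2L || nrow(region) < 3L) stop("malformed region polygon")
  bnd <- rbind(region, region[1, ])
  inside <- mgcv::in.out(bnd, cbind(trace$x, trace$y))
  if (!any(inside)) {
    warning("trajectory never enters the choice region")
    return(0)
  }
  dt <- diff(trace$t)
  sum(dt[inside[-length(inside)]])
}

#' Sixth-degree polynomial fit of a trajectory
#'
#' Least-squares fit of y positions on x positions with a degree-6
#' polynomial; smooth single-pass trajectories are fit almost perfectly while
#' VTE zig-zags are not.  `r2 = 1 - SSE/SST` where SSE is the error sum of
#' squares about the fit and SST the total sum of squares about the mean.
#'
#' @param trace A [position_trace()] with >= 8 samples and nonzero y spread.
#' @param degree Polynomial degree (default 6).
#' @return A `poly_fit` list: `coeffs` (ascending powers), `y_hat`, `sse`,
#'   `sst`, `r2`.
#' @export
poly_fit_r2 <- function(trace, degree = 6) {
  x <- trace$x; y <- trace$y
  if (length(x) < degree + 2L) stop("need at least ", degree + 2L, " samples")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero y spread: r^2 undefined (SST = 0)")
  # scale x for numerical conditioning of the Vandermonde system
  xs <- x - mean(x)
  sdx <- pop_sd(x)
  if (sdx > 0) xs <- xs / sdx
  fit <- stats::lm(y ~ stats::poly(xs, degree, raw = TRUE))
  y_hat <- stats::fitted(fit)
  sse <- sum((y - y_hat)^2)
  structure(list(coeffs = unname(stats::coef(fit)), y_hat = unname(y_hat),
                 sse = sse, sst = sst, r2 = 1 - sse / sst),
            class = "poly_fit")
}

#' Number of Fourier coefficients describing the polynomial fit
#'
#' Counts the smallest number of discrete Fourier magnitudes (largest first,
#' conjugate pairs counted once) whose summed spectral energy reaches
#' `energy_fraction` of the total.  The best linear trend is removed first,
#' so the count measures oscillatory structure beyond the smooth passage
#' (a raw ramp would otherwise need many coefficients purely from its
#' non-periodicity): a straight path counts 0, a single oscillation 1, and
#' the damped-oscillation-like fits typical of VTEs several.
#'
#' @param fit A `poly_fit` from [poly_fit_r2()], or a numeric vector of fit
#'   estimates.
#' @param energy_fraction Fraction of spectral energy to capture
#'   (default 0.95).
#' @return Integer count (0 for a constant fit estimate).
#' @export
fourier_coef_count <- function(fit, energy_fraction = 0.95) {
  y <- if (inherits(fit, "poly_fit")) fit$y_hat else as.numeric(fit)
  n <- length(y)
  if (n < 4L) stop("need at least 4 fit estimates")
  z <- stats::residuals(stats::lm(y ~ seq_len(n)))   # detrend, incl. mean
  if (all(abs(z) < 1e-12 * max(1, mean(abs(y))))) return(0L)
  xf <- stats::fft(z)
  half <- if (n %% 2 == 0) n / 2 + 1 else (n + 1) / 2
  e <- Mod(xf[2:half])^2
  # double interior bins to account for conjugate-pair energy
  if (n %% 2 == 0) e[-length(e)] <- 2 * e[-length(e)] else e <- 2 * e
  e <- sort(e, decreasing = TRUE)
  as.integer(which(cumsum(e) >= energy_fraction * sum(e))[1])
}

#' Trajectory feature vector for one choice-epoch trajectory
#'
#' Assembles the trajectory features: positional SDs, IdPhi and its
#' session z-score, choice-point dwell time, degree-6 fit r^2, and the
#' Fourier coefficient count.  Raw IdPhi is included as the seventh feature
#' by default (`include_idphi`).
#'
#' @param trace A [position_trace()] for the choice epoch.
#' @param session_idphis IdPhi values of all trials in the same session
#'   (used to z-score this trial's IdPhi); must include this trial's value.
#' @param choice_region Choice-point polygon (see [choice_duration()]).
#' @param include_idphi Include raw IdPhi alongside zIdPhi.
#' @param wrap,smooth Passed to [compute_heading()].
#' @return Named numeric vector of features.
#' @export
extract_trajectory_features <- function(trace, session_idphis,
                                        choice_region = default_choice_region(),
                                        include_idphi = TRUE,
                                        wrap = TRUE, smooth = 0) {
  heading <- compute_heading(trace, wrap = wrap, smooth = smooth)
  idphi <- compute_idphi(heading)
  sds <- position_sds(trace)
  mu <- mean(session_idphis); s <- pop_sd(session_idphis)
  if (s == 0) stop("degenerate session: zero IdPhi spread")
  fit <- poly_fit_r2(trace)
  out <- c(sds,
           zidphi = (idphi - mu) / s,
           dur = choice_duration(trace, choice_region),
           r2 = fit$r2,
           n_coef = as.numeric(fourier_coef_count(fit)))
  if (include_idphi) out <- c(out, idphi = idphi)
  out
}

#' Trajectory feature table for a whole session
#'
#' Computes per-trial trajectory features for a list of choice-epoch traces,
#' z-scoring IdPhi across the session.  Trials whose feature computation
#' fails are flagged (dropped with a warning naming them), not silently
#' ignored.
#'
#' @param traces Named or unnamed list of [position_trace()] objects, one per
#'   trial.
#' @param trial_id Integer trial ids (defaults to list position).
#' @param label Optional per-trial labels (`"VTE"`/`"nonVTE"`); defaults to
#'   `"nonVTE"` placeholders when unknown.
#' @param choice_region,include_idphi,wrap,smooth See
#'   [extract_trajectory_features()].
#' @return A [feature_table()].
#' @export
session_trajectory_features <- function(traces, trial_id = seq_along(traces),
                                        label = NULL,
                                        choice_region = default_choice_region(),
                                        include_idphi = TRUE,
                                        wrap = TRUE, smooth = 0) {
  idphis <- vapply(traces, function(tr)
    compute_idphi(compute_heading(tr, wrap = wrap, smooth = smooth)),
    numeric(1))
  rows <- lapply(seq_along(traces), function(i) {
    tryCatch(extract_trajectory_features(traces[[i]], idphis,
                                         choice_region = choice_region,
                                         include_idphi = include_idphi,
                                         wrap = wrap, smooth = smooth),
             error = function(e) e)
  })
  failed <- vapply(rows, inherits, logical(1), what = "error")
  if (any(failed))
    warning("trajectory features failed for trials ",
            paste(trial_id[failed], collapse = ", "), "; rows dropped")
  ok <- !failed
  feats <- do.call(rbind, rows[ok])
  if (is.null(label)) label <- rep("nonVTE", length(traces))
  feature_table(trial_id[ok], label[ok], feats)
}

#' Single-metric zIdPhi threshold classifier
#'
#' Scans thresholds at the 50th to 80th percentiles of the zIdPhi
#' distribution (1-percentile steps), predicting VTE above threshold, and
#' selects the threshold maximizing the two-point ROC area `(TPR + TNR)/2`.
#' This is the single-feature baseline the multi-feature classifiers are
#' compared against.
#'
#' @param zidphi Numeric zIdPhi scores.
#' @param labels `"VTE"`/`"nonVTE"` per trial (both classes required).
#' @return List with `threshold`, `percentile`, `area` (two-point ROC area),
#'   and `predictions`.
#' @export
zidphi_threshold_classifier <- function(zidphi, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to place a threshold")
  probs <- seq(0.50, 0.80, by = 0.01)
  thr <- stats::quantile(zidphi, probs, names = FALSE)
  is_vte <- labels == "VTE"
  areas <- vapply(thr, function(th) {
    pred <- zidphi > th
    tpr <- sum(pred & is_vte) / sum(is_vte)
    tnr <- sum(!pred & !is_vte) / sum(!is_vte)
    (tpr + tnr) / 2
  }, numeric(1))
  best <- which.max(areas)
  list(threshold = thr[best], percentile = probs[best], area = areas[best],
       predictions = ifelse(zidphi > thr[best], "VTE", "nonVTE"))
}
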