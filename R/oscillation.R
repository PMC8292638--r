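# Hippocampal field-potential features.
#
# The pipeline mirrors how CA1 recordings are treated: 30 kHz raw traces are
# decimated to 1 kHz and z-scored over the whole session so amplitude is in
# SD units; theta cycles are segmented peak-to-peak on an 80 Hz lowpassed
# copy (peaks at least 0.0833 s apart, the upper edge of the 4-12 Hz theta
# band); gamma power comes from zero-lag third-order Butterworth bandpasses
# (35-55 Hz low, 61-100 Hz high) via the analytic-signal envelope.  Per trial
# epoch this yields a 12-variable feature vector; the periodogram gives the
# alternative 1-100 Hz PSD feature set.

GAMMA_BANDS <- list(low = c(35, 55), high = c(61, 100))

#' Preprocess a raw field-potential trace
#'
#' Decimates (anti-alias filtered by default) and z-scores the full session
#' trace with the population SD, putting amplitude in units of standard
#' deviations.
#'
#' @param raw Numeric raw samples.
#' @param fs_in Input sampling rate in Hz (default 30000).
#' @param factor Decimation factor (default 30, giving 1 kHz).
#' @param antialias Apply the anti-alias lowpass before subsampling.
#' @param session_id Session identifier for the returned trace.
#' @return An [lfp_trace()] at `fs_in / factor` Hz, mean 0 and SD 1.
#' @export
preprocess_lfp <- function(raw, fs_in = 30000, factor = 30,
                           antialias = TRUE, session_id = "session") {
  if (length(raw) < factor) stop("raw trace shorter than one output sample")
  if (pop_sd(raw) == 0) stop("constant signal cannot be z-scored")
  x <- decimate_signal(raw, factor, antialias = antialias)
  lfp_trace(pop_z(x), fs = fs_in / factor, session_id = session_id)
}

#' Lowpass a trace for theta-cycle landmark detection
#'
#' Zero-lag (forward-backward) Butterworth lowpass with an 80 Hz cutoff;
#' theta peaks are not displaced because the filter has no phase lag.
#'
#' @param x An [lfp_trace()], [lfp_segment()], or numeric vector.
#' @param fs Sampling rate in Hz (taken from the object when available).
#' @param cutoff Cutoff frequency in Hz (default 80).
#' @param order Butterworth order (default 3).
#' @return Numeric filtered samples.
#' @export
lowpass_for_cycles <- function(x, fs = NULL, cutoff = 80, order = 3) {
  if (inherits(x, c("lfp_trace", "lfp_segment"))) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs required for a bare numeric signal")
  bf <- butter_design(order, cutoff / (fs / 2), "low")
  zero_phase_filter(bf$b, bf$a, x)
}

#' Segment theta cycles peak-to-peak
#'
#' Local maxima of the lowpassed signal separated by at least
#' `min_separation` seconds are theta peaks (when two candidates fall
#' closer, the larger wins); the minimum between consecutive peaks is the
#' trough (earliest sample on ties).  A cycle runs peak -> trough -> next
#' peak, with descending duration peak->trough and ascending duration
#' trough->next peak.
#'
#' @param filtered Numeric lowpassed samples (see [lowpass_for_cycles()]).
#' @param fs Sampling rate in Hz.
#' @param min_separation Minimum peak separation in seconds (default
#'   0.0833, the 12 Hz upper edge of theta).
#' @param max_duration Optional cap on cycle duration in seconds; `NULL`
#'   (default) imposes none.
#' @return Data frame with one row per cycle: `peak_idx`, `trough_idx`,
#'   `next_peak_idx` (sample indices), `desc_ms`, `asc_ms`, `total_ms`.
#'   Empty (with a warning) when fewer than 2 peaks are found.
#' @export
detect_theta_cycles <- function(filtered, fs, min_separation = 0.0833,
                                max_duration = NULL) {
  x <- filtered
  n <- length(x)
  empty <- data.frame(peak_idx = integer(0), trough_idx = integer(0),
                      next_peak_idx = integer(0), desc_ms = numeric(0),
                      asc_ms = numeric(0), total_ms = numeric(0))
  if (n < 3L) { warning("segment too short for cycle detection"); return(empty) }
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) >= 2L) {
    min_gap <- min_separation * fs
    ord <- cand[order(x[cand], decreasing = TRUE)]
    keep <- logical(0)
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_gap)) kept <- c(kept, p)
    }
    peaks <- sort(kept)
  } else peaks <- cand
  if (length(peaks) < 2L) {
    warning("fewer than 2 theta peaks detected")
    return(empty)
  }
  trough <- vapply(seq_len(length(peaks) - 1L), function(i) {
    lo <- peaks[i]; hi <- peaks[i + 1L]
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1))
  cyc <- data.frame(peak_idx = peaks[-length(peaks)], trough_idx = trough,
                    next_peak_idx = peaks[-1])
  cyc$desc_ms <- (cyc$trough_idx - cyc$peak_idx) / fs * 1000
  cyc$asc_ms <- (cyc$next_peak_idx - cyc$trough_idx) / fs * 1000
  cyc$total_ms <- cyc$desc_ms + cyc$asc_ms
  cyc <- cyc[cyc$desc_ms > 0 & cyc$asc_ms > 0, , drop = FALSE]
  if (!is.null(max_duration))
    cyc <- cyc[cyc$total_ms <= max_duration * 1000, , drop = FALSE]
  cyc
}

#' Theta-cycle asymmetry index
#'
#' `AI = log(asc) - log(desc)` (natural log): positive for cycles with
#' longer ascending than descending durations, zero for symmetric cycles,
#' and antisymmetric under swapping the two durations.
#'
#' @param asc Ascending durations, or a cycle data frame from
#'   [detect_theta_cycles()].
#' @param desc Descending durations (ignored when `asc` is a data frame).
#' @return Numeric AI value(s).
#' @export
asymmetry_index <- function(asc, desc = NULL) {
  if (is.data.frame(asc)) {
    desc <- asc$desc_ms
    asc <- asc$asc_ms
  }
  if (any(asc <= 0) || any(desc <= 0))
    stop("ascending and descending durations must be positive")
  log(asc) - log(desc)
}

#' Gamma-band power envelope
#'
#' Bandpasses at 35-55 Hz (low gamma) or 61-100 Hz (high gamma) with a
#' zero-lag third-order Butterworth filter, re-z-scores the bandpassed
#' series (amplitude in SD units), and estimates instantaneous power as the
#' squared modulus of the analytic signal.  For session-level analyses pass
#' the whole session trace so the z-scoring is a single common scale and
#' per-trial power differences survive.
#'
#' @param x An [lfp_trace()], [lfp_segment()], or numeric vector.
#' @param band `"low"` or `"high"`, or a numeric `c(lo, hi)` in Hz.
#' @param fs Sampling rate in Hz (taken from the object when available).
#' @param normalize Re-z-score the bandpassed series (default `TRUE`).
#' @param order Butterworth order (default 3).
#' @return A `gamma_envelope` list: `band`, `g` (bandpassed, z-units),
#'   `p` (power, z-units squared).
#' @export
gamma_envelope <- function(x, band = c("low", "high"), fs = NULL,
                           normalize = TRUE, order = 3) {
  if (inherits(x, c("lfp_trace", "lfp_segment"))) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs)) stop("fs required for a bare numeric signal")
  if (is.character(band)) band_hz <- GAMMA_BANDS[[match.arg(band)]]
  else band_hz <- band
  if (band_hz[2] >= fs / 2) stop("band extends beyond Nyquist")
  bf <- butter_design(order, band_hz / (fs / 2), "pass")
  g <- zero_phase_filter(bf$b, bf$a, x)
  if (normalize) g <- pop_z(g)
  structure(list(band = band_hz, g = g, p = Mod(analytic_signal(g))^2),
            class = "gamma_envelope")
}

#' Cycle-by-cycle gamma ratio
#'
#' For each theta cycle, the time average of low-gamma power across the
#' cycle divided by the time average of high-gamma power; the trial-level
#' gamma ratio is the mean of these per-cycle values.
#'
#' @param cycles Cycle data frame from [detect_theta_cycles()].
#' @param lg,hg `gamma_envelope` objects covering the same samples the
#'   cycle indices refer to.
#' @return Numeric per-cycle gamma ratios (cycles with zero high-gamma
#'   power are skipped with a warning).
#' @export
gamma_ratio <- function(cycles, lg, hg) {
  if (!nrow(cycles)) return(numeric(0))
  if (max(cycles$next_peak_idx) > length(lg$p))
    stop("cycles extend beyond the envelope extent")
  gr <- vapply(seq_len(nrow(cycles)), function(i) {
    idx <- cycles$peak_idx[i]:(cycles$next_peak_idx[i] - 1L)
    denom <- mean(hg$p[idx])
    if (denom == 0) return(NA_real_)
    mean(lg$p[idx]) / denom
  }, numeric(1))
  if (anyNA(gr)) warning(sum(is.na(gr)), " cycles skipped (zero high-gamma power)")
  gr[!is.na(gr)]
}

# 12-variable aggregation shared by the per-segment and per-session paths;
# power is averaged per cycle first, so trial features are cycle-weighted
osc_features_from <- function(filtered, lg, hg, fs, min_cycles = 3L, ...) {
  cyc <- detect_theta_cycles(filtered, fs, ...)
  if (nrow(cyc) < min_cycles)
    stop(structure(class = c("too_few_cycles", "error", "condition"),
                   list(message = paste0("only ", nrow(cyc),
                                         " theta cycles (need >= ", min_cycles, ")"),
                        call = NULL)))
  ai <- asymmetry_index(cyc)
  cyc_mean <- function(p) vapply(seq_len(nrow(cyc)), function(i)
    mean(p[cyc$peak_idx[i]:(cyc$next_peak_idx[i] - 1L)]), numeric(1))
  lgp <- cyc_mean(lg$p)
  hgp <- cyc_mean(hg$p)
  gr <- gamma_ratio(cyc, lg, hg)
  c(ai_mean = mean(ai), ai_sd = pop_sd(ai),
    asc_mean = mean(cyc$asc_ms), desc_mean = mean(cyc$desc_ms),
    lg_mean = mean(lgp), lg_sd = pop_sd(lgp),
    hg_mean = mean(hgp), hg_sd = pop_sd(hgp),
    gr_mean = mean(gr), gr_sd = pop_sd(gr),
    cycdur_mean = mean(cyc$total_ms), cycdur_sd = pop_sd(cyc$total_ms))
}

#' 12-variable oscillation feature vector for one epoch segment
#'
#' Theta-cycle asymmetry index (mean, SD), mean ascending and descending
#' durations, cycle-averaged low- and high-gamma power (mean, SD), the
#' gamma ratio (mean, SD), and the cycle duration (mean, SD).  Gamma
#' normalization here is per segment; use [session_osc_features()] when
#' comparing power across trials of a session.
#'
#' @param segment An [lfp_segment()] (>= 250 ms, >= 3 complete theta cycles).
#' @param min_cycles Minimum number of complete cycles (default 3).
#' @param normalize_gamma Z-score the bandpassed gamma series before the
#'   envelope (default `TRUE`, the standard pipeline; `FALSE` keeps raw
#'   band power, useful for absolute parameter-recovery checks).
#' @param ... Passed to [detect_theta_cycles()].
#' @return Named numeric vector of length 12.
#' @export
extract_osc_features <- function(segment, min_cycles = 3L,
                                 normalize_gamma = TRUE, ...) {
  if (length(segment$samples) < 0.25 * segment$fs)
    stop("segment shorter than two theta periods")
  filtered <- lowpass_for_cycles(segment)
  lg <- gamma_envelope(segment, "low", normalize = normalize_gamma)
  hg <- gamma_envelope(segment, "high", normalize = normalize_gamma)
  osc_features_from(filtered, lg, hg, segment$fs, min_cycles = min_cycles, ...)
}

#' Oscillation feature table for a whole session
#'
#' Filters and normalizes once over the full session trace (so gamma power
#' is on a single session-wide scale), then slices each trial's epoch and
#' computes the 12-variable feature vector.  Trials with too few theta
#' cycles are flagged and dropped with a warning naming them.
#'
#' @param lfp A session [lfp_trace()] (z-scored, 1 kHz).
#' @param epochs A [trial_epochs()] table.
#' @param epoch `"choice"` or `"delay"`.
#' @param label Optional per-trial labels aligned with `epochs$trial_id`.
#' @param min_cycles Minimum complete theta cycles per trial (default 3).
#' @param normalize_gamma See [extract_osc_features()].
#' @param ... Passed to [detect_theta_cycles()].
#' @return A [feature_table()] with the 12 oscillation features.
#' @export
session_osc_features <- function(lfp, epochs, epoch = c("choice", "delay"),
                                 label = NULL, min_cycles = 3L,
                                 normalize_gamma = TRUE, ...) {
  epoch <- match.arg(epoch)
  filtered <- lowpass_for_cycles(lfp)
  lg <- gamma_envelope(lfp, "low", normalize = normalize_gamma)
  hg <- gamma_envelope(lfp, "high", normalize = normalize_gamma)
  ids <- epochs$trial_id
  rows <- lapply(seq_along(ids), function(i) {
    t0 <- epochs[[paste0(epoch, "_start")]][i]
    t1 <- epochs[[paste0(epoch, "_end")]][i]
    i0 <- ceiling((t0 - lfp$t0) * lfp$fs - 1e-9) + 1L
    i1 <- ceiling((t1 - lfp$t0) * lfp$fs - 1e-9)
    if (i0 < 1L || i1 > length(lfp$samples)) return(simpleError("outside extent"))
    idx <- i0:i1
    sub <- function(env) structure(list(band = env$band, g = env$g[idx],
                                        p = env$p[idx]), class = "gamma_envelope")
    tryCatch(osc_features_from(filtered[idx], sub(lg), sub(hg), lfp$fs,
                               min_cycles = min_cycles, ...),
             error = function(e) e)
  })
  failed <- vapply(rows, inherits, logical(1), what = "error")
  if (any(failed))
    warning("oscillation features unusable for trials ",
            paste(ids[failed], collapse = ", "))
  if (is.null(label)) label <- rep("nonVTE", length(ids))
  feature_table(ids[!failed], label[!failed], do.call(rbind, rows[!failed]))
}

#' Periodogram power spectral density, 1-100 Hz
#'
#' Single-window periodogram of the (already z-transformed) segment with a
#' Hamming taper, averaged into 1 Hz bins; powers are kept linear, not
#' converted to decibels.
#'
#' @param segment An [lfp_segment()] or numeric vector of at least 1 s
#'   (1 Hz resolution).
#' @param fs Sampling rate in Hz (taken from the object when available).
#' @param fmax Highest frequency bin in Hz (default 100).
#' @return List with `freqs` (1..fmax Hz) and `power` (z-units^2/Hz).
#' @export
compute_psd <- function(segment, fs = NULL, fmax = 100) {
  if (inherits(segment, c("lfp_trace", "lfp_segment"))) {
    fs <- segment$fs
    segment <- segment$samples
  }
  if (is.null(fs)) stop("fs required for a bare numeric signal")
  n <- length(segment)
  if (n < fs) stop("segment shorter than 1 s: cannot resolve 1 Hz bins")
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xf <- stats::fft(segment * w)
  nhalf <- floor(n / 2)
  pxx <- Mod(xf[1:(nhalf + 1)])^2 / (fs * sum(w^2))
  scale2 <- rep(2, nhalf + 1)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nhalf + 1] <- 1
  pxx <- pxx * scale2
  freqs <- (0:nhalf) * fs / n
  centers <- seq_len(fmax)
  power <- vapply(centers, function(f)
    mean(pxx[freqs >= f - 0.5 & freqs < f + 0.5]), numeric(1))
  list(freqs = centers, power = power)
}

#' PSD feature table for a whole session
#'
#' @param lfp A session [lfp_trace()].
#' @param epochs A [trial_epochs()] table.
#' @param epoch `"choice"` or `"delay"`.
#' @param label Optional per-trial labels.
#' @param fmax Highest frequency bin in Hz (default 100).
#' @return A [feature_table()] with columns `psd_1` .. `psd_<fmax>`.
#' @export
session_psd_features <- function(lfp, epochs, epoch = c("choice", "delay"),
                                 label = NULL, fmax = 100) {
  epoch <- match.arg(epoch)
  ids <- epochs$trial_id
  rows <- lapply(seq_along(ids), function(i) {
    seg <- slice_epoch(lfp, epochs, ids[i], epoch)
    tryCatch(compute_psd(seg, fmax = fmax)$power, error = function(e) e)
  })
  failed <- vapply(rows, inherits, logical(1), what = "error")
  if (any(failed))
    warning("PSD unusable for trials ", paste(ids[failed], collapse = ", "))
  feats <- do.call(rbind, rows[!failed])
  colnames(feats) <- paste0("psd_", seq_len(fmax))
  if (is.null(label)) label <- rep("nonVTE", length(ids))
  feature_table(ids[!failed], label[!failed], feats)
}

#' Select PSD frequencies that separate VTE from non-VTE trials
#'
#' Per-frequency two-sample two-tailed Kolmogorov-Smirnov tests of the VTE
#' vs non-VTE power distributions, followed by Benjamini-Hochberg false
#' discovery rate correction; surviving frequencies form the classifier's
#' PSD feature set.  Run this on training data only within each split to
#' avoid selection leakage.
#'
#' @param psd_table A [feature_table()] of PSD features with labels.
#' @param alpha FDR level (default 0.05).
#' @return Character vector of surviving feature names (empty, with a
#'   warning, when none survive).
#' @export
select_psd_features <- function(psd_table, alpha = 0.05) {
  labs <- psd_table$label
  if (length(unique(labs)) < 2L || min(table(labs)) < 2L)
    stop("need at least 2 trials of each class")
  feats <- feature_names(psd_table)
  pvals <- vapply(feats, function(nm) {
    a <- psd_table[[nm]][labs == "VTE"]
    b <- psd_table[[nm]][labs == "nonVTE"]
    suppressWarnings(stats::ks.test(a, b)$p.value)
  }, numeric(1))
  adj <- stats::p.adjust(pvals, method = "BH")
  keep <- feats[adj <= alpha]
  if (!length(keep)) warning("no PSD frequencies survive FDR correction")
  keep
}
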