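# Data model, epoch slicing, and plain-text readers/writers.
#
# Positions arrive as timestamped head coordinates (~35 Hz camera, millisecond
# timer converted to seconds on read); field potentials as 1 kHz traces
# (int16 binary + JSON sidecar, or single-column CSV); labels as per-trial
# votes from four raters.  Time windows are half-open [start, end) so that
# epoch slicing partitions a session without double-counting boundary frames.

#' Construct a session of head positions
#'
#' @param t Timestamps in seconds, strictly increasing.
#' @param x,y Head coordinates (camera pixels, or the simulator's maze units).
#' @param session_id Session identifier.
#' @param nominal_rate Nominal camera frame rate in Hz; estimated from the
#'   median frame interval when `NULL`.
#' @param trial_id,epoch Optional per-frame annotations.
#' @return A `session_positions` object.
#' @export
session_positions <- function(t, x, y, session_id = "session",
                              nominal_rate = NULL,
                              trial_id = NULL, epoch = NULL) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (anyNA(t) || !all(is.finite(x)) || !all(is.finite(y)))
    stop("positions must be finite")
  if (is.unsorted(t, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  if (is.null(nominal_rate)) nominal_rate <- 1 / stats::median(diff(t))
  if (nominal_rate <= 0) stop("nominal_rate must be positive")
  frames <- data.frame(t = t, x = x, y = y)
  if (!is.null(trial_id)) frames$trial_id <- trial_id
  if (!is.null(epoch)) frames$epoch <- epoch
  structure(list(session_id = session_id, frames = frames,
                 nominal_rate = nominal_rate),
            class = "session_positions")
}

#' @export
print.session_positions <- function(x, ...) {
  cat(sprintf("<session_positions> %s: %d frames, %.1f-%.1f s, ~%.1f Hz\n",
              x$session_id, nrow(x$frames), min(x$frames$t),
              max(x$frames$t), x$nominal_rate))
  invisible(x)
}

#' Construct a single-trial position trace
#'
#' Holds the trajectory samples that enter the heading-angle and polynomial
#' fit features.
#'
#' @param t Seconds, strictly increasing, length >= 3.
#' @param x,y Coordinates.
#' @return A `position_trace`.
#' @export
position_trace <- function(t, x, y) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) < 3L) stop("a position trace needs at least 3 samples")
  if (is.unsorted(t, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  if (!all(is.finite(c(t, x, y)))) stop("trace values must be finite")
  structure(list(t = t, x = x, y = y), class = "position_trace")
}

#' Construct a session field-potential trace
#'
#' @param samples Numeric samples (z-units after preprocessing).
#' @param fs Sampling rate in Hz (1000 after preprocessing).
#' @param session_id Session identifier.
#' @param t0 Time of the first sample in seconds.
#' @return An `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs, session_id = "session", t0 = 0) {
  if (!all(is.finite(samples))) stop("LFP samples must be finite")
  if (fs <= 0) stop("fs must be positive")
  structure(list(samples = as.numeric(samples), fs = fs,
                 session_id = session_id, t0 = t0),
            class = "lfp_trace")
}

#' Construct a single-epoch field-potential segment
#'
#' @param samples Numeric samples.
#' @param fs Sampling rate in Hz.
#' @param trial_id Trial the segment belongs to.
#' @param epoch `"choice"` or `"delay"`.
#' @return An `lfp_segment`.
#' @export
lfp_segment <- function(samples, fs, trial_id = NA_integer_,
                        epoch = c("choice", "delay")) {
  epoch <- match.arg(epoch)
  structure(list(samples = as.numeric(samples), fs = fs,
                 trial_id = trial_id, epoch = epoch),
            class = "lfp_segment")
}

#' Construct per-trial epoch windows
#'
#' Each trial has a choice epoch (start arm exit to reward-arm choice), a
#' return epoch (reward site back to the next start arm) and a 10 s delay
#' epoch, in that order and non-overlapping.
#'
#' @param df Data frame with columns `trial_id`, `start_arm`, `chosen_arm`,
#'   `rewarded`, and `<epoch>_start` / `<epoch>_end` in seconds for epochs
#'   choice, return, delay.
#' @param delay_duration Expected delay length in seconds.
#' @param tol Tolerance on the delay duration (frame quantization).
#' @return A `trial_epochs` data frame.
#' @export
trial_epochs <- function(df, delay_duration = 10, tol = 0.1) {
  need <- c("trial_id", "start_arm", "chosen_arm", "rewarded",
            "choice_start", "choice_end", "return_start", "return_end",
            "delay_start", "delay_end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing trial columns: ", paste(miss, collapse = ", "))
  ok_order <- df$choice_start < df$choice_end &
    df$choice_end <= df$return_start & df$return_start < df$return_end &
    df$return_end <= df$delay_start & df$delay_start < df$delay_end
  if (!all(ok_order)) stop("epoch windows must be ordered choice < return < delay")
  if (any(abs((df$delay_end - df$delay_start) - delay_duration) > tol))
    stop("delay epochs must last ", delay_duration, " s")
  if (!all(df$start_arm %in% c("north", "south")))
    stop("start_arm must be north or south")
  if (!all(df$chosen_arm %in% c("east", "west")))
    stop("chosen_arm must be east or west")
  structure(df, class = c("trial_epochs", "data.frame"))
}

#' Slice one trial epoch out of a session recording
#'
#' Windows are half-open `[start, end)`: a sample belongs to the epoch iff
#' `start <= t < end`, so choice/return/delay slices partition the trial.
#'
#' @param x A `session_positions` or `lfp_trace`.
#' @param epochs A `trial_epochs` table.
#' @param trial A trial id present in `epochs`.
#' @param epoch `"choice"`, `"return"`, or `"delay"`.
#' @return A [position_trace()] or [lfp_segment()].
#' @export
slice_epoch <- function(x, epochs, trial, epoch = c("choice", "return", "delay")) {
  epoch <- match.arg(epoch)
  row <- epochs[epochs$trial_id == trial, , drop = FALSE]
  if (nrow(row) != 1L) stop("trial ", trial, " not found in epochs")
  t0 <- row[[paste0(epoch, "_start")]]
  t1 <- row[[paste0(epoch, "_end")]]
  if (t1 <= t0) stop("empty slice: window [", t0, ", ", t1, ") has zero length")
  UseMethod("slice_epoch")
}

#' @export
slice_epoch.session_positions <- function(x, epochs, trial,
                                          epoch = c("choice", "return", "delay")) {
  epoch <- match.arg(epoch)
  row <- epochs[epochs$trial_id == trial, , drop = FALSE]
  t0 <- row[[paste0(epoch, "_start")]]; t1 <- row[[paste0(epoch, "_end")]]
  tr <- range(x$frames$t)
  if (t0 < tr[1] - 1 / x$nominal_rate || t1 > tr[2] + 1 / x$nominal_rate)
    stop("window [", t0, ", ", t1, ") outside recording extent")
  keep <- x$frames$t >= t0 & x$frames$t < t1
  if (!any(keep)) stop("empty slice: no frames in window")
  f <- x$frames[keep, , drop = FALSE]
  position_trace(f$t, f$x, f$y)
}

#' @export
slice_epoch.lfp_trace <- function(x, epochs, trial,
                                  epoch = c("choice", "return", "delay")) {
  epoch <- match.arg(epoch)
  if (epoch == "return") stop("LFP features are computed for choice and delay epochs")
  row <- epochs[epochs$trial_id == trial, , drop = FALSE]
  t0 <- row[[paste0(epoch, "_start")]]; t1 <- row[[paste0(epoch, "_end")]]
  n <- length(x$samples)
  i0 <- ceiling((t0 - x$t0) * x$fs - 1e-9) + 1L
  i1 <- ceiling((t1 - x$t0) * x$fs - 1e-9)      # last sample with t < t1
  if (i0 < 1L || i1 > n) stop("window outside recording extent")
  if (i1 < i0) stop("empty slice")
  lfp_segment(x$samples[i0:i1], x$fs, trial_id = trial, epoch = epoch)
}

# ---------------------------------------------------------------- readers --

#' Read head positions from CSV
#'
#' Expects columns `t_ms,x,y,trial_id,epoch` (header required); timestamps in
#' milliseconds are converted to seconds.  Rows with non-finite coordinates
#' are dropped with a warning; duplicated timestamps are an error.
#'
#' @param path CSV file path.
#' @param session_id Session identifier to attach.
#' @return A [session_positions()].
#' @export
read_positions <- function(path, session_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_ms", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("position CSV missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- !is.finite(df$t_ms) | !is.finite(df$x) | !is.finite(df$y)
  if (any(bad)) {
    warning(sum(bad), " malformed position rows dropped")
    df <- df[!bad, , drop = FALSE]
  }
  df <- df[order(df$t_ms), , drop = FALSE]
  if (anyDuplicated(df$t_ms)) stop("duplicated timestamps in position CSV")
  session_positions(df$t_ms / 1000, df$x, df$y, session_id = session_id,
                    trial_id = df$trial_id, epoch = df$epoch)
}

#' Write head positions to CSV
#'
#' Inverse of [read_positions()]; timestamps written in milliseconds.
#'
#' @param positions A `session_positions`.
#' @param path Output CSV path.
#' @export
write_positions <- function(positions, path) {
  f <- positions$frames
  out <- data.frame(t_ms = fmt_num(f$t * 1000), x = fmt_num(f$x),
                    y = fmt_num(f$y),
                    trial_id = if (!is.null(f$trial_id)) f$trial_id else NA,
                    epoch = if (!is.null(f$epoch)) f$epoch else NA)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the per-trial epoch table from CSV
#'
#' Columns `trial_id,start_arm,chosen_arm,rewarded,*_start_ms,*_end_ms` for
#' the choice, return, and delay epochs; milliseconds converted to seconds.
#'
#' @param path CSV file path.
#' @return A [trial_epochs()] table.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ms <- c("choice_start_ms", "choice_end_ms", "return_start_ms",
          "return_end_ms", "delay_start_ms", "delay_end_ms")
  miss <- setdiff(c("trial_id", "start_arm", "chosen_arm", "rewarded", ms),
                  names(df))
  if (length(miss)) stop("trial CSV missing columns: ",
                         paste(miss, collapse = ", "))
  out <- data.frame(trial_id = df$trial_id, start_arm = df$start_arm,
                    chosen_arm = df$chosen_arm,
                    rewarded = as.logical(df$rewarded))
  for (m in ms) out[[sub("_ms$", "", m)]] <- df[[m]] / 1000
  trial_epochs(out)
}

#' Write the per-trial epoch table to CSV
#'
#' @param epochs A `trial_epochs` table.
#' @param path Output CSV path.
#' @export
write_trials <- function(epochs, path) {
  out <- data.frame(trial_id = epochs$trial_id, start_arm = epochs$start_arm,
                    chosen_arm = epochs$chosen_arm, rewarded = epochs$rewarded)
  for (ep in c("choice", "return", "delay"))
    for (side in c("start", "end"))
      out[[paste0(ep, "_", side, "_ms")]] <-
        fmt_num(epochs[[paste0(ep, "_", side)]] * 1000)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field-potential trace
#'
#' Accepts either a single-column CSV of samples, or a flat little-endian
#' int16 binary with a JSON sidecar `<path>.json` carrying `fs`,
#' `scale_to_uV`, and `session_id`.
#'
#' @param path File path (`.csv` or binary).
#' @param fs Sampling rate, required for CSV input without a sidecar.
#' @return An [lfp_trace()].
#' @export
read_lfp <- function(path, fs = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (grepl("\\.csv$", path)) {
    samples <- utils::read.csv(path)[[1]]
    scale <- 1
  } else {
    if (!file.exists(sidecar)) stop("binary LFP requires a JSON sidecar")
    n <- file.info(path)$size / 2
    samples <- readBin(path, "integer", n = n, size = 2, endian = "little")
    scale <- meta$scale_to_uV %||% 1
  }
  fs <- fs %||% meta$fs
  if (is.null(fs)) stop("sampling rate not given and no sidecar found")
  lfp_trace(samples * scale, fs = fs,
            session_id = meta$session_id %||% basename(path))
}

#' Write a field-potential trace
#'
#' CSV output for `.csv` paths; otherwise int16 binary plus JSON sidecar.
#' Binary output quantizes to the int16 grid after dividing by
#' `scale_to_uV`.
#'
#' @param trace An `lfp_trace`.
#' @param path Output path.
#' @param scale_to_uV Scale factor stored in the sidecar for binary output.
#' @export
write_lfp <- function(trace, path, scale_to_uV = 1) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(data.frame(sample = fmt_num(trace$samples)), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    writeBin(as.integer(round(trace$samples / scale_to_uV)), path,
             size = 2, endian = "little")
  }
  jsonlite::write_json(list(fs = trace$fs, scale_to_uV = scale_to_uV,
                            session_id = trace$session_id),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read rater votes from CSV
#'
#' Columns `trial_id,rater1..rater4` with values `VTE|nonVTE`.
#'
#' @param path CSV file path.
#' @return Data frame of votes (one row per trial).
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", paste0("rater", 1:4))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("label CSV missing columns: ",
                         paste(miss, collapse = ", "))
  votes <- as.matrix(df[paste0("rater", 1:4)])
  if (!all(votes %in% c("VTE", "nonVTE")))
    stop("votes must be 'VTE' or 'nonVTE'")
  df[need]
}

#' Write rater votes to CSV
#'
#' @param labels Data frame with `trial_id` and `rater1..rater4`.
#' @param path Output CSV path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels[c("trial_id", paste0("rater", 1:4))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ----------------------------------------------------------- feature table --

#' Construct a trials-by-features table
#'
#' @param trial_id Integer trial ids.
#' @param label Factor or character, `"VTE"` / `"nonVTE"`.
#' @param features Numeric matrix or data frame (trials x features) with
#'   unique column names and no missing values.
#' @return A `feature_table` (data frame subclass).
#' @export
feature_table <- function(trial_id, label, features) {
  features <- as.data.frame(features)
  if (anyDuplicated(names(features))) stop("feature names must be unique")
  if (any(!vapply(features, is.numeric, logical(1))))
    stop("features must be numeric")
  if (anyNA(features)) stop("feature table must not contain missing values")
  if (!all(label %in% c("VTE", "nonVTE")))
    stop("labels must be 'VTE' or 'nonVTE'")
  stopifnot(length(trial_id) == nrow(features), length(label) == nrow(features))
  out <- cbind(data.frame(trial_id = trial_id,
                          label = as.character(label)), features)
  structure(out, class = c("feature_table", "data.frame"))
}

#' Feature names of a feature table
#' @param table A `feature_table`.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) setdiff(names(table), c("trial_id", "label"))

#' Write a feature table to CSV at full double precision
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(table, path) {
  if (anyNA(table)) stop("refusing to write a feature table with missing values")
  out <- table
  for (nm in feature_names(table)) out[[nm]] <- fmt_num(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV file path.
#' @param schema Optional character vector of expected feature names; unknown
#'   columns are a schema error.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("trial_id", "label") %in% names(df)))
    stop("feature CSV needs trial_id and label columns")
  feats <- setdiff(names(df), c("trial_id", "label"))
  if (!is.null(schema)) {
    unknown <- setdiff(feats, schema)
    if (length(unknown)) stop("unknown feature columns: ",
                              paste(unknown, collapse = ", "))
  }
  feature_table(df$trial_id, df$label, df[feats])
}

# full-precision numeric formatting for CSV round-trips
fmt_num <- function(x) sprintf("%.17g", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
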