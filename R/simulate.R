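# Synthetic plus-maze sessions with matching field potentials.
#
# The generator states the world the detection method assumes: sessions of
# ~60 trials with VTEs on ~20% of them; non-VTE choice trajectories are
# smooth arcs from a north/south start arm through the center platform to an
# east/west reward arm, while VTE trajectories insert 1-3 head sweeps toward
# the unchosen arm (partial advance, reversal, reorientation) that lengthen
# the trial; the field potential is asymmetric theta (a phase-warped 8 Hz
# wave whose ascending/descending ratio realizes exp(ai_target)) plus
# theta-phase-modulated low (45 Hz) and high (80 Hz) gamma bursts with
# class-conditional power targets and 1/f background noise.  Four rater vote
# sets are derived from ground truth with independent flip errors.

#' Simulator configuration
#'
#' Defaults state the task and effect sizes the pipeline is designed for:
#' 60-trial sessions, 20% VTEs, 35 Hz tracking, 1 kHz field potentials with
#' 8 Hz theta, positive theta asymmetry that is larger on VTE trials, low
#' gamma elevated and high gamma slightly depressed on VTE choices, and a
#' 5% independent rater error rate (which keeps agreement above 90% and
#' kappa above 0.7).  Class-conditional entries are named vectors
#' `c(nonVTE = ., VTE = .)`.
#'
#' @param n_trials Trials per session.
#' @param vte_fraction Probability a trial is a VTE.
#' @param frame_rate Camera frame rate, Hz.
#' @param lfp_fs Field-potential sampling rate, Hz.
#' @param theta_freq Theta frequency, Hz.
#' @param ai_target Theta asymmetry index per class (dimensionless).
#' @param lg_power_target,hg_power_target Relative gamma band power per
#'   class (z-units^2; only ratios between classes are identifiable after
#'   session-level normalization).
#' @param sweep_count_range Min/max head sweeps per class.
#' @param choice_duration Mean non-VTE choice duration, seconds; each sweep
#'   adds `sweep_duration`.
#' @param sweep_duration Extra seconds per head sweep.
#' @param return_duration Return epoch duration, seconds.
#' @param delay_duration Delay epoch duration, seconds (task-fixed 10 s).
#' @param position_noise_sd Frame-to-frame tracking noise, maze units.
#' @param rater_error_rate Per-rater independent label flip probability.
#' @param arm_length,center_half_width Maze geometry, maze units.
#' @param gamma_amp Gamma carrier amplitude at power target 1.
#' @param noise_amp Broadband 1/f noise SD relative to unit theta.
#' @param epoch_effects Named logical: which epochs carry the
#'   class-conditional LFP effects (default: choice only, so delay-epoch
#'   features are uninformative, as observed in the task this emulates).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trials = 60, vte_fraction = 0.20, frame_rate = 35,
                       lfp_fs = 1000, theta_freq = 8,
                       ai_target = c(nonVTE = 0.10, VTE = 0.20),
                       lg_power_target = c(nonVTE = 1.0, VTE = 1.5),
                       hg_power_target = c(nonVTE = 1.0, VTE = 0.85),
                       sweep_count_range = list(nonVTE = c(0, 0), VTE = c(1, 3)),
                       choice_duration = 2.0, sweep_duration = 0.8,
                       return_duration = 4, delay_duration = 10,
                       position_noise_sd = 1.0, rater_error_rate = 0.05,
                       arm_length = 100, center_half_width = 15,
                       gamma_amp = 0.35, noise_amp = 0.15,
                       epoch_effects = c(choice = TRUE, return = FALSE,
                                         delay = FALSE)) {
  stopifnot(vte_fraction > 0, vte_fraction < 1, frame_rate > 0, lfp_fs > 0,
            theta_freq > 0)
  structure(as.list(environment()), class = "sim_config")
}

ARM_TIPS <- list(north = c(0, 1), south = c(0, -1),
                 east = c(1, 0), west = c(-1, 0))

# quintic smoothstep: zero velocity and acceleration at both ends
smoothstep <- function(u) u^3 * (10 - 15 * u + 6 * u^2)

# cubic Bezier with both control points on the center platform, so the path
# runs down the start arm, corners across the center, and out the chosen arm
bezier_center <- function(p0, p2, u) {
  cbind((1 - u)^3 * p0[1] + u^3 * p2[1],
        (1 - u)^3 * p0[2] + u^3 * p2[2])
}

#' Simulate one choice-epoch trajectory
#'
#' Non-VTE: a smooth arc from the start-arm tip through the center to the
#' chosen-arm tip.  VTE: the same backbone with head-sweep excursions toward
#' the unchosen arm inserted at the center, each a partial advance, reversal
#' and reorientation that also lengthens the trial.
#'
#' @param kind `"VTE"` or `"nonVTE"`.
#' @param cfg A [sim_config()].
#' @param start_arm `"north"` or `"south"`.
#' @param chosen_arm `"east"` or `"west"`.
#' @param t0 Start time in seconds.
#' @return A [position_trace()]; the sweep count is in `attr(, "sweeps")`.
#' @export
simulate_trajectory <- function(kind = c("nonVTE", "VTE"), cfg = sim_config(),
                                start_arm = "south", chosen_arm = "east",
                                t0 = 0) {
  kind <- match.arg(kind)
  L <- cfg$arm_length
  p0 <- ARM_TIPS[[start_arm]] * L
  p2 <- ARM_TIPS[[chosen_arm]] * L
  rng <- cfg$sweep_count_range[[kind]]
  sweeps <- if (rng[2] > rng[1]) sample(rng[1]:rng[2], 1) else rng[1]
  dur <- cfg$choice_duration + sweeps * cfg$sweep_duration +
    stats::rnorm(1, 0, 0.15 * cfg$choice_duration)
  dur <- max(dur, 1.0)
  dur <- round(dur * cfg$lfp_fs) / cfg$lfp_fs   # align epochs to the LFP grid
  n <- max(floor(dur * cfg$frame_rate), 12L)
  tt <- seq(0, by = 1 / cfg$frame_rate, length.out = n)
  w <- tt / dur

  if (sweeps == 0L) {
    u <- smoothstep(w)
    xy <- bezier_center(p0, p2, u)
  } else {
    # pause the backbone mid-run while the head sweeps toward the unchosen arm
    pause <- c(0.35, 0.65)
    u_prog <- ifelse(w < pause[1], w / pause[1] * 0.5,
                     ifelse(w > pause[2],
                            0.5 + (w - pause[2]) / (1 - pause[2]) * 0.5, 0.5))
    u <- smoothstep(pmin(pmax(u_prog, 0), 1))
    xy <- bezier_center(p0, p2, u)
    unchosen <- ARM_TIPS[[setdiff(c("east", "west"), chosen_arm)]]
    inwin <- w >= pause[1] & w <= pause[2]
    s <- (w - pause[1]) / (pause[2] - pause[1])
    amp <- 1.8 * cfg$center_half_width
    bump <- amp * sin(pi * pmin(pmax(s, 0), 1) * sweeps)^2
    xy[, 1] <- xy[, 1] + ifelse(inwin, bump * unchosen[1], 0)
    xy[, 2] <- xy[, 2] + ifelse(inwin, bump * unchosen[2], 0)
  }
  xy <- xy + matrix(stats::rnorm(2 * n, 0, cfg$position_noise_sd), ncol = 2)
  out <- position_trace(t0 + tt, xy[, 1], xy[, 2])
  attr(out, "sweeps") <- sweeps
  attr(out, "duration") <- dur
  out
}

# internal path for return/delay epochs (not class-conditional)
filler_positions <- function(cfg, from, to, dur, t0, kind = c("move", "hold")) {
  kind <- match.arg(kind)
  n <- max(floor(dur * cfg$frame_rate), 4L)
  tt <- seq(0, by = 1 / cfg$frame_rate, length.out = n)
  L <- cfg$arm_length
  if (kind == "move") {
    u <- smoothstep(tt / dur)
    xy <- bezier_center(ARM_TIPS[[from]] * L, ARM_TIPS[[to]] * L, u)
  } else {
    xy <- matrix(rep(ARM_TIPS[[from]] * L, each = n), ncol = 2)
  }
  xy <- xy + matrix(stats::rnorm(2 * n, 0, cfg$position_noise_sd), ncol = 2)
  data.frame(t = t0 + tt, x = xy[, 1], y = xy[, 2])
}

#' Simulate a field-potential epoch
#'
#' Asymmetric theta from a monotone phase warp of a sinusoid (the warp sets
#' the ascending/descending duration ratio to `exp(ai_target)` while
#' preserving the period exactly), low-gamma bursts centered near the
#' ascending phase and high-gamma bursts near the theta peak (both
#' amplitude-modulated by theta phase, powers set by the class targets),
#' plus 1/f broadband noise.
#'
#' @param kind `"VTE"` or `"nonVTE"` (selects the class-conditional
#'   parameters).
#' @param duration Seconds (>= 1 recommended).
#' @param cfg A [sim_config()].
#' @param normalize Z-score the segment (default `TRUE`; session assembly
#'   z-scores the whole trace instead).
#' @return An [lfp_segment()] at `cfg$lfp_fs`.
#' @export
simulate_lfp <- function(kind = c("nonVTE", "VTE"), duration = 2,
                         cfg = sim_config(), normalize = TRUE) {
  kind <- match.arg(kind)
  fs <- cfg$lfp_fs
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  ai <- cfg$ai_target[[kind]]
  fd <- 1 / (1 + exp(ai))   # descending (peak->trough) fraction of the cycle
  u <- (cfg$theta_freq * t) %% 1
  # smooth monotone phase warp: v(u) = u - A (1 - cos 2 pi u) / 2 pi places
  # the trough at u = fd while keeping the waveform locally symmetric around
  # peaks and troughs (no slope kink for the lowpass to shift)
  A <- if (abs(fd - 0.5) < 1e-12) 0 else
    (fd - 0.5) * 2 * pi / (1 - cos(2 * pi * fd))
  v <- u - A * (1 - cos(2 * pi * u)) / (2 * pi)
  theta <- cos(2 * pi * v)

  # burst centers at the symmetric cycle landmarks (trough for low gamma,
  # peak for high gamma) so amplitude modulation cannot bias the
  # ascending/descending split the asymmetry index measures
  env_lg <- 0.5 - 0.5 * cos(2 * pi * v)   # trough preference
  env_hg <- 0.5 + 0.5 * cos(2 * pi * v)   # peak preference
  ph <- stats::runif(2, 0, 2 * pi)
  lg <- sqrt(cfg$lg_power_target[[kind]]) * cfg$gamma_amp * env_lg *
    cos(2 * pi * 45 * t + ph[1])
  hg <- sqrt(cfg$hg_power_target[[kind]]) * cfg$gamma_amp * env_hg *
    cos(2 * pi * 80 * t + ph[2])

  noise <- 0
  if (cfg$noise_amp > 0) {
    m <- stats::nextn(n, c(2, 3, 5))   # keep the FFT length friendly
    white <- stats::rnorm(m)
    xf <- stats::fft(white)
    f <- pmin(0:(m - 1), m - (0:(m - 1))) * fs / m
    xf <- xf / sqrt(pmax(f, 1))
    pink <- Re(stats::fft(xf, inverse = TRUE))[seq_len(n)] / m
    noise <- cfg$noise_amp * pink / stats::sd(pink)
  }
  x <- theta + lg + hg + noise
  if (normalize) x <- pop_z(x)
  lfp_segment(x, fs = fs, epoch = "choice")
}

#' Simulate a full plus-maze session
#'
#' Assembles `n_trials` trials with random start arms, alternation-rule
#' reward flags, choice/return/delay epochs (delay fixed at
#' `cfg$delay_duration`), ground-truth VTE labels drawn at `vte_fraction`,
#' head positions for every epoch, an epoch-aligned continuous field
#' potential (class-conditional effects only in the epochs named by
#' `cfg$epoch_effects`), and four rater vote sets derived from truth with
#' independent flip probability `rater_error_rate`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the session is fully reproducible from it.
#' @return A `sim_session` list: `positions` ([session_positions()]),
#'   `trials` ([trial_epochs()]), `lfp` ([lfp_trace()], z-scored),
#'   `truth` (per-trial `"VTE"`/`"nonVTE"`), `votes` (rater data frame),
#'   `ground_truth` (per-trial generative parameters).
#' @export
simulate_session <- function(cfg = sim_config(), seed = 1) {
  with_seed(seed, {
    n <- cfg$n_trials
    truth <- ifelse(stats::runif(n) < cfg$vte_fraction, "VTE", "nonVTE")
    start_arm <- sample(c("north", "south"), n, replace = TRUE)
    chosen_arm <- character(n)
    prev <- sample(c("east", "west"), 1)
    for (i in seq_len(n)) {
      correct <- setdiff(c("east", "west"), prev)
      chosen_arm[i] <- if (stats::runif(1) < 0.8) correct else prev
      prev <- chosen_arm[i]
    }
    rewarded <- c(TRUE, chosen_arm[-1] != chosen_arm[-n])

    frames <- list(); lfp_parts <- list(); rows <- list(); gt <- list()
    cursor <- 0
    for (i in seq_len(n)) {
      tr <- simulate_trajectory(truth[i], cfg, start_arm[i], chosen_arm[i],
                                t0 = cursor)
      cdur <- attr(tr, "duration")
      next_start <- if (i < n) start_arm[i + 1] else sample(c("north", "south"), 1)
      ret <- filler_positions(cfg, chosen_arm[i], next_start,
                              cfg$return_duration, cursor + cdur, "move")
      dly <- filler_positions(cfg, next_start, next_start, cfg$delay_duration,
                              cursor + cdur + cfg$return_duration, "hold")
      frames[[i]] <- rbind(data.frame(t = tr$t, x = tr$x, y = tr$y), ret, dly)

      ekind <- function(ep) if (isTRUE(cfg$epoch_effects[[ep]])) truth[i] else "nonVTE"
      lfp_parts[[i]] <- c(
        simulate_lfp(ekind("choice"), cdur, cfg, normalize = FALSE)$samples,
        simulate_lfp(ekind("return"), cfg$return_duration, cfg,
                     normalize = FALSE)$samples,
        simulate_lfp(ekind("delay"), cfg$delay_duration, cfg,
                     normalize = FALSE)$samples)

      rows[[i]] <- data.frame(
        trial_id = i, start_arm = start_arm[i], chosen_arm = chosen_arm[i],
        rewarded = rewarded[i],
        choice_start = cursor, choice_end = cursor + cdur,
        return_start = cursor + cdur,
        return_end = cursor + cdur + cfg$return_duration,
        delay_start = cursor + cdur + cfg$return_duration,
        delay_end = cursor + cdur + cfg$return_duration + cfg$delay_duration)
      gt[[i]] <- data.frame(trial_id = i, kind = truth[i],
                            sweeps = attr(tr, "sweeps"),
                            choice_duration = cdur,
                            ai_target = cfg$ai_target[[truth[i]]],
                            lg_target = cfg$lg_power_target[[truth[i]]],
                            hg_target = cfg$hg_power_target[[truth[i]]])
      cursor <- cursor + cdur + cfg$return_duration + cfg$delay_duration
    }

    allf <- do.call(rbind, frames)
    positions <- session_positions(allf$t, allf$x, allf$y,
                                   session_id = paste0("sim-seed", seed),
                                   nominal_rate = cfg$frame_rate)
    lfp <- lfp_trace(pop_z(unlist(lfp_parts)), fs = cfg$lfp_fs,
                     session_id = paste0("sim-seed", seed))
    votes <- as.data.frame(lapply(1:4, function(r) {
      flip <- stats::runif(n) < cfg$rater_error_rate
      ifelse(flip, ifelse(truth == "VTE", "nonVTE", "VTE"), truth)
    }))
    names(votes) <- paste0("rater", 1:4)
    votes <- cbind(data.frame(trial_id = seq_len(n)), votes)

    structure(list(positions = positions,
                   trials = trial_epochs(do.call(rbind, rows),
                                         delay_duration = cfg$delay_duration),
                   lfp = lfp, truth = truth, votes = votes,
                   ground_truth = do.call(rbind, gt),
                   config = cfg, seed = seed),
              class = "sim_session")
  })
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> seed %d: %d trials (%d VTE), %.0f s, LFP %d kHz\n",
              x$seed, length(x$truth), sum(x$truth == "VTE"),
              max(x$trials$delay_end), x$lfp$fs / 1000))
  invisible(x)
}

#' Simulate a plain Gaussian feature table
#'
#' Balanced two-class table of independent normal features with a mean
#' shift `effect` on VTE trials; `effect = 0` gives completely
#' uninformative features (the chance-calibration world).
#'
#' @param n_per_class Trials per class.
#' @param n_features Number of feature columns.
#' @param effect Mean shift (in SDs) of every feature on VTE trials.
#' @param seed Integer seed.
#' @return A [feature_table()].
#' @export
simulate_gaussian_features <- function(n_per_class = 142, n_features = 7,
                                       effect = 0, seed = 1) {
  with_seed(seed, {
    n <- 2L * n_per_class
    label <- rep(c("VTE", "nonVTE"), each = n_per_class)
    shift <- ifelse(label == "VTE", effect, 0)
    feats <- sapply(seq_len(n_features), function(j) stats::rnorm(n) + shift)
    colnames(feats) <- paste0("f", seq_len(n_features))
    feature_table(seq_len(n), label, feats)
  })
}
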