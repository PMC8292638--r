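# Independent oracles and small fixture builders shared across the suite.

# brute-force integrated heading change on raw coordinates
oracle_idphi <- function(x, y, wrap = TRUE) {
  phi <- atan2(diff(y), diff(x))
  d <- abs(diff(phi))
  if (wrap) d <- pmin(d, 2 * pi - d)
  sum(d)
}

# exhaustive pairwise-concordance AUC (ties count one half)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == "VTE"]
  neg <- scores[truth != "VTE"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# degree-6 r^2 by direct normal equations on centered/scaled x
oracle_r2 <- function(x, y, degree = 6) {
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  V <- outer(xs, 0:degree, `^`)
  beta <- solve(t(V) %*% V, t(V) %*% y)
  yh <- as.numeric(V %*% beta)
  1 - sum((y - yh)^2) / sum((y - mean(y))^2)
}

# densely sampled quarter-circle arc (heading sweeps pi/2)
arc_trace <- function(n = 200, r = 50) {
  th <- seq(0, pi / 2, length.out = n)
  position_trace(seq_len(n) / 35, r * cos(th), r * sin(th))
}

straight_trace <- function(n = 20, dx = 1, dy = 0) {
  position_trace(seq_len(n) / 35, dx * seq_len(n), dy * seq_len(n))
}

# phase-warped theta wave whose ascending/descending ratio is exp(ai)
warped_theta <- function(ai, freq = 8, fs = 1000, duration = 2) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  fd <- 1 / (1 + exp(ai))
  u <- (freq * t) %% 1
  A <- if (abs(fd - 0.5) < 1e-12) 0 else
    (fd - 0.5) * 2 * pi / (1 - cos(2 * pi * fd))
  cos(2 * pi * (u - A * (1 - cos(2 * pi * u)) / (2 * pi)))
}

pure_tone <- function(freq, fs = 1000, duration = 1, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, duration - 1 / fs, by = 1 / fs))
}

# curate + extract every feature modality for several sessions and pool the
# trials (the published analysis pools trials across sessions and animals)
pooled_features <- function(cfg, seeds) {
  offset <- 0
  traj <- list(); oscc <- list(); oscd <- list()
  for (k in seq_along(seeds)) {
    s <- simulate_session(cfg, seed = seeds[k])
    noisy <- noise_exclusion(s$lfp, s$trials, "choice")
    lab <- curate_labels(s$votes, noise_excluded = noisy)
    keep <- lab$consensus != "excluded"
    ids <- lab$trial_id[keep]; ll <- lab$consensus[keep]
    traces <- lapply(ids, function(id)
      slice_epoch(s$positions, s$trials, id, "choice"))
    tt <- suppressWarnings(session_trajectory_features(
      traces, trial_id = ids, label = ll,
      choice_region = default_choice_region(cfg$center_half_width)))
    ep <- s$trials[s$trials$trial_id %in% ids, , drop = FALSE]
    oc <- suppressWarnings(session_osc_features(s$lfp, ep, "choice", label = ll))
    od <- suppressWarnings(session_osc_features(s$lfp, ep, "delay", label = ll))
    shift <- function(tb) { tb$trial_id <- tb$trial_id + offset; tb }
    traj[[k]] <- shift(tt); oscc[[k]] <- shift(oc); oscd[[k]] <- shift(od)
    offset <- offset + cfg$n_trials
  }
  bindft <- function(lst) {
    df <- do.call(rbind, lapply(lst, as.data.frame))
    feature_table(df$trial_id, df$label,
                  df[setdiff(names(df), c("trial_id", "label"))])
  }
  t_all <- bindft(traj); c_all <- bindft(oscc); d_all <- bindft(oscd)
  common <- Reduce(intersect,
                   list(t_all$trial_id, c_all$trial_id, d_all$trial_id))
  subft <- function(tb) {
    i <- match(common, tb$trial_id)
    feature_table(common, tb$label[i], tb[i, feature_names(tb), drop = FALSE])
  }
  t_all <- subft(t_all); c_all <- subft(c_all); d_all <- subft(d_all)
  comb <- feature_table(common, t_all$label,
                        cbind(as.data.frame(t_all)[feature_names(t_all)],
                              as.data.frame(c_all)[feature_names(c_all)]))
  list(traj = t_all, osc_choice = c_all, osc_delay = d_all, combined = comb,
       labels = data.frame(trial_id = common, consensus = t_all$label))
}

# one shared mid-sized simulated session, built lazily and reused
.fixture_env <- new.env(parent = emptyenv())
shared_session <- function() {
  if (is.null(.fixture_env$session))
    .fixture_env$session <- simulate_session(sim_config(n_trials = 40),
                                             seed = 101)
  .fixture_env$session
}
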