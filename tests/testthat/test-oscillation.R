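# Theta-cycle segmentation, asymmetry, gamma power, PSD features.

test_that("preprocessing decimates to 1 kHz and z-scores the session", {
  t <- seq(0, 1 - 1 / 30000, by = 1 / 30000)
  raw <- 250 * sin(2 * pi * 8 * t) + 40
  lfp <- preprocess_lfp(raw)
  expect_identical(length(lfp$samples), 1000L)
  expect_equal(lfp$fs, 1000)
  expect_equal(mean(lfp$samples), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(lfp$samples^2)), 1, tolerance = 1e-10)
  # spectral peak survives at 8 Hz
  psd <- compute_psd(lfp$samples, fs = 1000)
  expect_equal(which.max(psd$power), 8L)
  expect_error(preprocess_lfp(rep(1, 3e4)), "constant")
})

test_that("a pure 8 Hz second yields 7 symmetric 125 ms cycles", {
  filt <- lowpass_for_cycles(pure_tone(8, 1000, 1, amp = 1), fs = 1000)
  cyc <- detect_theta_cycles(filt, 1000)
  expect_identical(nrow(cyc), 7L)
  expect_true(all(abs(cyc$total_ms - 125) <= 1))
  expect_true(all(abs(asymmetry_index(cyc)) <= 0.02))
  expect_true(all(cyc$asc_ms + cyc$desc_ms == cyc$total_ms))
  # consecutive cycles share boundary peaks
  expect_equal(cyc$peak_idx[-1], cyc$next_peak_idx[-nrow(cyc)])
})

test_that("asymmetric waves give asc/desc in the generated ratio", {
  w <- warped_theta(log(3), fs = 1000, duration = 3)
  cyc <- detect_theta_cycles(lowpass_for_cycles(w, fs = 1000), 1000)
  expect_gt(nrow(cyc), 15)
  expect_equal(mean(cyc$asc_ms) / mean(cyc$desc_ms), 3, tolerance = 0.1)
})

test_that("the 83.3 ms separation rule merges peaks of fast oscillations", {
  filt <- lowpass_for_cycles(pure_tone(20, 1000, 2), fs = 1000)
  cyc <- detect_theta_cycles(filt, 1000)
  gaps <- diff(sort(unique(c(cyc$peak_idx, cyc$next_peak_idx))))
  expect_true(all(gaps >= 83))
  expect_lt(nrow(cyc), 2 / 0.05 * 0.75)   # far fewer than one per 50 ms period
  expect_gte(nrow(cyc), floor(2 / 0.0833 / 2))
})

test_that("asymmetry index closed forms and antisymmetry hold", {
  expect_equal(asymmetry_index(62.5, 62.5), 0)
  expect_equal(asymmetry_index(100, 50), log(2))
  expect_equal(asymmetry_index(50, 100), -asymmetry_index(100, 50))
  expect_error(asymmetry_index(0, 10), "positive")
})

test_that("gamma envelope of a unit-SD tone has power 2 in band, 0 out", {
  tone <- pure_tone(45, 1000, 2)
  lg <- gamma_envelope(tone, "low", fs = 1000)
  mid <- 300:1700
  expect_equal(mean(lg$p[mid]), 2, tolerance = 0.02)
  expect_lt(max(abs(lg$p[mid] - 2)) / 2, 0.05)  # constant within 5%
  hg <- gamma_envelope(tone, "high", fs = 1000, normalize = FALSE)
  expect_lt(mean(hg$p[mid]), 0.01)
  expect_error(gamma_envelope(tone, band = c(400, 600), fs = 1000), "Nyquist")
})

test_that("gamma ratio follows closed forms and is local to cycles", {
  cyc <- data.frame(peak_idx = c(1L, 126L), trough_idx = c(63L, 188L),
                    next_peak_idx = c(126L, 251L))
  p <- rep(2, 300)
  env <- function(p) structure(list(band = c(35, 55), g = sqrt(p), p = p),
                               class = "gamma_envelope")
  expect_equal(gamma_ratio(cyc, env(p), env(p)), c(1, 1))
  expect_equal(gamma_ratio(cyc, env(2 * p), env(p)), c(2, 2))
  # a burst confined to the second cycle changes only that cycle
  p2 <- p; p2[130:200] <- 10
  gr <- gamma_ratio(cyc, env(p2), env(p))
  expect_equal(gr[1], 1)
  expect_gt(gr[2], 1)
})

test_that("the oscillation feature vector has 12 entries and sane limits", {
  set.seed(5)
  cfg <- sim_config(ai_target = c(nonVTE = 0, VTE = 0),
                    lg_power_target = c(nonVTE = 1, VTE = 1),
                    hg_power_target = c(nonVTE = 1, VTE = 1))
  f <- extract_osc_features(simulate_lfp("nonVTE", 2, cfg),
                            normalize_gamma = FALSE)
  expect_length(f, 12L)
  expect_named(f, c("ai_mean", "ai_sd", "asc_mean", "desc_mean", "lg_mean",
                    "lg_sd", "hg_mean", "hg_sd", "gr_mean", "gr_sd",
                    "cycdur_mean", "cycdur_sd"))
  expect_equal(unname(f["ai_mean"]), 0, tolerance = 0.1)
  expect_equal(unname(f["cycdur_mean"]), 125, tolerance = 5)
  expect_equal(unname(f["gr_mean"]), 1, tolerance = 0.25)
  short <- lfp_segment(pure_tone(8, 1000, 0.4), fs = 1000)
  expect_error(extract_osc_features(short), "cycles")
})

test_that("periodogram concentrates tone power and satisfies Parseval", {
  psd <- compute_psd(pure_tone(10, 1000, 2), fs = 1000)
  expect_length(psd$power, 100L)
  expect_equal(psd$freqs, 1:100)
  expect_equal(which.max(psd$power), 10L)
  expect_gt(sum(psd$power[9:11]) / sum(psd$power), 0.95)
  set.seed(8)
  x <- rnorm(2000)
  psd2 <- compute_psd(x, fs = 1000)
  # flat spectrum: the 1-100 Hz band holds its share of the variance
  # (one-sided density 2 sigma^2 / fs per Hz)
  expect_equal(sum(psd2$power), 100 * 2 * var(x) / 1000, tolerance = 0.15)
  expect_lt(sd(psd2$power) / mean(psd2$power), 1.2)
  expect_error(compute_psd(rnorm(500), fs = 1000), "1 Hz")
})

test_that("PSD feature selection finds injected bands and rejects nulls", {
  set.seed(13)
  n <- 40
  base <- t(replicate(2 * n, compute_psd(rnorm(1200), fs = 1000)$power))
  colnames(base) <- paste0("psd_", 1:100)
  labs <- rep(c("VTE", "nonVTE"), each = n)
  # class difference only at 40-50 Hz
  shifted <- base
  shifted[labs == "VTE", 40:50] <- shifted[labs == "VTE", 40:50] * 3
  tab <- feature_table(seq_len(2 * n), labs, shifted)
  keep <- select_psd_features(tab)
  freqs <- as.integer(sub("psd_", "", keep))
  expect_gt(length(freqs), 5)
  # survivors concentrate on the injected band (BH allows ~5% stragglers)
  expect_gte(mean(freqs >= 38 & freqs <= 52), 0.8)
  null_tab <- feature_table(seq_len(2 * n), labs, base)
  expect_warning(none <- select_psd_features(null_tab), "no PSD")
  expect_length(none, 0L)
})
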