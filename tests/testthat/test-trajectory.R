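# Trajectory features: heading integration, spread, fit quality.

test_that("heading is axis-aligned for straight walks and sweeps on arcs", {
  expect_equal(compute_heading(straight_trace(dx = 1, dy = 0))$phi,
               rep(0, 19))
  expect_equal(compute_heading(straight_trace(dx = 0, dy = 1))$phi,
               rep(pi / 2, 19))
  h <- compute_heading(arc_trace(200))
  expect_true(all(diff(h$phi) > 0))                    # monotone sweep
  expect_equal(abs(h$phi[length(h$phi)] - h$phi[1]), pi / 2, tolerance = 0.05)
  still <- position_trace(1:3, rep(1, 3), rep(2, 3))
  expect_error(compute_heading(still), "degenerate")
})

test_that("IdPhi matches closed forms and the brute-force oracle", {
  expect_equal(compute_idphi(compute_heading(straight_trace())), 0)
  expect_equal(compute_idphi(compute_heading(arc_trace(400))), pi / 2,
               tolerance = 0.01)
  # out-and-back reversal contributes a turn of at least pi
  out_back <- position_trace(1:21, c(1:11, 10:1), rep(0, 21))
  expect_gte(compute_idphi(compute_heading(out_back)), pi)
  set.seed(31)
  for (i in 1:20) {
    x <- cumsum(rnorm(30)); y <- cumsum(rnorm(30))
    tr <- position_trace(1:30, x, y)
    expect_equal(compute_idphi(compute_heading(tr)), oracle_idphi(x, y))
  }
})

test_that("IdPhi is invariant under rotation and translation", {
  set.seed(7)
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(40))
  base <- compute_idphi(compute_heading(position_trace(1:40, x, y)))
  for (th in c(0.3, 1.2, 2.9)) {
    xr <- cos(th) * x - sin(th) * y + 17
    yr <- sin(th) * x + cos(th) * y - 4
    expect_equal(compute_idphi(compute_heading(position_trace(1:40, xr, yr))),
                 base, tolerance = 1e-10)
  }
})

test_that("inserting a head sweep never decreases IdPhi", {
  set.seed(12)
  for (i in 1:10) {
    x <- seq(0, 30, length.out = 40) + rnorm(40, 0, 0.05)
    y <- rnorm(40, 0, 0.05)
    base <- compute_idphi(compute_heading(position_trace(1:40, x, y)))
    xs <- append(x, x[20] + c(3, 6, 3), after = 20)  # excursion and return
    ys <- append(y, c(4, 8, 4), after = 20)
    more <- compute_idphi(compute_heading(position_trace(1:43, xs, ys)))
    expect_gte(more, base)
  }
})

test_that("session z-scoring has population moments and affine invariance", {
  expect_equal(zscore_by_session(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(zscore_by_session(c(-5, 5)), c(-1, 1))
  expect_error(zscore_by_session(rep(2, 10)), "constant")
  set.seed(3)
  v <- rnorm(50)
  expect_equal(zscore_by_session(3.7 * v - 11), zscore_by_session(v))
})

test_that("position SDs use divisor N and match the circle second moment", {
  expect_equal(position_sds(position_trace(1:3, c(0, 1, 2), rep(5, 3))),
               c(x_sd = sqrt(2 / 3), y_sd = 0))
  th <- seq(0, 2 * pi, length.out = 2001)[-2001]
  circ <- position_trace(seq_along(th), 3 * cos(th), 3 * sin(th))
  expect_equal(unname(position_sds(circ)), rep(3 / sqrt(2), 2),
               tolerance = 1e-3)
})

test_that("choice dwell time follows the frame-count oracle", {
  region <- default_choice_region(10)
  inside <- position_trace(seq(0, 2, length.out = 21), rep(0, 21), rep(0, 21))
  expect_equal(choice_duration(inside, region), 2)
  outside <- position_trace(1:10, rep(50, 10), rep(50, 10))
  expect_warning(d0 <- choice_duration(outside, region), "never enters")
  expect_equal(d0, 0)
  # first half of frames inside at uniform rate -> about half the span
  half <- position_trace(seq(0, 1, length.out = 40),
                         seq(0.5, 20, length.out = 40), rep(0, 40))
  expect_equal(choice_duration(half, region), 0.5, tolerance = 0.1)
})

test_that("degree-6 fits are exact on polynomials and match the oracle", {
  x <- seq(-2, 2, length.out = 40)
  sq <- poly_fit_r2(position_trace(1:40, x, x^2))
  expect_equal(sq$r2, 1, tolerance = 1e-10)
  y6 <- 1 - x + 0.5 * x^3 - 0.1 * x^6
  expect_equal(poly_fit_r2(position_trace(1:40, x, y6))$r2, 1,
               tolerance = 1e-6)
  set.seed(9)
  for (i in 1:10) {
    xs <- sort(rnorm(50)); ys <- sin(3 * xs) + rnorm(50, 0, 0.3)
    fit <- poly_fit_r2(position_trace(1:50, xs, ys))
    expect_equal(fit$r2, oracle_r2(xs, ys), tolerance = 1e-6)
  }
  expect_error(poly_fit_r2(position_trace(1:40, x, rep(1, 40))), "SST")
})

test_that("Fourier coefficient counts match line-spectrum oracles", {
  expect_equal(fourier_coef_count(rep(3.2, 64)), 0L)
  t <- seq(0, 1, length.out = 65)[-65]
  expect_equal(fourier_coef_count(sin(2 * pi * 4 * t)), 1L)
  expect_equal(fourier_coef_count(sin(2 * pi * 4 * t) + sin(2 * pi * 9 * t)), 2L)
})

test_that("assembled trajectory features behave on canonical inputs", {
  tr <- straight_trace(40, dx = 2, dy = 1)
  f <- extract_trajectory_features(tr, session_idphis = c(0, 1, 2),
                                   choice_region = default_choice_region(1e4))
  expect_equal(unname(f["idphi"]), 0)
  expect_equal(unname(f["r2"]), 1, tolerance = 1e-8)
  expect_lte(f["n_coef"], 1)
  s <- shared_session()
  ids <- s$trials$trial_id
  traces <- lapply(ids, function(id)
    slice_epoch(s$positions, s$trials, id, "choice"))
  ft <- session_trajectory_features(traces, trial_id = ids, label = s$truth,
    choice_region = default_choice_region(s$config$center_half_width))
  z <- ft$zidphi
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  # simulated VTEs integrate more heading change than non-VTEs
  expect_gt(mean(ft$idphi[ft$label == "VTE"]),
            mean(ft$idphi[ft$label == "nonVTE"]))
})

test_that("zIdPhi threshold scan maximizes the two-point ROC area", {
  z <- c(rnorm(70, 0), rnorm(30, 6))
  labs <- rep(c("nonVTE", "VTE"), c(70, 30))
  fit <- zidphi_threshold_classifier(z, labs)
  expect_equal(fit$area, 1)                       # separable within the scan
  expect_true(all(fit$predictions[labs == "VTE"] == "VTE"))
  set.seed(21)
  areas <- replicate(30, {
    zz <- rnorm(1000)
    zidphi_threshold_classifier(zz, sample(rep(c("VTE", "nonVTE"), 500)))$area
  })
  # permutation oracle at large n (threshold selection biases small samples)
  expect_lt(abs(mean(areas) - 0.5), 0.02)
  expect_error(zidphi_threshold_classifier(1:5, rep("VTE", 5)), "both classes")
})
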