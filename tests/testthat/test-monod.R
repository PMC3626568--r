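test_that("noiseless Monod points are recovered to optimizer precision", {
  s <- 10^seq(-4, log10(0.05), length.out = 30)
  pts <- data.frame(s = s, mu = monod_mu(s, 0.705, 0.0026))
  fit <- fit_monod(pts, bootstrap_reps = 50, seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$mu0_hat, 0.705, tolerance = 1e-6)
  expect_equal(fit$Ks_hat, 0.0026, tolerance = 1e-6)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  expect_lte(fit$Ks_ci[1], fit$Ks_hat)
  expect_gte(fit$Ks_ci[2], fit$Ks_hat)
  # fitted curve monotone increasing and bounded by mu0_hat, by construction
  curve_mu <- fit$mu0_hat * s / (fit$Ks_hat + s)
  expect_true(all(diff(curve_mu) > 0))
  expect_true(all(curve_mu <= fit$mu0_hat))
})

test_that("degenerate substrate spans are flagged, not fitted", {
  s <- seq(0.02, 0.05, length.out = 10)  # all s >> Ks, span < 10-fold
  pts <- data.frame(s = s, mu = monod_mu(s, 0.705, 0.0026))
  fit <- fit_monod(pts)
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "unidentifiable")
  expect_error(fit_monod(pts[1:3, ]), "at least 5 points")
})

test_that("deceleration selection pairs rate and substrate consistently", {
  # fine-grid noiseless trajectory: selected (s, mu) points sit on the law
  p <- sim_params(s0 = 0.2)
  tr <- simulate_batch(p, grid = seq(0, 400, by = 0.25))
  ser <- trajectory_series(tr)
  gr <- growth_rate_series(ser, window_min = 0.75)
  ss <- infer_substrate(ser, s0 = p$s0 + p$s_carryover, c = p$c,
                        anchor = "initial", od_offset = p$od0)
  arrest <- detect_arrest(gr)
  pts <- select_deceleration_points(gr, ss, arrest = arrest)
  expect_gte(nrow(pts), 5)
  rel <- pts$mu / monod_mu(pts$s, p$mu0, p$Ks) - 1
  # the windowed rate is a short time average, so the last points before
  # arrest (substrate e-folding time < 1 min) deviate by a few percent
  expect_lt(sqrt(mean(rel^2)), 0.02)
  expect_lt(max(abs(rel)), 0.10)

  # a window that excludes every point (series truncated to exponential
  # phase, all substrate far above the cut) is an error, not an empty frame
  expo <- tr$time <= 150
  ser_exp <- trajectory_series(tr[expo, ])
  gr_exp <- growth_rate_series(ser_exp, window_min = 0.75)
  ss_exp <- infer_substrate(ser_exp, s0 = p$s0 + p$s_carryover, c = p$c,
                            anchor = "initial", od_offset = p$od0)
  expect_error(select_deceleration_points(gr_exp, ss_exp), "points")
})

test_that("wider smoothing windows inflate the apparent Ks (bias audit)", {
  ds <- simulate_growth_panel(calibration_nitrogen_levels(), seed = 1,
                              noise = zero_noise())
  series <- average_replicates(ds)
  fit_for_window <- function(w) {
    pts <- do.call(rbind, lapply(series, function(ser) {
      gr <- growth_rate_series(ser, window_min = w)
      ss <- infer_substrate(ser, s0 = ser$condition$s0, c = 15.1,
                            anchor = "final")
      select_deceleration_points(gr, ss, arrest = detect_arrest(gr),
                                 min_points = 0L)
    }))
    fit_monod(pts, bootstrap_reps = 0)
  }
  f9 <- fit_for_window(9)
  f21 <- fit_for_window(21)
  expect_true(f9$converged && f21$converged)
  # time-averaging over the fast transition smears the knee outward
  expect_gt(f21$Ks_hat, f9$Ks_hat)
  expect_gt(f9$Ks_hat, 0.0026)
})

test_that("measurement-error-aware fit recovers Ks from noiseless plates", {
  nz <- zero_noise()
  ds <- simulate_growth_panel(calibration_nitrogen_levels(), seed = 1,
                              noise = nz)
  series <- average_replicates(ds)
  pts <- do.call(rbind, lapply(series, monod_input_points, c_od = 15.1))
  fit <- fit_monod_eiv(pts, bootstrap_reps = 0)
  expect_equal(fit$Ks_hat, 0.0026, tolerance = 0.05)
  expect_equal(fit$mu0_hat, 0.705, tolerance = 0.02)
})

test_that("parameter recovery holds across seeds at default noise", {
  ks <- sapply(1:10, function(s) nitrogen_study(s)$monod_fit$Ks_hat)
  mu0 <- sapply(1:10, function(s) nitrogen_study(s)$monod_fit$mu0_hat)
  expect_lt(abs(mean(ks) - 0.0026) / 0.0026, 0.15)
  expect_lt(abs(mean(mu0) - 0.705) / 0.705, 0.05)
  # pooled points: a 3-min grid through ~30 min of deceleration per
  # condition leaves a healthy point count
  expect_gte(min(sapply(1:10, function(s)
    nitrogen_study(s)$monod_fit$n_points)), 10)
})
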