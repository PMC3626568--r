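test_that("Monod law has its defining properties and fixed regression value", {
  expect_equal(monod_mu(0.0026, mu0 = 0.705, Ks = 0.0026), 0.705 / 2)
  expect_equal(monod_mu(0, mu0 = 0.705, Ks = 0.0026), 0)
  # frozen regression value: 0.705 * 0.2 / 0.2026
  expect_equal(monod_mu(0.2, mu0 = 0.705, Ks = 0.0026), 0.6959526,
               tolerance = 1e-6)
  s <- seq(0, 5, by = 0.01)
  mu <- monod_mu(s, 0.705, 0.0026)
  expect_true(all(diff(mu) > 0))
  expect_true(all(mu <= 0.705))
  expect_error(monod_mu(-0.1, 0.705, 0.0026), "must be finite and >= 0")
})

test_that("promoter activity model is band-pass with a near-fold_amp peak", {
  pp <- promoter_params(fold_amp = 5, theta_on = 0.25, theta_off = 0.005,
                        h_on = 4, h_off = 4)
  expect_equal(promoter_activity(1e6, pp), pp$pa_basal, tolerance = 1e-6)
  expect_equal(promoter_activity(0, pp), pp$pa_basal)
  # brute-force grid maximization over s in (0, 1]
  s <- seq(1e-4, 1, length.out = 50000)
  peak <- max(promoter_activity(s, pp)) / pp$pa_basal
  expect_gte(peak, 4)
  expect_lte(peak, 5)
  s_peak <- s[which.max(promoter_activity(s, pp))]
  expect_gt(s_peak, pp$theta_off)
  expect_lt(s_peak, pp$theta_on)
})

test_that("parameter containers validate their invariants", {
  expect_error(sim_params(mu0 = -1), "mu0")
  expect_error(sim_params(s0 = -0.1), "s0")
  expect_error(promoter_params(theta_off = 0.3), "theta_off")
  expect_error(promoter_params(fold_amp = 0.5), "fold_amp")
  expect_error(noise_params(read_cv = -0.1), "CVs")
})

test_that("batch simulation respects yield bookkeeping and the conservation law", {
  # Ks -> 0 limit: pure exponential growth, then a hard stop at the yield cap
  p <- sim_params(Ks = 1e-7, s0 = 0.2)
  tr <- simulate_batch(p)
  expect_equal(tail(tr$od, 1), p$od0 + (p$s0 + p$s_carryover) / p$c,
               tolerance = 1e-6)
  early <- tr$time <= 60
  slope <- coef(lm(log(od) ~ time, data = tr[early, ]))[["time"]] * 60
  expect_equal(slope, p$mu0, tolerance = 1e-6)

  set.seed(42)
  for (i in 1:5) {
    p <- sim_params(mu0 = runif(1, 0.3, 1.2), Ks = 10^runif(1, -4, -2),
                    c = runif(1, 10, 25), s0 = runif(1, 0.15, 1),
                    s_carryover = runif(1, 0, 0.15), t_end = 900)
    tr <- simulate_batch(p, grid = seq(0, 900, by = 3))
    S <- p$s0 + p$s_carryover
    err <- max(abs(tr$s + p$c * (tr$od - p$od0) - S))
    expect_lt(err, 10 * p$solver_abs_tol * max(1, p$s0))
    expect_true(all(diff(tr$od) >= -1e-12))
    expect_true(all(diff(tr$s) <= 1e-12))
    expect_true(all(diff(tr$gfp) >= -1e-12))
  }
})

test_that("ODE integrator matches the closed-form Monod batch oracle", {
  set.seed(7)
  for (i in 1:20) {
    p <- sim_params(mu0 = runif(1, 0.3, 1.2), Ks = 10^runif(1, -4, -2),
                    c = runif(1, 10, 25), s0 = runif(1, 0.15, 1.5),
                    s_carryover = runif(1, 0, 0.15),
                    od0 = 10^runif(1, -3, -2), t_end = 5000)
    od_max <- p$od0 + (p$s0 + p$s_carryover) / p$c
    targets <- p$od0 + c(0.1, 0.5, 0.9, 0.999) * (od_max - p$od0)
    t_oracle <- sapply(targets, implicit_monod_time, params = p)
    tr <- simulate_batch(p, grid = sort(unique(c(0, t_oracle))))
    od_sim <- tr$od[match(t_oracle, tr$time)]
    # convert the OD discrepancy at the oracle time into a time offset via
    # the local growth speed dOD/dt = mu(s) * OD
    s_here <- pmax(p$s0 + p$s_carryover - p$c * (od_sim - p$od0), 0)
    speed <- monod_mu(s_here, p$mu0, p$Ks) / 60 * od_sim
    dt_equiv <- abs(od_sim - targets) / speed
    expect_lt(max(dt_equiv), 0.1)
  }
})

test_that("implicit Monod time has exponential limit, monotonicity, domain checks", {
  p <- sim_params(Ks = 1e-9, s0 = 0.2)
  expect_equal(implicit_monod_time(0.01, p), log(0.01 / p$od0) / p$mu0 * 60,
               tolerance = 1e-4)
  p2 <- sim_params(s0 = 0.2)
  expect_equal(implicit_monod_time(p2$od0 * (1 + 1e-12), p2), 0,
               tolerance = 1e-6)
  ods <- seq(0.003, 0.02, length.out = 8)
  expect_true(all(diff(sapply(ods, implicit_monod_time, params = p2)) > 0))
  expect_error(implicit_monod_time(0.5, p2), "od_target")
  expect_error(implicit_monod_time(0.01, sim_params(mode = "regulated")),
               "monod mode")
})

test_that("grid validation and mode requirements are enforced", {
  p <- sim_params(t_end = 100)
  expect_error(simulate_batch(p, grid = c(0, 50, 150)), "within")
  expect_error(simulate_batch(p, grid = c(0, 50, 50)), "strictly increasing")
  expect_error(simulate_batch(sim_params(mode = "regulated")), "promoter")
})

test_that("finite-difference dGFP/dt over OD reproduces the activity model", {
  p <- sim_params(s0 = 0.47, mode = "regulated")
  pp <- promoter_params()
  tr <- simulate_batch(p, pp, grid = seq(0, 400, by = 0.5))
  n <- nrow(tr)
  pa_fd <- (tr$gfp[-(1:2)] - tr$gfp[1:(n - 2)]) / 1 / tr$od[2:(n - 1)]
  rel <- pa_fd / tr$pa[2:(n - 1)] - 1
  expect_lt(sqrt(mean(rel^2)), 0.01)
})

test_that("removing the expression pulse prolongs the deceleration", {
  pp <- promoter_params()
  T_dec <- function(mode) {
    tr <- simulate_batch(sim_params(s0 = 0.2, mode = mode), pp)
    detect_arrest(growth_rate_series(trajectory_series(tr), 21))$T_dec
  }
  expect_lt(T_dec("regulated"), T_dec("mutant_no_pulse"))
})
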