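test_that("log-derivative is window-invariant on exact exponentials", {
  times <- seq(0, 300, by = 3)
  ser <- structure(list(condition_id = "exp", times = times,
                        mean_od = 0.01 * exp(0.7 * times / 60),
                        n_wells = 1L), class = "condition_series")
  for (w in c(9, 21, 45)) {
    gr <- growth_rate_series(ser, w)
    expect_equal(gr$mu, rep(0.7, length(times)), tolerance = 1e-9)
    expect_equal(gr$mu_max, 0.7, tolerance = 1e-9)
    expect_equal(gr$generation_time, log(2) / 0.7 * 60, tolerance = 1e-9)
  }
  flat <- structure(list(condition_id = "c", times = times,
                         mean_od = rep(0.5, length(times)), n_wells = 1L),
                    class = "condition_series")
  expect_equal(growth_rate_series(flat, 21)$mu, rep(0, length(times)))
})

test_that("growth-rate estimation rejects invalid input", {
  times <- seq(0, 60, by = 3)
  ser <- structure(list(times = times, mean_od = c(rep(0.1, 20), 0)),
                   class = "condition_series")
  expect_error(growth_rate_series(ser, 21), "positive")
  ser2 <- structure(list(times = times, mean_od = rep(0.1, 21)),
                    class = "condition_series")
  expect_error(growth_rate_series(ser2, 4), "2 sampling intervals")
  expect_error(growth_rate_series(ser2, 100), "larger than the series")
})

test_that("maximal rate from default-noise plates is close to the truth", {
  tab <- nitrogen_study(1)$condition_table
  expect_true(all(abs(tab$mu_max / 0.705 - 1) < 0.03))
})

test_that("arrest detection classifies step, ramp and combined profiles", {
  times <- seq(0, 600, by = 3)
  # step: maximal growth then an instant stop
  mu_step <- ifelse(times < 300, 0.7, 0)
  a <- detect_arrest(fake_gr(times, mu_step))
  expect_equal(a$stop_class, "abrupt")
  expect_equal(a$T_dec, 3)
  expect_equal(a$t_arrest, 300)

  # 4-h linear ramp from mu_max to zero
  mu_ramp <- pmax(pmin(0.7, 0.7 * (540 - times) / 240), 0)
  a2 <- detect_arrest(fake_gr(times, mu_ramp))
  expect_equal(a2$stop_class, "gradual")
  expect_gt(a2$T_dec, 200)

  # no arrest: rate never drops
  a3 <- detect_arrest(fake_gr(times, rep(0.7, length(times))))
  expect_equal(a3$stop_class, "no_arrest")
  expect_true(is.na(a3$t_arrest))
})

test_that("simulated stop classes: limiting abrupt, non-limiting gradual, intermediate mixed", {
  classify <- function(s0, mode) {
    tr <- simulate_batch(sim_params(s0 = s0, mode = mode))
    detect_arrest(growth_rate_series(trajectory_series(tr), 21))
  }
  for (s0 in c(0.16, 0.2, 0.24, 0.31, 0.47)) {
    expect_equal(classify(s0, "monod")$stop_class, "abrupt")
  }
  expect_equal(classify(18.7, "nonlimiting_entry")$stop_class, "gradual")
  # density slowdown followed by substrate exhaustion
  expect_equal(classify(6, "nonlimiting_entry")$stop_class, "mixed")
})

test_that("deceleration durations order: limiting < mutant < non-limiting", {
  pp <- promoter_params()
  T_dec <- function(s0, mode) {
    tr <- simulate_batch(sim_params(s0 = s0, mode = mode), pp)
    detect_arrest(growth_rate_series(trajectory_series(tr), 21))$T_dec
  }
  t_monod <- T_dec(0.2, "monod")
  t_mut <- T_dec(0.2, "mutant_no_pulse")
  t_non <- T_dec(18.7, "nonlimiting_entry")
  expect_lt(t_monod, t_mut)
  expect_lt(t_mut, t_non)
})

test_that("replicate averaging honours single wells and empty conditions", {
  tr <- simulate_batch(sim_params(s0 = 0.2), grid = seq(0, 300, by = 3))
  des <- make_checkerboard_design(
    plate_condition("a", "nitrogen", 0.2),
    plate_condition("b", "nitrogen", 0.47))
  pbc <- list(a = condition_params(plate_condition("a", "nitrogen", 0.2)),
              b = condition_params(plate_condition("b", "nitrogen", 0.47)))
  ds <- generate_plate(des, pbc, zero_noise())
  # 48 identical noiseless wells: mean equals trajectory, SEM is zero
  ser <- average_replicates(ds)
  expect_equal(max(ser$a$sem_od), 0)
  expect_lt(max(abs(ser$a$mean_od / simulate_batch(pbc$a$sim,
    grid = ser$a$times)$od - 1)), 1e-9)
  # one well only: mean is that well, SEM absent
  ds1 <- ds
  ds1$records <- ds1$records[ds1$records$well == "A1", ]
  ds1$design$wells <- ds1$design$wells[ds1$design$wells$well == "A1", ]
  ser1 <- average_replicates(ds1)
  expect_equal(ser1$a$n_wells, 1L)
  expect_true(all(is.na(ser1$a$sem_od)))
})
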