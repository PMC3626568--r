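cond_n <- function(s0, id = paste0("N", s0), reporter = "none",
                   strain = "wildtype") {
  plate_condition(id, "nitrogen", s0, strain, reporter)
}

test_that("checkerboard design assigns 48+48 wells with no like neighbours", {
  des <- make_checkerboard_design(cond_n(0.2), cond_n(0.94))
  counts <- table(des$wells$condition_id)
  expect_equal(as.integer(counts[c("N0.2", "N0.94")]), c(48L, 48L))
  w <- des$wells
  row_i <- match(substr(w$well, 1, 1), LETTERS)
  col_i <- as.integer(substring(w$well, 2))
  cond <- matrix(NA_character_, 8, 12)
  cond[cbind(row_i, col_i)] <- w$condition_id
  same_right <- cond[, -1] == cond[, -12]
  same_down <- cond[-1, ] == cond[-8, ]
  expect_equal(sum(same_right) + sum(same_down), 0L)
  expect_error(make_checkerboard_design(cond_n(0.2), cond_n(0.2)),
               "distinct")
})

test_that("zero-noise plates reproduce the deterministic trajectory", {
  des <- make_checkerboard_design(cond_n(0.2), cond_n(0.47))
  pbc <- list(N0.2 = condition_params(cond_n(0.2)),
              N0.47 = condition_params(cond_n(0.47)))
  ds <- generate_plate(des, pbc, zero_noise())
  tr <- simulate_batch(pbc$N0.2$sim, grid = seq(0, 1200, by = 3))
  one <- ds$records[ds$records$well == "A1" & ds$records$channel == "OD600", ]
  expect_equal(des$wells$condition_id[des$wells$well == "A1"], "N0.2")
  expect_lt(max(abs(one$value / tr$od - 1)), 1e-9)
})

test_that("generation is deterministic given the seed", {
  des <- make_checkerboard_design(cond_n(0.2), cond_n(0.47))
  pbc <- list(N0.2 = condition_params(cond_n(0.2)),
              N0.47 = condition_params(cond_n(0.47)))
  d1 <- generate_plate(des, pbc, noise_params(seed = 11))
  d2 <- generate_plate(des, pbc, noise_params(seed = 11))
  expect_identical(d1$records, d2$records)
  d3 <- generate_plate(des, pbc, noise_params(seed = 12))
  expect_false(identical(d1$records, d3$records))
})

test_that("default noise yields ~2% SEM of the mean OD over 48 replicates", {
  ser <- nitrogen_study(1)$series[["N0.47"]]
  gr <- growth_rate_series(ser, 21)
  expo <- gr$mu >= 0.9 * gr$mu_max & ser$times >= 30
  sem_pct <- mean(ser$sem_od[expo] / ser$mean_od[expo]) * 100
  expect_gt(sem_pct, 1.4)
  expect_lt(sem_pct, 2.6)
})

test_that("static well factors cancel in the logarithmic derivative", {
  des <- make_checkerboard_design(cond_n(0.2), cond_n(0.47))
  pbc <- list(N0.2 = condition_params(cond_n(0.2)),
              N0.47 = condition_params(cond_n(0.47)))
  nz <- noise_params(well_scale_cv = 0.3, read_cv = 0, gfp_read_cv = 0,
                     day_scale_cv = 0.2, seed = 5)
  ds <- generate_plate(des, pbc, nz)
  one <- ds$records[ds$records$well == "A1" & ds$records$channel == "OD600", ]
  ser <- structure(list(condition_id = "w", times = one$time_min,
                        mean_od = one$value, n_wells = 1L),
                   class = "condition_series")
  gr <- growth_rate_series(ser, 21)
  tr <- simulate_batch(pbc$N0.2$sim, grid = seq(0, 1200, by = 3))
  gr_true <- growth_rate_series(trajectory_series(tr), 21)
  expect_equal(gr$mu, gr_true$mu, tolerance = 1e-9)
})

test_that("plate files round-trip and are validated on read", {
  des <- make_checkerboard_design(cond_n(0.2), cond_n(0.47, reporter = "glnA"))
  pbc <- list(N0.2 = condition_params(cond_n(0.2)),
              N0.47 = condition_params(cond_n(0.47, reporter = "glnA")))
  ds <- generate_plate(des, pbc, noise_params(seed = 3))
  path <- tempfile(fileext = ".csv")
  write_plate(ds, path)
  back <- read_plate(path)
  expect_equal(back$records, ds$records)
  expect_equal(back$design$wells$condition_id, ds$design$wells$condition_id)
  expect_equal(back$design$conditions[["N0.47"]]$s0, 0.47)

  bad <- ds
  bad$records$value[100] <- -0.01
  write_plate(bad, path)
  expect_error(read_plate(path), "row 100")

  bad2 <- ds
  bad2$records$channel[5] <- "OD700"
  write_plate(bad2, path)
  expect_error(read_plate(path), "unknown channel at row 5")

  bad3 <- ds
  bad3$records$time_min[2] <- bad3$records$time_min[3]
  write_plate(bad3, path)
  expect_error(read_plate(path), "non-monotone")
})

test_that("missing wells are tolerated and reduce the replicate count", {
  des <- make_checkerboard_design(cond_n(0.2), cond_n(0.47))
  pbc <- list(N0.2 = condition_params(cond_n(0.2)),
              N0.47 = condition_params(cond_n(0.47)))
  ds <- generate_plate(des, pbc, noise_params(seed = 4))
  drop_wells <- head(des$wells$well[des$wells$condition_id == "N0.2"], 3)
  ds$records <- ds$records[!ds$records$well %in% drop_wells, ]
  ser <- average_replicates(ds)
  expect_equal(ser[["N0.2"]]$n_wells, 45L)
  expect_equal(ser[["N0.47"]]$n_wells, 48L)
})

test_that("missing condition parameters are a configuration error", {
  des <- make_checkerboard_design(cond_n(0.2), cond_n(0.47))
  expect_error(
    generate_plate(des, list(N0.2 = condition_params(cond_n(0.2))),
                   noise_params()),
    "no parameters for condition")
})
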