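# Shared fixtures, built once per test session. Simulated studies are cached
# by key so that unit tests and the acceptance suite reuse the same runs.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

nitrogen_study <- function(seed) {
  cached(paste0("nitro", seed), run_study(seed = seed))
}

glucose_study <- function(seed) {
  cached(paste0("gluc", seed), run_study(seed = seed, nutrient = "glucose"))
}

reporter_study <- function(seed) {
  cached(paste0("rep", seed), run_study(seed = seed, reporter = TRUE))
}

zero_noise <- function(seed = 1L) {
  noise_params(well_scale_cv = 0, read_cv = 0, gfp_read_cv = 0,
               day_scale_cv = 0, seed = seed)
}

# condition_series wrapper around a deterministic trajectory (single "well")
trajectory_series <- function(tr, id = "truth") {
  ser <- list(condition_id = id, condition = NULL, times = tr$time,
              mean_od = tr$od, sem_od = rep(NA_real_, nrow(tr)), n_wells = 1L)
  if (!is.null(tr$gfp)) {
    ser$gfp_times <- tr$time
    ser$mean_gfp <- tr$gfp
    ser$sem_gfp <- rep(NA_real_, nrow(tr))
    ser$n_wells_gfp <- 1L
  }
  structure(ser, class = "condition_series")
}

# hand-built growth_rate_series for synthetic rate profiles
fake_gr <- function(times, mu, window_min = 3) {
  structure(list(condition_id = "fake", times = times, mu = mu,
                 support = rep(3L, length(times)), window_min = window_min,
                 mu_max = max(mu), generation_time = log(2) / max(mu) * 60),
            class = "growth_rate_series")
}
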