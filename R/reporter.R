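#' Promoter activity from OD and GFP series
#'
#' Promoter activity is the rate of accumulation of reporter fluorescence per
#' unit biomass, `PA(t) = (dGFP/dt) / OD(t)`. The derivative is estimated as
#' the OLS slope of the mean GFP signal over a centered sliding window on the
#' GFP grid; OD is interpolated onto the GFP grid linearly in `ln OD`
#' (exponential interpolation). The SEM is propagated from the replicate
#' SEMs of the GFP points through the OLS slope weights.
#'
#' @param series A `condition_series` containing both channels.
#' @param window_min Derivative window (min), default 24 (3 points at 8-min
#'   GFP sampling); must cover at least 2 GFP intervals.
#' @return An object of class `pa_series`: list with `times` (GFP grid),
#'   `pa` (AU per OD per min), `sem_pa`, `window_min`.
#' @export
promoter_activity_series <- function(series, window_min = 24) {
  if (is.null(series$mean_gfp)) {
    stop("promoter_activity_series: series has no GFP channel")
  }
  gt <- series$gfp_times
  dt <- stats::median(diff(gt))
  if (window_min < 2 * dt) {
    stop("promoter_activity_series: window must span >= 2 GFP intervals")
  }
  od_on_gfp <- exp(stats::approx(series$times, log(series$mean_od),
                                 xout = gt, rule = 2)$y)
  ss <- sliding_slope(gt, series$mean_gfp, window_min)
  pa <- ss$slope / od_on_gfp

  sem_pa <- rep(NA_real_, length(gt))
  if (!is.null(series$sem_gfp) && !all(is.na(series$sem_gfp))) {
    half <- window_min / 2
    for (i in seq_along(gt)) {
      j <- which(gt >= gt[i] - half & gt <= gt[i] + half)
      if (length(j) < 2L) next
      xc <- gt[j] - mean(gt[j])
      w <- xc / sum(xc^2)
      sem_pa[i] <- sqrt(sum((w * series$sem_gfp[j])^2)) / od_on_gfp[i]
    }
  }
  structure(list(condition_id = series$condition_id, times = gt, pa = pa,
                 sem_pa = sem_pa, window_min = window_min),
            class = "pa_series")
}

#' Detect and quantify the pre-arrest promoter-activity pulse
#'
#' Quantifies the pulse of assimilation-gene expression in the last
#' generation of growth:
#'
#' * `basal_pa`: median PA over the early exponential phase - the first half
#'   of the window where `mu >= frac_high * mu_max` (i.e. before
#'   `t_dec_start/2`). The late exponential phase is excluded because under a
#'   limiting nutrient it already overlaps the induction band.
#' * rise detection: at least `persist` consecutive samples with
#'   `pa > basal_pa * (1 + k_onset)`; `detected` additionally requires
#'   `fold_change >= fold_min`.
#' * `peak_pa` / `peak_time`: maximum PA from the rise onward;
#'   `fold_change = peak_pa / basal_pa`.
#' * `onset_time`: the interpolated time at which PA first crosses the
#'   half-rise level `(basal_pa + peak_pa)/2`. For a Hill-type activation
#'   this localizes the activation midpoint; a fixed threshold just above
#'   basal would sit on the foot of the Hill curve and systematically
#'   overestimate the substrate level at onset.
#' * `onset_substrate`: inferred substrate at `onset_time` (interpolated
#'   from `ss`).
#' * `shutdown_time`: first post-peak time with
#'   `pa <= shutdown_factor * basal_pa` (expression shuts down when growth
#'   stops).
#' * `generations_before_arrest`: `(t_arrest - onset_time) * mu_max / ln 2`
#'   (with `mu_max` converted to 1/min) - how many generations before the
#'   growth stop the rise occurs.
#'
#' @param pa A [promoter_activity_series()] result.
#' @param ss A [infer_substrate()] result for the same condition.
#' @param arrest A [detect_arrest()] result for the same condition.
#' @param k_onset Relative rise above basal that counts as induction
#'   (default 0.5).
#' @param persist Number of consecutive supra-threshold samples required
#'   (default 2).
#' @param fold_min Minimum fold change for `detected = TRUE` (default 2).
#' @param shutdown_factor Multiple of basal defining shutdown (default 1.5).
#' @return An object of class `pulse_result`; when no pulse is detected,
#'   `detected = FALSE` and the pulse fields are `NA`.
#' @export
detect_pulse <- function(pa, ss, arrest, k_onset = 0.5, persist = 2L,
                         fold_min = 2, shutdown_factor = 1.5) {
  stopifnot(inherits(pa, "pa_series"), inherits(ss, "substrate_series"),
            inherits(arrest, "arrest_result"))
  if (is.na(arrest$t_dec_start)) {
    stop("detect_pulse: arrest result carries no deceleration window")
  }
  basal_sel <- pa$times <= arrest$t_dec_start / 2
  if (sum(basal_sel & is.finite(pa$pa)) < 3L) {
    stop("detect_pulse: fewer than 3 PA points in the basal window")
  }
  basal <- stats::median(pa$pa[basal_sel], na.rm = TRUE)

  none <- structure(list(detected = FALSE, basal_pa = basal,
                         onset_time = NA_real_, onset_substrate = NA_real_,
                         peak_time = NA_real_, peak_pa = NA_real_,
                         fold_change = NA_real_, shutdown_time = NA_real_,
                         generations_before_arrest = NA_real_,
                         k_onset = k_onset, fold_min = fold_min),
                    class = "pulse_result")

  above <- is.finite(pa$pa) & pa$pa > basal * (1 + k_onset)
  run <- rle(above)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  rise_runs <- which(run$values & run$lengths >= persist)
  if (!is.na(arrest$t_arrest)) {
    # a pre-arrest pulse must begin before growth stops; late drifts during
    # stationary phase are not the phenomenon being quantified
    rise_runs <- rise_runs[pa$times[starts[rise_runs]] <= arrest$t_arrest]
  }
  if (length(rise_runs) == 0L) return(none)
  rise_idx <- starts[rise_runs[1L]]

  post <- seq(rise_idx, length(pa$pa))
  peak_rel <- which.max(pa$pa[post])
  peak_idx <- post[peak_rel]
  peak_pa <- pa$pa[peak_idx]
  fold <- peak_pa / basal
  if (fold < fold_min) return(none)

  half_level <- (basal + peak_pa) / 2
  below <- which(pa$pa < half_level & pa$times < pa$times[peak_idx])
  onset_time <- if (length(below)) {
    i <- max(below)
    t0 <- pa$times[i]; t1 <- pa$times[i + 1L]
    y0 <- pa$pa[i]; y1 <- pa$pa[i + 1L]
    t0 + (half_level - y0) / (y1 - y0) * (t1 - t0)
  } else pa$times[rise_idx]
  onset_substrate <- stats::approx(ss$times, ss$s, onset_time, rule = 2)$y

  after_peak <- which(pa$times > pa$times[peak_idx] &
                        pa$pa <= shutdown_factor * basal)
  shutdown_time <- if (length(after_peak)) pa$times[min(after_peak)] else NA_real_

  gens <- if (!is.na(arrest$t_arrest)) {
    (arrest$t_arrest - onset_time) * (arrest$mu_max / 60) / log(2)
  } else NA_real_

  structure(list(detected = TRUE, basal_pa = basal, onset_time = onset_time,
                 onset_substrate = onset_substrate,
                 peak_time = pa$times[peak_idx], peak_pa = peak_pa,
                 fold_change = fold, shutdown_time = shutdown_time,
                 generations_before_arrest = gens,
                 k_onset = k_onset, fold_min = fold_min),
            class = "pulse_result")
}
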