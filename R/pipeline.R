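#' Build simulation parameters for a plate condition
#'
#' Maps a [plate_condition()] to its forward-model parameters: nutrient
#' defaults for Ks and the OD-substrate conversion, growth mode from strain
#' and reporter (`nonlimiting` -> density-capped stationary entry, a reporter
#' on a wildtype strain -> the regulated pulse model, otherwise plain Monod),
#' and the shared kinetic constants.
#'
#' @param cond A [plate_condition()].
#' @param mu0 Maximal growth rate (1/h).
#' @param s_carryover Inoculum substrate carryover (mM).
#' @param od0 Inoculum OD.
#' @param t_end Horizon (min).
#' @param promoter [promoter_params()] used for reporter/mutant conditions
#'   (default [promoter_params()]).
#' @return list with components `sim` and `promoter` (possibly `NULL`),
#'   ready for [generate_plate()].
#' @export
condition_params <- function(cond, mu0 = log(2) / 59 * 60, s_carryover = 0.09,
                             od0 = 0.002, t_end = 1200,
                             promoter = promoter_params()) {
  stopifnot(inherits(cond, "plate_condition"))
  nd <- nutrient_defaults(cond$nutrient)
  has_reporter <- !identical(cond$reporter, "none")
  mode <- if (cond$strain == "nonlimiting") {
    "nonlimiting_entry"
  } else if (cond$strain == "mutant_no_pulse") {
    "mutant_no_pulse"
  } else if (has_reporter) "regulated" else "monod"
  list(sim = sim_params(mu0 = mu0, Ks = nd$Ks, c = nd$c, s0 = cond$s0,
                        s_carryover = s_carryover, od0 = od0, t_end = t_end,
                        mode = mode),
       promoter = if (has_reporter || mode %in% c("regulated",
                                                  "mutant_no_pulse")) {
         promoter
       } else NULL)
}

pair_extremes <- function(n) {
  # pair lowest with highest, 2nd lowest with 2nd highest, ... so that the
  # per-plate day factor is not confounded with the substrate series
  if (n %% 2L != 0L) {
    stop("simulate_growth_panel: need an even number of levels ",
         "(two conditions per plate)")
  }
  k <- n %/% 2
  cbind(seq_len(k), n + 1 - seq_len(k))
}

#' Simulate a two-condition-per-plate nutrient panel
#'
#' Generates one checkerboard plate per pair of substrate levels, pairing the
#' extremes of the series (lowest with highest, second lowest with second
#' highest, ...) so the per-plate day-scale factor is orthogonal to the
#' substrate gradient. Levels at or above `nonlimiting_min` are simulated in
#' the density-capped stationary-entry mode; the rest deplete their substrate.
#'
#' @param levels Initial substrate levels (mM), e.g.
#'   [default_nitrogen_levels()]. An odd count leaves the median level out.
#' @param nutrient `"nitrogen"` or `"glucose"`.
#' @param seed Integer seed (one plate uses `seed`, the next `seed + 1`, ...).
#' @param noise A [noise_params()] (its seed field is overridden per plate);
#'   `NULL` for the defaults.
#' @param reporter Reporter name to attach to every condition, or `"none"`
#'   for growth-only plates.
#' @param nonlimiting_min Levels >= this (mM) are treated as non-limiting
#'   (default 10).
#' @param label Prefix for plate ids (default `"N"`/`"G"` by nutrient).
#' @param ... Passed to [condition_params()] (`mu0`, `s_carryover`, `od0`,
#'   `t_end`, `promoter`).
#' @return A list of `plate_dataset` objects.
#' @export
simulate_growth_panel <- function(levels, nutrient = "nitrogen", seed = 1L,
                                  noise = NULL, reporter = "none",
                                  nonlimiting_min = 10, label = NULL, ...) {
  stopifnot(length(levels) >= 2L)
  if (is.null(noise)) noise <- noise_params(seed = seed)
  levels <- sort(levels)
  prefix <- if (nutrient == "nitrogen") "N" else "G"
  if (is.null(label)) label <- prefix
  conds <- lapply(levels, function(s0) {
    plate_condition(paste0(prefix, format(s0)), nutrient = nutrient, s0 = s0,
                    strain = if (s0 >= nonlimiting_min) "nonlimiting"
                    else "wildtype",
                    reporter = reporter)
  })
  pairs <- pair_extremes(length(conds))
  lapply(seq_len(nrow(pairs)), function(k) {
    ca <- conds[[pairs[k, 1L]]]
    cb <- conds[[pairs[k, 2L]]]
    des <- make_checkerboard_design(ca, cb,
                                    plate_id = sprintf("%s_plate%02d",
                                                       label, k))
    pbc <- stats::setNames(lapply(list(ca, cb), condition_params, ...),
                           c(ca$condition_id, cb$condition_id))
    nz <- noise
    # distinct random stream per plate, non-overlapping across run seeds
    nz$seed <- as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
    generate_plate(des, pbc, nz)
  })
}

#' Growth, calibration and Monod analysis of a simulated or measured panel
#'
#' Runs the full growth-side pipeline on a set of plates:
#' replicate averaging, growth-rate estimation (logarithmic derivative,
#' `window_min` smoothing), arrest detection and stop classification,
#' final-OD extraction, the final-OD-vs-s0 calibration over limiting
#' plateaued conditions, substrate inference (final-OD anchoring with the
#' fitted conversion), deceleration-point construction
#' ([monod_input_points()]) and the pooled measurement-error-aware Monod fit
#' ([fit_monod_eiv()]).
#'
#' @param datasets A `plate_dataset` or list of them.
#' @param window_min Growth-rate smoothing window (min), default 21.
#' @param s_window_mM Substrate cut for the Monod fit (mM), default 0.05.
#' @param s0_max Calibration restricted to conditions with `s0 <= s0_max`
#'   (mM), default 1.
#' @param bootstrap_reps Bootstrap resamples for the Monod Ks CI (default 0;
#'   the EIV bootstrap is comparatively costly).
#' @param seed Seed for the bootstrap.
#' @return A list of class `growth_analysis` with elements `series`,
#'   `growth_rates`, `arrests`, `condition_table` (per-condition summary
#'   data.frame), `calibration`, `substrate`, `monod_points`, `monod_fit`,
#'   `mean_generation_time`.
#' @export
analyze_growth_panel <- function(datasets, window_min = 21,
                                 s_window_mM = 0.05,
                                 s0_max = 1.0, bootstrap_reps = 0L,
                                 seed = 1L) {
  series <- average_replicates(datasets)
  grs <- lapply(series, growth_rate_series, window_min = window_min)
  arrests <- lapply(grs, detect_arrest)

  tab <- do.call(rbind, lapply(names(series), function(cid) {
    fo <- final_od(series[[cid]])
    data.frame(condition_id = cid,
               nutrient = series[[cid]]$condition$nutrient,
               s0 = series[[cid]]$condition$s0,
               n_wells = series[[cid]]$n_wells,
               mu_max = grs[[cid]]$mu_max,
               generation_time = grs[[cid]]$generation_time,
               t_arrest = arrests[[cid]]$t_arrest,
               T_dec = arrests[[cid]]$T_dec,
               stop_class = arrests[[cid]]$stop_class,
               final_od = as.numeric(fo),
               od_plateaued = isTRUE(attr(fo, "final")),
               stringsAsFactors = FALSE)
  }))

  limiting <- tab$s0 <= s0_max & tab$od_plateaued &
    tab$stop_class %in% c("abrupt", "mixed")
  calib <- fit_final_od_calibration(
    data.frame(condition_id = tab$condition_id, s0 = tab$s0,
               final_od = tab$final_od)[limiting, , drop = FALSE],
    s0_max = s0_max)

  fit_cids <- tab$condition_id[limiting]
  substrate <- stats::setNames(lapply(fit_cids, function(cid) {
    infer_substrate(series[[cid]], s0 = tab$s0[tab$condition_id == cid],
                    c = calib$c, anchor = "final")
  }), fit_cids)

  pts <- do.call(rbind, lapply(fit_cids, function(cid) {
    monod_input_points(series[[cid]], c_od = calib$c,
                       s_window_mM = s_window_mM, window_min = window_min)
  }))
  fit <- fit_monod_eiv(pts, bootstrap_reps = bootstrap_reps, seed = seed)

  structure(list(series = series, growth_rates = grs, arrests = arrests,
                 condition_table = tab, calibration = calib,
                 substrate = substrate, monod_points = pts, monod_fit = fit,
                 mean_generation_time = mean(tab$generation_time)),
            class = "growth_analysis")
}

#' Promoter-activity pulse analysis of a reporter panel
#'
#' Runs the reporter-side pipeline: replicate averaging, growth rate and
#' arrest per condition, substrate inference (final-OD anchoring, with the
#' conversion from a calibration over the panel's own limiting conditions, or
#' a supplied `c`), promoter activity (`dGFP/dt / OD`) and pulse detection.
#'
#' @param datasets A `plate_dataset` or list of them (reporter plates).
#' @param c_od Conversion factor (mM per OD); `NULL` (default) fits it from
#'   the panel's limiting final ODs.
#' @param pa_window_min PA derivative window (min), default 24.
#' @param window_min Growth-rate smoothing window (min), default 21.
#' @param s0_max Limiting cut for the internal calibration (mM), default 1.
#' @param ... Passed to [detect_pulse()].
#' @return A list of class `reporter_analysis` with elements `series`,
#'   `pa_series`, `pulses`, `pulse_table` (per-condition data.frame),
#'   `calibration` (or `NULL` when `c_od` supplied), `substrate`, `arrests`.
#' @export
analyze_reporter_panel <- function(datasets, c_od = NULL, pa_window_min = 24,
                                   window_min = 21, s0_max = 1.0, ...) {
  series <- average_replicates(datasets)
  grs <- lapply(series, growth_rate_series, window_min = window_min)
  arrests <- lapply(grs, detect_arrest)
  s0s <- vapply(series, function(x) x$condition$s0, numeric(1))

  calib <- NULL
  if (is.null(c_od)) {
    fo <- lapply(series, final_od)
    plateaued <- vapply(fo, function(x) isTRUE(attr(x, "final")), logical(1))
    use <- s0s <= s0_max & plateaued
    calib <- fit_final_od_calibration(
      data.frame(s0 = s0s[use], final_od = as.numeric(unlist(fo[use]))),
      s0_max = s0_max)
    c_od <- calib$c
  }

  limiting <- names(series)[s0s <= s0_max]
  substrate <- stats::setNames(lapply(limiting, function(cid) {
    infer_substrate(series[[cid]], s0 = s0s[[cid]], c = c_od,
                    anchor = "final")
  }), limiting)

  pas <- lapply(series, promoter_activity_series, window_min = pa_window_min)
  pulses <- stats::setNames(lapply(names(series), function(cid) {
    ssx <- if (cid %in% limiting) substrate[[cid]] else {
      # non-limiting control: initial anchoring (substrate never exhausted)
      infer_substrate(series[[cid]], s0 = s0s[[cid]], c = c_od,
                      anchor = "initial")
    }
    detect_pulse(pas[[cid]], ssx, arrests[[cid]], ...)
  }), names(series))

  ptab <- do.call(rbind, lapply(names(series), function(cid) {
    p <- pulses[[cid]]
    data.frame(condition_id = cid, s0 = s0s[[cid]],
               detected = p$detected, basal_pa = p$basal_pa,
               onset_time = p$onset_time,
               onset_substrate = p$onset_substrate,
               peak_time = p$peak_time, peak_pa = p$peak_pa,
               fold_change = p$fold_change,
               shutdown_time = p$shutdown_time,
               generations_before_arrest = p$generations_before_arrest,
               stringsAsFactors = FALSE)
  }))

  structure(list(series = series, pa_series = pas, pulses = pulses,
                 pulse_table = ptab, calibration = calib,
                 substrate = substrate, arrests = arrests, c_used = c_od),
            class = "reporter_analysis")
}

#' Default limiting panels used for parameter-recovery studies
#'
#' The four limiting nitrogen levels entering the final-OD calibration
#' (0.24, 0.31, 0.47, 0.94 mM), the three limiting glucose levels
#' (0.14, 0.28, 0.56 mM), and the three reporter levels (the lowest panel
#' levels whose initial substrate, including inoculum carryover, lies clearly
#' above the 0.25 mM induction threshold: 0.31, 0.47, 0.94 mM).
#'
#' @return Numeric vector of substrate levels (mM).
#' @export
calibration_nitrogen_levels <- function() c(0.24, 0.31, 0.47, 0.94)

#' @rdname calibration_nitrogen_levels
#' @export
calibration_glucose_levels <- function() c(0.14, 0.28, 0.56)

#' @rdname calibration_nitrogen_levels
#' @export
reporter_nitrogen_levels <- function() c(0.31, 0.47, 0.94)

#' One-call simulate + analyze study
#'
#' Convenience wrapper running the whole pipeline under one seed: simulates
#' the limiting panel of the chosen nutrient (and, for nitrogen with
#' `reporter = TRUE`, the regulated-mode reporter panel) and analyses it.
#'
#' @param seed Integer seed.
#' @param nutrient `"nitrogen"` or `"glucose"`.
#' @param reporter If `TRUE`, run the reporter panel (regulated mode) instead
#'   of the growth panel.
#' @param levels Substrate levels; defaults to the nutrient's
#'   calibration/reporter panel.
#' @param ... Passed on to [simulate_growth_panel()].
#' @return The `growth_analysis` or `reporter_analysis` object, with the
#'   simulated datasets attached as attribute `datasets`.
#' @export
run_study <- function(seed = 1L, nutrient = c("nitrogen", "glucose"),
                      reporter = FALSE, levels = NULL, ...) {
  nutrient <- match.arg(nutrient)
  if (is.null(levels)) {
    levels <- if (reporter) {
      # three limiting reporter levels plus the non-limiting control
      c(reporter_nitrogen_levels(), 18.7)
    } else if (nutrient == "nitrogen") {
      calibration_nitrogen_levels()
    } else {
      # three limiting levels plus an intermediate to fill the second plate
      c(calibration_glucose_levels(), 2.8)
    }
  }
  ds <- simulate_growth_panel(levels, nutrient = nutrient, seed = seed,
                              reporter = if (reporter) "glnA" else "none",
                              ...)
  res <- if (reporter) analyze_reporter_panel(ds) else
    analyze_growth_panel(ds, seed = seed)
  attr(res, "datasets") <- ds
  res
}
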