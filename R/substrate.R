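#' Final OD of a culture
#'
#' The plateau OD reached by a culture, computed as the median of the mean OD
#' over the last `tail_min` minutes of the series (a median tail is robust to
#' residual drift and isolated outliers). The tail is additionally checked
#' for residual growth: if its log-slope exceeds `still_growing_tol` the
#' value is flagged as not final (attribute `final = FALSE`), and such
#' conditions are excluded from the final-OD calibration.
#'
#' @param series A `condition_series` (or any list with `times`, `mean_od`).
#' @param tail_min Tail length in minutes (default 60).
#' @param still_growing_tol Residual log-slope (1/h) above which the culture
#'   is considered still growing (default 0.02/h).
#' @return The final OD (numeric scalar) with attribute `final` (logical).
#' @export
final_od <- function(series, tail_min = 60, still_growing_tol = 0.02) {
  times <- series$times
  od <- series$mean_od
  if (diff(range(times)) < tail_min) {
    stop("final_od: series shorter than the requested tail")
  }
  sel <- times >= max(times) - tail_min
  tt <- times[sel]
  yy <- log(od[sel])
  xc <- tt - mean(tt)
  slope_h <- sum(xc * yy) / sum(xc^2) * 60
  structure(stats::median(od[sel]), final = slope_h <= still_growing_tol)
}

#' Final-OD versus initial-substrate calibration
#'
#' Under a limiting nutrient the final OD is proportional to the initial
#' substrate level. An ordinary least-squares line `OD_f = a*s0 + b` is
#' fitted over the limiting conditions (`s0 <= s0_max`, excluding saturating
#' levels); the slope's reciprocal `c = 1/a` converts OD into substrate units
#' (mM consumed per OD unit produced), with its standard error propagated by
#' the delta method. A nonzero intercept `b` reflects growth supported by
#' substrate carried over with the inoculum (plus the inoculum OD itself).
#'
#' @param points data.frame with columns `s0` (mM) and `final_od` (OD);
#'   optionally `condition_id`.
#' @param s0_max Only points with `s0 <= s0_max` enter the fit (default
#'   1.0 mM, below the onset of saturation).
#' @return An object of class `calibration_result`: list with `a`, `a_se`,
#'   `b`, `b_se`, `c`, `c_se`, `r2`, `n`, `points`.
#' @export
fit_final_od_calibration <- function(points, s0_max = 1.0) {
  stopifnot(is.data.frame(points), all(c("s0", "final_od") %in% names(points)))
  use <- points[points$s0 <= s0_max, , drop = FALSE]
  if (length(unique(use$s0)) < 2L) {
    stop("fit_final_od_calibration: need >= 2 distinct s0 values <= s0_max")
  }
  fit <- stats::lm(final_od ~ s0, data = use)
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- sm$coefficients
  a <- cf["s0", "Estimate"]
  if (a <= 0) {
    stop("fit_final_od_calibration: non-positive slope; final OD does not ",
         "increase with s0 (data may be non-limiting)")
  }
  a_se <- cf["s0", "Std. Error"]
  structure(list(a = a, a_se = a_se,
                 b = cf["(Intercept)", "Estimate"],
                 b_se = cf["(Intercept)", "Std. Error"],
                 c = 1 / a, c_se = a_se / a^2,
                 r2 = sm$r.squared,
                 n = nrow(use), points = use),
            class = "calibration_result")
}

#' Infer the instantaneous substrate trajectory from OD
#'
#' Converts an OD time series into a substrate time series via the constant
#' yield assumption, `s` decreasing by `c` mM per OD unit grown. Two
#' anchorings are available:
#'
#' * `anchor = "initial"` (default): `s(t) = s0 - c*(OD(t) - od_offset)`,
#'   with `od_offset` defaulting to the first OD of the series so that
#'   `s(0) = s0`. Set `od_offset = 0` to reproduce the bare relation
#'   `s(t) = s0 - c*OD(t)`. If substrate was carried over with the inoculum,
#'   `s0` should include it for the inference to be exact.
#' * `anchor = "final"`: `s(t) = c*(OD_f - OD(t))` with `OD_f` the measured
#'   plateau ([final_od()]). For a culture that exhausts its substrate this
#'   self-corrects for inoculum carryover and overall scale factors without
#'   knowing them, and is the anchoring used when fitting uM-scale Monod
#'   constants.
#'
#' Values are clipped at zero; the number of clipped points is recorded in
#' the `n_clipped` field.
#'
#' @param series A `condition_series` (or list with `times`, `mean_od`).
#' @param s0 Nominal initial substrate (mM); used by the initial anchoring
#'   and reported alongside either way.
#' @param c Conversion factor (mM per OD), e.g. from
#'   [fit_final_od_calibration()].
#' @param anchor `"initial"` or `"final"` (see above).
#' @param od_offset OD subtracted before conversion under the initial
#'   anchoring; default the series' first OD.
#' @return An object of class `substrate_series`: list with `times`, `s`
#'   (mM), `s0_nominal`, `c_used`, `anchor`, `n_clipped`.
#' @export
infer_substrate <- function(series, s0, c, anchor = c("initial", "final"),
                            od_offset = NULL) {
  anchor <- match.arg(anchor)
  if (c <= 0) stop("infer_substrate: 'c' must be > 0")
  od <- series$mean_od
  raw <- if (anchor == "initial") {
    if (is.null(od_offset)) od_offset <- od[1L]
    s0 - c * (od - od_offset)
  } else {
    odf <- as.numeric(final_od(series))
    c * (odf - od)
  }
  s <- pmax(raw, 0)
  structure(list(condition_id = series$condition_id,
                 times = series$times, s = s, s0_nominal = s0, c_used = c,
                 anchor = anchor, n_clipped = sum(raw < 0)),
            class = "substrate_series")
}
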