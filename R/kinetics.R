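#' Monod growth law
#'
#' Specific growth rate as a hyperbolic function of the limiting-substrate
#' concentration: `mu = mu0 * s / (Ks + s)`. Continuous, strictly increasing
#' in `s`, and bounded by `mu0`.
#'
#' @param s Substrate concentration (mM); vectorized, must be >= 0.
#' @param mu0 Maximal specific growth rate (1/h).
#' @param Ks Half-saturation constant (mM).
#' @return Growth rate(s) in 1/h.
#' @examples
#' monod_mu(0.0026, mu0 = 0.705, Ks = 0.0026)  # half-maximal at s = Ks
#' @export
monod_mu <- function(s, mu0, Ks) {
  if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0)) {
    stop("monod_mu: 's' must be finite and >= 0")
  }
  if (mu0 <= 0 || Ks <= 0) stop("monod_mu: 'mu0' and 'Ks' must be > 0")
  mu0 * s / (Ks + s)
}

#' Band-pass promoter activity model
#'
#' Promoter activity as a function of substrate: basal activity times a pulse
#' term formed by the product of two Hill gates, an activation gate that opens
#' as substrate drops below `theta_on` and a shutdown gate that closes as
#' substrate is exhausted below `theta_off`:
#'
#' `PA(s) = pa_basal * (1 + (fold_amp - 1) * g_on(s) * g_off(s))`
#'
#' with `g_on = theta_on^h_on / (theta_on^h_on + s^h_on)` and
#' `g_off = s^h_off / (theta_off^h_off + s^h_off)`. Activity is ~basal at
#' high substrate, peaks between the two thresholds, and returns to ~basal as
#' substrate reaches zero (expression shuts down when growth stops).
#'
#' @param s Substrate concentration (mM); vectorized, >= 0.
#' @param promoter A [promoter_params()] object.
#' @return Promoter activity in AU per OD per min.
#' @export
promoter_activity <- function(s, promoter) {
  stopifnot(inherits(promoter, "promoter_params"))
  if (any(s < 0)) stop("promoter_activity: 's' must be >= 0")
  g_on <- promoter$theta_on^promoter$h_on /
    (promoter$theta_on^promoter$h_on + s^promoter$h_on)
  g_off <- ifelse(s == 0, 0,
                  s^promoter$h_off /
                    (promoter$theta_off^promoter$h_off + s^promoter$h_off))
  promoter$pa_basal * (1 + (promoter$fold_amp - 1) * g_on * g_off)
}

#' Simulate batch growth with substrate depletion
#'
#' Integrates the coupled biomass-substrate system
#' `dOD/dt = mu * OD`, `ds/dt = -c * mu * OD` (time in minutes; `mu`
#' converted internally from 1/h), together with reporter accumulation
#' `dGFP/dt = PA(s) * OD`. The growth law depends on the mode:
#'
#' * `monod`: `mu = mu0 * s / (Ks + s)`.
#' * `regulated`: `mu = mu0 * s / (s + Ks * enzyme_gain / e)` where the
#'   relative assimilation-enzyme level `e` follows
#'   `de/dt = mu0_min * (PA(s)/pa_basal - e)`. In basal exponential growth
#'   `e = 1` (effective Ks is `Ks * enzyme_gain`); at full induction `e`
#'   approaches `enzyme_gain` and the effective Ks relaxes to `Ks`.
#' * `mutant_no_pulse`: the regulated equations with `e` frozen at 1 (the
#'   induction pulse genetically removed).
#' * `nonlimiting_entry`: `mu = monod_mu(s) / (1 + (OD/density_cap_od)^m)`,
#'   a phenomenological density inhibition for the gradual entry to
#'   stationary phase when the nutrient is not limiting.
#'
#' Substrate is clipped at zero inside the integrator (uptake ceases when the
#' pool is exhausted). In the monod and regulated modes the conservation law
#' `s + c*(OD - od0) = s0 + s_carryover` holds to solver tolerance.
#'
#' @param params A [sim_params()] object.
#' @param promoter A [promoter_params()] object, or `NULL` for a strain
#'   without a reporter (required for regulated/mutant modes).
#' @param grid Output times (min), within `[0, t_end]`.
#' @return A data.frame of class `growth_trajectory` with columns `time`,
#'   `od`, `s`, `pa`, `gfp` and (regulated/mutant modes) `e`.
#' @export
simulate_batch <- function(params, promoter = NULL, grid = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(grid)) grid <- seq(0, params$t_end, by = 3)
  if (any(grid < 0) || any(grid > params$t_end)) {
    stop("simulate_batch: 'grid' must lie within [0, t_end]")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("simulate_batch: 'grid' must be strictly increasing")
  }
  regulated <- params$mode %in% c("regulated", "mutant_no_pulse")
  if (regulated && is.null(promoter)) {
    stop("simulate_batch: regulated/mutant modes need promoter parameters")
  }
  has_pa <- !is.null(promoter)
  mu0_min <- params$mu0 / 60
  S <- params$s0 + params$s_carryover

  # uptake is yield-coupled to growth (ds = -c dOD), so substrate follows
  # algebraically from the biomass state; this enforces the conservation law
  # exactly and keeps the exhausted-substrate plateau non-stiff
  s_of_od <- function(od) pmax(S - params$c * (od - params$od0), 0)

  y0 <- c(od = params$od0, gfp = 0)
  if (regulated) y0 <- c(y0, e = 1)

  # in the stationary-entry mode gene expression winds down with the same
  # density factor as growth (global downregulation on entry to stationary
  # phase): the reporter then declines gradually instead of pulsing when the
  # leftover substrate is finally consumed at high density
  density_inhib <- function(od) {
    1 / (1 + (od / params$density_cap_od)^params$density_cap_exponent)
  }

  deriv <- function(t, y, parms) {
    od <- y[["od"]]
    s <- s_of_od(od)
    mu <- switch(params$mode,
      monod = mu0_min * s / (params$Ks + s),
      nonlimiting_entry = mu0_min * s / (params$Ks + s) * density_inhib(od),
      regulated = mu0_min * s /
        (s + params$Ks * promoter$enzyme_gain / y[["e"]]),
      mutant_no_pulse = mu0_min * s /
        (s + params$Ks * promoter$enzyme_gain))
    pa <- if (has_pa) promoter_activity(s, promoter) else 0
    if (params$mode == "nonlimiting_entry") pa <- pa * density_inhib(od)
    dy <- c(od = mu * od, gfp = pa * od)
    if (params$mode == "regulated") {
      dy <- c(dy, e = mu0_min * (pa / promoter$pa_basal - y[["e"]]))
    } else if (params$mode == "mutant_no_pulse") {
      dy <- c(dy, e = 0)
    }
    list(dy)
  }

  times <- if (grid[1] > 0) c(0, grid) else grid
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda",
                      rtol = params$solver_rel_tol,
                      atol = params$solver_abs_tol)
  if (attr(sol, "istate")[1L] < 0) {
    stop("simulate_batch: ODE integration failed (istate = ",
         attr(sol, "istate")[1L], ")")
  }
  sol <- as.data.frame(sol)
  if (grid[1] > 0) sol <- sol[-1L, , drop = FALSE]
  # the yield cap is a hard bound; trim sub-tolerance solver overshoot
  sol$od <- pmin(sol$od, params$od0 + S / params$c)
  s_out <- s_of_od(sol$od)
  pa_out <- if (has_pa) promoter_activity(s_out, promoter) else rep(0, nrow(sol))
  if (params$mode == "nonlimiting_entry") pa_out <- pa_out * density_inhib(sol$od)
  out <- data.frame(time = sol$time, od = sol$od, s = s_out,
                    pa = pa_out, gfp = sol$gfp)
  if (regulated) out$e <- sol$e
  attr(out, "params") <- params
  attr(out, "promoter") <- promoter
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' Closed-form time to reach a target OD under Monod batch growth
#'
#' Independent oracle for the monod-mode integrator. Separating variables in
#' the coupled system `dOD/dt = mu(s) OD`, `s = S - c (OD - od0)` (with
#' `S = s0 + s_carryover`) gives an explicit time as a function of OD:
#'
#' `t(OD) = (60/mu0) * [ (1 + Ks/B) * ln(OD/od0) + (Ks/B) * ln(S / s(OD)) ]`
#'
#' where `B = S + c * od0`. This is evaluated directly, with no ODE solver.
#'
#' @param od_target Target OD; must satisfy
#'   `od0 < od_target < od0 + (s0 + s_carryover)/c`.
#' @param params A [sim_params()] object in monod mode.
#' @return Time in minutes at which the culture reaches `od_target`.
#' @export
implicit_monod_time <- function(od_target, params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$mode != "monod") {
    stop("implicit_monod_time: only defined for monod mode")
  }
  S <- params$s0 + params$s_carryover
  od_max <- params$od0 + S / params$c
  if (any(od_target < params$od0) || any(od_target >= od_max)) {
    stop(sprintf(
      "implicit_monod_time: 'od_target' must lie in [od0, od0 + S/c) = [%g, %g)",
      params$od0, od_max))
  }
  B <- S + params$c * params$od0
  s_at <- B - params$c * od_target
  (60 / params$mu0) * ((1 + params$Ks / B) * log(od_target / params$od0) +
                         (params$Ks / B) * log(S / s_at))
}
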