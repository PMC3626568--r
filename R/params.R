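#' Kinetic and simulation parameters for a batch culture
#'
#' Container for the ground-truth constants of the forward model: Monod
#' kinetics, yield-coupled substrate depletion, and the phenomenological
#' stationary-entry mode. Time is handled in minutes internally; growth rates
#' are expressed in 1/h throughout the public interface.
#'
#' @param mu0 Maximal specific growth rate (1/h). Default `log(2)/59*60`,
#'   i.e. a 59-min generation time.
#' @param Ks Monod half-saturation constant (mM). Default 0.0026 mM (2.6 uM),
#'   the nitrogen value; use 0.005 mM for glucose.
#' @param c Substrate-to-biomass conversion: mM of substrate consumed per OD
#'   unit produced (reciprocal of the final-OD calibration slope). Default
#'   15.1 (nitrogen); 21.3 for glucose.
#' @param s0 Initial limiting-substrate concentration (mM), excluding
#'   inoculum carryover.
#' @param s_carryover Substrate carried over with the inoculum (mM). Default
#'   0.09 mM, sized so that the final-OD calibration intercept lands near the
#'   observed few-thousandths of an OD unit.
#' @param od0 Inoculum optical density. Default 0.002 (a 1:500 dilution of a
#'   dense overnight culture).
#' @param t_end Simulation horizon (min). Default 1200 (20 h).
#' @param mode Growth-law variant: `"monod"` (plain Monod depletion),
#'   `"regulated"` (assimilation enzyme induced by the promoter pulse lowers
#'   the effective Ks), `"mutant_no_pulse"` (regulated equations with the
#'   enzyme frozen at its basal level), or `"nonlimiting_entry"`
#'   (density-dependent inhibition producing a gradual entry to stationary
#'   phase).
#' @param density_cap_od OD scale of the non-substrate growth inhibition used
#'   by `nonlimiting_entry` (OD units).
#' @param density_cap_exponent Steepness of that inhibition (unitless).
#' @param solver_rel_tol,solver_abs_tol ODE solver tolerances.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [promoter_params()], [simulate_batch()]
#' @export
sim_params <- function(mu0 = log(2) / 59 * 60,
                       Ks = 0.0026,
                       c = 15.1,
                       s0 = 0.2,
                       s_carryover = 0.09,
                       od0 = 0.002,
                       t_end = 1200,
                       mode = c("monod", "regulated", "mutant_no_pulse",
                                "nonlimiting_entry"),
                       density_cap_od = 0.45,
                       density_cap_exponent = 3,
                       solver_rel_tol = 1e-8,
                       solver_abs_tol = 1e-10) {
  mode <- match.arg(mode)
  p <- list(mu0 = mu0, Ks = Ks, c = c, s0 = s0, s_carryover = s_carryover,
            od0 = od0, t_end = t_end, mode = mode,
            density_cap_od = density_cap_od,
            density_cap_exponent = density_cap_exponent,
            solver_rel_tol = solver_rel_tol, solver_abs_tol = solver_abs_tol)
  for (nm in c("mu0", "Ks", "c", "od0", "t_end", "density_cap_od",
               "solver_rel_tol", "solver_abs_tol")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop(sprintf("sim_params: '%s' must be a single positive number", nm))
    }
  }
  if (!is.numeric(s0) || s0 < 0) stop("sim_params: 's0' must be >= 0")
  if (!is.numeric(s_carryover) || s_carryover < 0) {
    stop("sim_params: 's_carryover' must be >= 0")
  }
  structure(p, class = "sim_params")
}

#' Promoter activity model parameters
#'
#' Parameters of the band-pass promoter activity model: a Hill activation gate
#' that opens as substrate falls below `theta_on`, and a Hill shutdown gate
#' that closes activity as substrate is exhausted below `theta_off`.
#'
#' @param pa_basal Basal promoter activity (AU per OD per min).
#' @param fold_amp Peak-to-basal amplitude of the pulse (unitless, >= 1).
#' @param theta_on Substrate threshold below which activity rises (mM).
#'   Default 0.25 mM.
#' @param h_on Hill coefficient of activation. Default 12: the activation is
#'   ultrasensitive, confining induction to substrate below ~0.3 mM so that
#'   exponential-phase basal activity is independent of the starting nutrient
#'   level. (A shallow gate, e.g. h_on = 4, is already 1.5-2.5x induced at
#'   inoculation for starting substrate of 0.3-0.6 mM.)
#' @param theta_off Substrate level below which activity shuts down (mM).
#' @param h_off Hill coefficient of the shutdown gate.
#' @param enzyme_gain Relative boost of assimilation capacity at full
#'   induction (unitless, >= 1; used only in regulated/mutant modes).
#'
#' @return An object of class `promoter_params`.
#' @export
promoter_params <- function(pa_basal = 50,
                            fold_amp = 5,
                            theta_on = 0.25,
                            h_on = 12,
                            theta_off = 0.005,
                            h_off = 4,
                            enzyme_gain = 5) {
  p <- list(pa_basal = pa_basal, fold_amp = fold_amp, theta_on = theta_on,
            h_on = h_on, theta_off = theta_off, h_off = h_off,
            enzyme_gain = enzyme_gain)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1)))) {
    stop("promoter_params: all parameters must be single finite numbers")
  }
  if (pa_basal <= 0) stop("promoter_params: 'pa_basal' must be > 0")
  if (fold_amp < 1) stop("promoter_params: 'fold_amp' must be >= 1")
  if (theta_off >= theta_on) {
    stop("promoter_params: 'theta_off' must be below 'theta_on'")
  }
  if (h_on < 1 || h_off < 1) {
    stop("promoter_params: Hill coefficients must be >= 1")
  }
  if (enzyme_gain < 1) stop("promoter_params: 'enzyme_gain' must be >= 1")
  structure(p, class = "promoter_params")
}

#' Replicate noise model for synthetic plates
#'
#' Multiplicative lognormal noise decomposition for the plate generator:
#' one static scale factor per well (pipetting/optics spread, preserved across
#' time so that log-derivatives are unaffected), small per-read noise, and one
#' day-scale factor per plate. All factors have mean exactly 1.
#'
#' Defaults are calibrated to the assay they emulate: a 13% per-well spread
#' plus 2% per-read noise gives `sqrt(0.13^2 + 0.02^2)/sqrt(48)` ~ 1.9%
#' standard error of the mean OD over 48 replicates; GFP read noise of 3%
#' yields ~3% standard error on promoter activity after the sliding-window
#' derivative; the day factor spread is 7%.
#'
#' @param well_scale_cv Static per-well multiplicative scale CV (fraction).
#' @param read_cv Per-read multiplicative OD noise CV (fraction).
#' @param gfp_read_cv Per-read GFP noise CV (fraction).
#' @param day_scale_cv Per-plate (per-day) multiplicative factor CV (fraction).
#' @param seed Integer random seed; generation is deterministic given it.
#'
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(well_scale_cv = 0.13,
                         read_cv = 0.02,
                         gfp_read_cv = 0.03,
                         day_scale_cv = 0.07,
                         seed = 1L) {
  for (v in c(well_scale_cv, read_cv, gfp_read_cv, day_scale_cv)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("noise_params: all CVs must be single numbers >= 0")
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("noise_params: 'seed' must be a single integer")
  }
  structure(list(well_scale_cv = well_scale_cv, read_cv = read_cv,
                 gfp_read_cv = gfp_read_cv, day_scale_cv = day_scale_cv,
                 seed = as.integer(seed)),
            class = "noise_params")
}

# mean-1 lognormal deviates with a given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default nutrient panels
#'
#' The initial-substrate series emulated by the study design: an M9 nitrogen
#' (NH4Cl) series from 0.16 to 18.7 mM and a glucose series from 0.14 to
#' 11 mM. The highest level of each panel is non-limiting (growth there stops
#' by density-dependent entry to stationary phase, not substrate exhaustion).
#'
#' @return Numeric vector of initial substrate levels (mM).
#' @export
default_nitrogen_levels <- function() {
  c(0.16, 0.2, 0.24, 0.31, 0.47, 0.94, 2.0, 18.7)
}

#' @rdname default_nitrogen_levels
#' @export
default_glucose_levels <- function() {
  c(0.14, 0.28, 0.56, 2.8, 11)
}

#' Nutrient-specific kinetic constants
#'
#' The per-nutrient defaults used throughout: half-saturation constant Ks and
#' substrate-to-OD conversion c (mM consumed per OD unit produced).
#'
#' @param nutrient `"nitrogen"` or `"glucose"`.
#' @return A list with elements `Ks` (mM) and `c` (mM per OD).
#' @export
nutrient_defaults <- function(nutrient = c("nitrogen", "glucose")) {
  nutrient <- match.arg(nutrient)
  switch(nutrient,
         nitrogen = list(Ks = 0.0026, c = 15.1),
         glucose = list(Ks = 0.005, c = 21.3))
}
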