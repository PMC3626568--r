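#' Pair growth rate with substrate in the deceleration phase
#'
#' Builds the (s, mu) point cloud that carries information about the Monod
#' half-saturation constant: exponential-phase points (s >> Ks) pin mu0 but
#' say nothing about Ks, and post-arrest plateau points have mu ~ 0 with
#' noise-dominated inferred substrate, so only the deceleration window is
#' kept: `0 < s <= s_window_mM`, and time restricted to
#' `[t_dec_start - t_pad, t_arrest]` when an [detect_arrest()] result is
#' supplied.
#'
#' @param gr A [growth_rate_series()] (typically computed with the narrow
#'   9-min window; see [fit_monod()]).
#' @param ss A [infer_substrate()] result on the same time grid.
#' @param s_window_mM Upper substrate cut (mM), default 0.05 (~20x the
#'   expected Ks).
#' @param arrest Optional `arrest_result` bounding the deceleration phase.
#' @param t_pad Minutes added before `t_dec_start` (default one window).
#' @param min_points Minimum number of surviving points (default 5); fewer
#'   raises an error advising more conditions or seeds. Use 0 when pooling
#'   across conditions and checking the pooled count instead.
#' @return data.frame with columns `condition_id`, `time`, `s`, `mu`.
#' @export
select_deceleration_points <- function(gr, ss, s_window_mM = 0.05,
                                       arrest = NULL, t_pad = NULL,
                                       min_points = 5L) {
  stopifnot(inherits(gr, "growth_rate_series"),
            inherits(ss, "substrate_series"))
  common <- intersect(gr$times, ss$times)
  if (length(common) == 0L) {
    stop("select_deceleration_points: series share no time points")
  }
  mu <- gr$mu[match(common, gr$times)]
  s <- ss$s[match(common, ss$times)]
  keep <- is.finite(mu) & s > 0 & s <= s_window_mM
  if (!is.null(arrest) && !is.na(arrest$t_arrest)) {
    if (is.null(t_pad)) t_pad <- gr$window_min
    keep <- keep & common >= arrest$t_dec_start - t_pad &
      common <= arrest$t_arrest
  }
  if (sum(keep) < min_points) {
    stop("select_deceleration_points: only ", sum(keep), " points with 0 < s <= ",
         s_window_mM, " mM; pool more conditions or replicates")
  }
  data.frame(condition_id = if (is.null(gr$condition_id)) NA_character_
             else gr$condition_id,
             time = common[keep], s = s[keep], mu = mu[keep],
             stringsAsFactors = FALSE)
}

#' Deceleration-phase Monod input points with measurement-error scales
#'
#' The estimator-grade constructor of (s, mu) pairs for uM-scale Monod
#' fitting. Working from the replicate-averaged OD series directly, it
#'
#' 1. anchors substrate to the measured plateau,
#'    `s(t) = c * (OD_f - OD(t))` with `OD_f` a long-tail median
#'    (`tail_min`, default 180 min) - self-correcting for inoculum carryover
#'    and scale factors;
#' 2. projects the substrate series onto non-increasing sequences (isotonic
#'    regression; monotone depletion is a hard physical constraint and the
#'    projection pools away plateau noise);
#' 3. computes growth rates between successive OD measurements
#'    (`mu = diff(ln OD)/dt`, assigned to interval midpoints) - the assay's
#'    native rate definition; wider smoothing windows average the rate over
#'    a transition that is faster than the sampling and bias Ks upward
#'    (about 2-4 fold for a 21-min window in simulation);
#' 4. pairs each rate with the logarithmic mean of the interval-endpoint
#'    substrates, `(s1 - s2)/ln(s1/s2)`: the interval rate is the time
#'    average of mu, and for near-exponential substrate decay (s << Ks) the
#'    time-averaged mu equals mu evaluated at exactly the log-mean s;
#' 5. keeps points in the deceleration window (`0 < s <= s_window_mM`,
#'    between the start of deceleration and the arrest) that are above the
#'    substrate noise floor (`floor_k` times the per-point substrate noise,
#'    estimated from the plateau jitter) and above `mu_floor_frac * mu_max`
#'    (rates below that sit within one sampling interval of complete arrest
#'    and are unmeasurable at the sampling resolution);
#' 6. attaches per-condition noise scales: `sx` (mM, substrate) and `sy`
#'    (1/h, rate), both estimated from the plateau jitter of the same
#'    series, plus `mu0_exp`, the median exponential-phase rate.
#'
#' @param series A `condition_series`.
#' @param c_od Conversion factor (mM per OD).
#' @param s_window_mM Upper substrate cut (mM), default 0.05.
#' @param mu_floor_frac Minimum rate as a fraction of `mu_max`, default 0.2.
#' @param floor_k Substrate noise-floor multiplier, default 1.
#' @param tail_min Plateau tail for the anchor (min), default 180.
#' @param window_min Smoothing window for arrest detection (min), default 21.
#' @return data.frame with columns `condition_id`, `time`, `s`, `mu`, `sx`,
#'   `sy`, `mu0_exp` (possibly 0 rows if the condition has no usable
#'   deceleration points).
#' @export
monod_input_points <- function(series, c_od, s_window_mM = 0.05,
                               mu_floor_frac = 0.2, floor_k = 1,
                               tail_min = 180, window_min = 21) {
  gr <- growth_rate_series(series, window_min = window_min)
  arrest <- detect_arrest(gr)
  tt <- series$times
  lod <- log(series$mean_od)
  n <- length(tt)

  odf <- stats::median(series$mean_od[tt >= max(tt) - tail_min])
  s_raw <- pmax(c_od * (odf - series$mean_od), 0)
  s <- -stats::isoreg(tt, -s_raw)$yf

  mu <- diff(lod) / diff(tt) * 60
  tmid <- (tt[-1L] + tt[-n]) / 2
  s1 <- s[-n]
  s2 <- s[-1L]
  x <- ifelse(s1 > 0 & s2 > 0,
              ifelse(abs(s1 - s2) < 1e-12, s1,
                     (s1 - s2) / log(pmax(s1, 1e-300) / pmax(s2, 1e-300))),
              NA_real_)

  tail_sel <- tt >= max(tt) - 60
  sx <- max(c_od * stats::sd(diff(series$mean_od[tail_sel])) / sqrt(2), 1e-6)
  sy <- max(stats::sd(diff(lod[tail_sel])) / sqrt(2) * sqrt(2) /
              stats::median(diff(tt)) * 60, 1e-4)
  basal <- gr$times < arrest$t_dec_start & gr$times >= 30
  mu0_exp <- stats::median(gr$mu[basal], na.rm = TRUE)

  keep <- is.finite(mu) & is.finite(x) & x > floor_k * sx &
    x <= s_window_mM & mu >= mu_floor_frac * gr$mu_max
  if (!is.na(arrest$t_arrest)) {
    keep <- keep & tmid >= arrest$t_dec_start - window_min &
      tmid <= arrest$t_arrest
  }
  data.frame(condition_id = series$condition_id, time = tmid[keep],
             s = x[keep], mu = mu[keep], sx = sx, sy = sy,
             mu0_exp = mu0_exp, stringsAsFactors = FALSE)
}

#' Measurement-error-aware Monod fit with pinned maximal rate
#'
#' One-parameter profile fit of the half-saturation constant. The maximal
#' rate is pinned to its exponential-phase estimate (where it is measured to
#' well under a percent), which removes the strong Ks-mu0 inflation
#' covariance of the joint fit. Ks is then estimated by maximum likelihood
#' under Gaussian errors in both coordinates (errors-in-variables): for each
#' candidate Ks the latent substrate of every point is profiled out by
#' minimizing `((mu - f(s'))/sy)^2 + ((s - s')/sx)^2`. Plain least squares
#' on the same points is biased upward because the substrate noise is
#' comparable to Ks itself and noise in the two coordinates is correlated
#' through the shared OD readings.
#'
#' @param points data.frame from [monod_input_points()] (needs columns `s`,
#'   `mu`, `sx`, `sy`, `mu0_exp`), typically pooled over the limiting
#'   conditions.
#' @param mu0 Fixed maximal rate (1/h); default the mean of the points'
#'   per-condition exponential-phase estimates.
#' @param Ks_range Search interval for Ks (mM).
#' @param bootstrap_reps Case-resampling bootstrap replicates for the Ks
#'   confidence interval (0 to skip).
#' @param seed Seed for the bootstrap.
#' @return An object of class `monod_fit` (same shape as [fit_monod()],
#'   `diagnostic = "eiv, mu0 pinned"`).
#' @export
fit_monod_eiv <- function(points, mu0 = NULL, Ks_range = c(2e-4, 0.05),
                          bootstrap_reps = 0L, seed = NULL) {
  stopifnot(is.data.frame(points),
            all(c("s", "mu", "sx", "sy") %in% names(points)))
  if (nrow(points) < 5L) stop("fit_monod_eiv: need at least 5 points")
  if (is.null(mu0)) {
    if (!"mu0_exp" %in% names(points)) {
      stop("fit_monod_eiv: supply 'mu0' or points with a 'mu0_exp' column")
    }
    mu0 <- mean(points$mu0_exp)
  }
  profile_rss <- function(Ks, d) {
    tot <- 0
    for (i in seq_len(nrow(d))) {
      f <- function(si) {
        ((d$mu[i] - mu0 * si / (Ks + si)) / d$sy[i])^2 +
          ((d$s[i] - si) / d$sx[i])^2
      }
      tot <- tot + stats::optimize(f, c(0, 2 * max(Ks_range)))$objective
    }
    tot
  }
  est <- function(d) {
    exp(stats::optimize(function(lk) profile_rss(exp(lk), d),
                        log(Ks_range))$minimum)
  }
  Ks_hat <- est(points)
  res <- structure(list(mu0_hat = mu0, Ks_hat = Ks_hat,
                        mu0_ci = c(NA_real_, NA_real_),
                        Ks_ci = c(NA_real_, NA_real_),
                        n_points = nrow(points),
                        rss = profile_rss(Ks_hat, points),
                        converged = TRUE,
                        diagnostic = "eiv, mu0 pinned",
                        bootstrap_reps = 0L),
                   class = "monod_fit")
  if (bootstrap_reps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(points)
    reps <- vapply(seq_len(bootstrap_reps), function(i) {
      est(points[sample.int(n, n, replace = TRUE), , drop = FALSE])
    }, numeric(1))
    res$Ks_ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE))
    res$bootstrap_reps <- bootstrap_reps
  }
  res
}

#' Fit the Monod law to (substrate, growth-rate) points
#'
#' Nonlinear least squares of `mu = mu0 * s / (Ks + s)` over deceleration
#' points, typically pooled across limiting conditions. Initialization:
#' `mu0` at the maximal observed rate, `Ks` at the substrate level nearest
#' half-maximum. Confidence intervals by case-resampling bootstrap (the
#' points are few and their errors heteroscedastic, so asymptotic intervals
#' are avoided). A degenerate design (substrate span < 10-fold, no curvature
#' information) yields `converged = FALSE` with a diagnostic rather than an
#' error, as does an optimizer failure.
#'
#' @param points data.frame with columns `s` (mM) and `mu` (1/h), e.g. from
#'   [select_deceleration_points()].
#' @param bootstrap_reps Number of bootstrap resamples (default 500).
#' @param seed Seed for the bootstrap resampling.
#' @param conf_level Confidence level for the bootstrap percentile intervals.
#' @return An object of class `monod_fit`: list with `mu0_hat`, `Ks_hat`
#'   (mM), `mu0_ci`, `Ks_ci`, `n_points`, `rss`, `converged`, `diagnostic`,
#'   `bootstrap_reps`.
#' @export
fit_monod <- function(points, bootstrap_reps = 500L, seed = NULL,
                      conf_level = 0.95) {
  stopifnot(is.data.frame(points), all(c("s", "mu") %in% names(points)))
  n <- nrow(points)
  res <- structure(list(mu0_hat = NA_real_, Ks_hat = NA_real_,
                        mu0_ci = c(NA_real_, NA_real_),
                        Ks_ci = c(NA_real_, NA_real_),
                        n_points = n, rss = NA_real_, converged = FALSE,
                        diagnostic = "", bootstrap_reps = 0L),
                   class = "monod_fit")
  if (n < 5L) stop("fit_monod: need at least 5 points")
  span <- max(points$s) / min(points$s)
  if (!is.finite(span) || span < 10) {
    res$diagnostic <- "Ks unidentifiable: substrate span < 10-fold"
    return(res)
  }
  single <- function(d) {
    mu0_0 <- max(d$mu)
    Ks_0 <- max(d$s[which.min(abs(d$mu - mu0_0 / 2))], min(d$s) / 2, 1e-6)
    fit <- tryCatch(
      minpack.lm::nlsLM(mu ~ mu0 * s / (Ks + s), data = d,
                        start = list(mu0 = mu0_0, Ks = Ks_0),
                        lower = c(mu0 = 0, Ks = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    list(mu0 = unname(cf["mu0"]), Ks = unname(cf["Ks"]),
         rss = sum(stats::residuals(fit)^2))
  }
  main <- single(points)
  if (is.null(main)) {
    res$diagnostic <- "optimizer failed"
    return(res)
  }
  res$mu0_hat <- main$mu0
  res$Ks_hat <- main$Ks
  res$rss <- main$rss
  res$converged <- TRUE

  if (bootstrap_reps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(bootstrap_reps), function(i) {
      b <- single(points[sample.int(n, n, replace = TRUE), , drop = FALSE])
      if (is.null(b)) c(NA_real_, NA_real_) else c(b$mu0, b$Ks)
    }, numeric(2))
    alpha <- (1 - conf_level) / 2
    res$mu0_ci <- unname(stats::quantile(reps[1L, ], c(alpha, 1 - alpha),
                                         na.rm = TRUE))
    res$Ks_ci <- unname(stats::quantile(reps[2L, ], c(alpha, 1 - alpha),
                                        na.rm = TRUE))
    res$bootstrap_reps <- sum(is.finite(reps[2L, ]))
  }
  res
}
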