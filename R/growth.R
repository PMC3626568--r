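#' Average replicate wells into per-condition series
#'
#' For every condition on the plate(s), computes the mean and standard error
#' of the mean over the wells present, per time point and channel (OD and,
#' where measured, GFP, each on its own grid). Wells absent from a dataset
#' simply reduce `n_wells`; with a single well the SEM is reported as `NA`.
#'
#' @param datasets A `plate_dataset` or a list of them (e.g. several plates
#'   of one experiment; conditions are pooled across plates by id).
#' @return A named list of `condition_series` objects, each a list with
#'   `condition_id`, `condition` (the [plate_condition()]), `times`,
#'   `mean_od`, `sem_od`, `n_wells`, and (if GFP present) `gfp_times`,
#'   `mean_gfp`, `sem_gfp`, `n_wells_gfp`.
#' @export
average_replicates <- function(datasets) {
  if (inherits(datasets, "plate_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "plate_dataset")))

  rec <- do.call(rbind, lapply(datasets, function(d) {
    merge(d$records, d$design$wells,
          by.x = c("well"), by.y = "well", sort = FALSE)
  }))
  conds <- do.call(c, lapply(datasets, function(d) d$design$conditions))
  conds <- conds[!duplicated(names(conds))]

  out <- lapply(unique(rec$condition_id), function(cid) {
    sub <- rec[rec$condition_id == cid, , drop = FALSE]
    if (nrow(sub) == 0L) stop("average_replicates: condition with 0 wells: ", cid)
    ser <- list(condition_id = cid, condition = conds[[cid]])
    od <- channel_stats(sub[sub$channel == "OD600", , drop = FALSE])
    ser$times <- od$times
    ser$mean_od <- od$mean
    ser$sem_od <- od$sem
    ser$n_wells <- od$n
    gf <- sub[sub$channel == "GFP535", , drop = FALSE]
    if (nrow(gf)) {
      g <- channel_stats(gf)
      ser$gfp_times <- g$times
      ser$mean_gfp <- g$mean
      ser$sem_gfp <- g$sem
      ser$n_wells_gfp <- g$n
    }
    structure(ser, class = "condition_series")
  })
  names(out) <- unique(rec$condition_id)
  out
}

channel_stats <- function(sub) {
  if (nrow(sub) == 0L) stop("average_replicates: channel has no records")
  times <- sort(unique(sub$time_min))
  wells <- unique(paste(sub$plate_id, sub$well))
  m <- matrix(NA_real_, nrow = length(times), ncol = length(wells),
              dimnames = list(NULL, wells))
  idx_t <- match(sub$time_min, times)
  idx_w <- match(paste(sub$plate_id, sub$well), wells)
  m[cbind(idx_t, idx_w)] <- sub$value
  n <- rowSums(!is.na(m))
  mean_v <- rowMeans(m, na.rm = TRUE)
  sem <- if (ncol(m) >= 2L) {
    apply(m, 1L, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1))
  } else rep(NA_real_, length(times))
  list(times = times, mean = mean_v, sem = sem, n = length(wells))
}

# OLS slope of y on x for each centered sliding window of width `width`
# (one-sided truncated at the ends). Returns slope and per-point support.
sliding_slope <- function(x, y, width) {
  n <- length(x)
  slope <- support <- numeric(n)
  half <- width / 2
  for (i in seq_len(n)) {
    j <- which(x >= x[i] - half & x <= x[i] + half)
    support[i] <- length(j)
    if (length(j) < 2L) {
      slope[i] <- NA_real_
      next
    }
    xc <- x[j] - mean(x[j])
    slope[i] <- sum(xc * y[j]) / sum(xc^2)
  }
  list(slope = slope, support = support)
}

#' Growth rate as the logarithmic derivative of OD
#'
#' Estimates the instantaneous specific growth rate mu(t) at every time point
#' as the slope of an ordinary least-squares line fitted to `ln(mean_od)`
#' versus time over a centered sliding window (one-sided truncated at the
#' series ends), converted to 1/h. Static per-well scale factors and day
#' factors cancel exactly in the logarithmic derivative.
#'
#' `mu_max` is the maximum of mu over points with at least half-window
#' support, and `generation_time = ln(2)/mu_max` in minutes.
#'
#' @param series A `condition_series` (from [average_replicates()]) or any
#'   list with `times` (min) and `mean_od`.
#' @param window_min Smoothing window width (min); must cover at least two
#'   sampling intervals. Default 21 min (7 points at 3-min sampling), robust
#'   to ~2% SEM noise; a narrower window (9 min) is used when feeding the
#'   Monod fit to limit smearing of the deceleration transition.
#' @return An object of class `growth_rate_series`: list with `times`, `mu`
#'   (1/h), `support`, `window_min`, `mu_max`, `generation_time` (min).
#' @export
growth_rate_series <- function(series, window_min = 21) {
  times <- series$times
  od <- series$mean_od
  if (any(od <= 0)) stop("growth_rate_series: OD must be positive everywhere")
  dt <- stats::median(diff(times))
  if (window_min < 2 * dt) {
    stop("growth_rate_series: window must span at least 2 sampling intervals")
  }
  if (window_min > diff(range(times))) {
    stop("growth_rate_series: window larger than the series")
  }
  ss <- sliding_slope(times, log(od), window_min)
  mu <- ss$slope * 60
  full <- max(ss$support)
  eligible <- ss$support >= ceiling(full / 2)
  # robust maximum: median of the 5 largest eligible rates; a plain max over
  # ~10^2 noisy points is biased upward by extreme-value selection
  top <- sort(mu[eligible], decreasing = TRUE)
  mu_max <- stats::median(top[seq_len(min(5L, length(top)))])
  structure(list(condition_id = series$condition_id,
                 times = times, mu = mu, support = ss$support,
                 window_min = window_min, mu_max = mu_max,
                 generation_time = log(2) / mu_max * 60),
            class = "growth_rate_series")
}

#' Detect growth arrest and classify the stop
#'
#' Locates the growth arrest as the first time the growth rate stays at or
#' below `frac_low * mu_max` for at least `sustain_min` minutes, and the
#' start of deceleration as the last preceding time with
#' `mu >= frac_high * mu_max`. The deceleration duration
#' `T_dec = t_arrest - t_dec_start` drives the classification:
#'
#' * `abrupt` if `T_dec <= 60` min;
#' * `mixed` if a gradual drift below `frac_high` (>= 60 min) precedes a
#'   terminal drop of at least `0.5 * mu_max` completed within the last
#'   60 min, or if `T_dec` falls between 60 and 120 min;
#' * `gradual` if `T_dec >= 120` min with no such terminal drop.
#'
#' If the rate never stays below `frac_low * mu_max`, the series is reported
#' as `no_arrest` rather than raising an error.
#'
#' @param gr A [growth_rate_series()].
#' @param frac_high Fraction of `mu_max` defining "still at maximal growth"
#'   (default 0.9).
#' @param frac_low Fraction of `mu_max` operationalizing "zero growth"
#'   (default 0.05).
#' @param sustain_min Minimum duration (min) the rate must stay low
#'   (default 15).
#' @return An object of class `arrest_result`: list with `t_arrest`,
#'   `t_dec_start`, `T_dec`, `stop_class`, `mu_max` and the thresholds used.
#' @export
detect_arrest <- function(gr, frac_high = 0.9, frac_low = 0.05,
                          sustain_min = 15) {
  stopifnot(inherits(gr, "growth_rate_series"))
  times <- gr$times
  mu <- gr$mu
  mu_max <- gr$mu_max
  low <- !is.na(mu) & mu <= frac_low * mu_max

  t_arrest <- NA_real_
  for (i in which(low)) {
    if (times[i] + sustain_min > times[length(times)]) break
    j <- which(times >= times[i] & times <= times[i] + sustain_min)
    if (all(low[j])) {
      t_arrest <- times[i]
      break
    }
  }
  base <- list(mu_max = mu_max, frac_high = frac_high, frac_low = frac_low,
               sustain_min = sustain_min)
  if (is.na(t_arrest)) {
    return(structure(c(list(t_arrest = NA_real_, t_dec_start = NA_real_,
                            T_dec = NA_real_, stop_class = "no_arrest"),
                       base), class = "arrest_result"))
  }
  high_idx <- which(!is.na(mu) & mu >= frac_high * mu_max & times < t_arrest)
  t_dec_start <- if (length(high_idx)) times[max(high_idx)] else times[1L]
  T_dec <- t_arrest - t_dec_start

  stop_class <- if (T_dec <= 60) {
    "abrupt"
  } else {
    mu_before <- stats::approx(times, mu, t_arrest - 60, rule = 2)$y
    terminal_drop <- is.finite(mu_before) &&
      mu_before >= (0.5 + frac_low) * mu_max
    if (T_dec >= 120 && !terminal_drop) "gradual" else "mixed"
  }
  structure(c(list(t_arrest = t_arrest, t_dec_start = t_dec_start,
                   T_dec = T_dec, stop_class = stop_class), base),
            class = "arrest_result")
}
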