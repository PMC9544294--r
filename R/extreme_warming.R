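# Per-window OLS machinery shared by the global-rate and per-cell stages.
# slope of y on t by the closed form sum((t - tbar) y) / sum((t - tbar)^2);
# residual SD uses denominator n - 2 (OLS residual degrees of freedom).
window_ols <- function(years, ymat) {
  xc <- years - mean(years)
  sxx <- sum(xc^2)
  n <- length(years)
  slope <- as.numeric(crossprod(xc, ymat)) / sxx
  ybar <- colMeans(ymat)
  fitted <- outer(xc, slope) + rep(ybar, each = n)
  rss <- colSums((ymat - fitted)^2)
  list(slope = slope, resid_sd = sqrt(rss / (n - 2)))
}

#' Sliding centennial warming rates of the global-mean SST
#'
#' Slides a `window_yr`-year window in steps of `step_yr` years over the
#' area-weighted global-mean SST and reports each window's OLS warming rate
#' in degrees C per century.
#'
#' @param x an [sst_series()], or a numeric global-mean series with a
#'   `years` attribute (or named by year).
#' @param window_yr window length in years (inclusive endpoints).
#' @param step_yr step between window starts.
#' @return data frame of class `century_windows`: `start_year`, `end_year`,
#'   `global_rate` (degrees C/century), `is_extreme` (`NA` until
#'   [classify_extreme()]).
#' @export
centennial_rates <- function(x, window_yr = 100L, step_yr = 10L) {
  if (inherits(x, "sst_series")) {
    years <- x$years
    g <- global_mean_series(x)
  } else {
    g <- as.numeric(x)
    years <- attr(x, "years")
    if (is.null(years) && !is.null(names(x))) years <- as.integer(names(x))
    if (is.null(years)) years <- seq_along(g)
  }
  if (length(g) < window_yr)
    stop("series shorter than one window (", window_yr, " years)")
  starts <- seq(1L, length(g) - window_yr + 1L, by = step_yr)
  rate <- vapply(starts, function(s) {
    idx <- s:(s + window_yr - 1L)
    t <- years[idx]
    xc <- t - mean(t)
    sum(xc * g[idx]) / sum(xc^2) * 100
  }, numeric(1))
  out <- data.frame(start_year = years[starts],
                    end_year = years[starts + window_yr - 1L],
                    global_rate = rate,
                    is_extreme = NA)
  class(out) <- c("century_windows", "data.frame")
  out
}

#' Calibrate the extreme-warming threshold from control-run windows
#'
#' The threshold is the stated percentile (linear-interpolation percentile)
#' of the control run's centennial global warming rates. Users may bypass
#' calibration entirely and set a fixed threshold (e.g. 0.18 degrees
#' C/century) in the pipeline configuration.
#'
#' @param control_windows a `century_windows` data frame (or numeric rates).
#' @param percentile percentile in `[0, 100]`.
#' @return threshold in degrees C per century.
#' @export
calibrate_threshold <- function(control_windows, percentile = 95) {
  rates <- if (is.data.frame(control_windows)) control_windows$global_rate
           else as.numeric(control_windows)
  if (length(rates) < 20)
    stop("need at least 20 control windows to calibrate (got ",
         length(rates), ")")
  as.numeric(stats::quantile(rates, percentile / 100, type = 7, names = FALSE))
}

#' Flag extreme centennial windows
#'
#' A window is extreme iff its global rate meets or exceeds the threshold
#' (inclusive).
#'
#' @param windows a `century_windows` data frame.
#' @param threshold degrees C per century.
#' @return the windows with `is_extreme` set.
#' @export
classify_extreme <- function(windows, threshold) {
  windows$is_extreme <- windows$global_rate >= threshold
  windows
}

#' Per-cell trend, variability and pattern-scaled SNR over an era's extreme
#' windows
#'
#' For every extreme window whose start year falls in `era_range`, computes
#' the per-cell OLS trend and residual SD, then averages over windows. The
#' mean trend is pattern-scaled by the era-mean global rate (degrees C local
#' per degree C of global warming) before the signal-to-noise ratio is
#' formed, so eras with different forcing are comparable:
#' `snr = |trend / (global_trend_mean / 100)| / variability`. The raw
#' (unscaled) ratio `|trend| / variability` is also reported. Cells with zero
#' variability get a missing SNR (with a warning) rather than an infinite one.
#'
#' @param series an [sst_series()].
#' @param windows classified `century_windows` (see [classify_extreme()]).
#' @param era_range numeric `c(min, max)` of window start years assigned to
#'   this era (default: all windows in the series).
#' @return object of class `cell_climate_stats`: matrices `trend`
#'   (degrees C/yr), `variability` (degrees C), `scaled_trend`, `snr`,
#'   `snr_raw`, plus `global_trend_mean` (degrees C/century), the windows
#'   used, the era tag and grid.
#' @export
cell_stats_for_era <- function(series, windows, era_range = c(-Inf, Inf)) {
  stopifnot(inherits(series, "sst_series"))
  use <- windows[!is.na(windows$is_extreme) & windows$is_extreme &
                   windows$start_year >= era_range[1] &
                   windows$start_year <= era_range[2] &
                   windows$start_year >= min(series$years) &
                   windows$end_year <= max(series$years), , drop = FALSE]
  if (nrow(use) == 0) stop("no extreme windows in era")
  grid <- series$grid
  nt <- length(series$years)
  flat <- matrix(series$sst, nrow = nt)
  ocean <- !as.vector(grid$land_mask)
  slopes <- matrix(NA_real_, nrow(use), ncol(flat))
  sds <- matrix(NA_real_, nrow(use), ncol(flat))
  for (i in seq_len(nrow(use))) {
    idx <- which(series$years >= use$start_year[i] &
                   series$years <= use$end_year[i])
    ols <- window_ols(series$years[idx], flat[idx, ocean, drop = FALSE])
    slopes[i, ocean] <- ols$slope
    sds[i, ocean] <- ols$resid_sd
  }
  shape <- function(v) matrix(v, n_lat(grid), n_lon(grid))
  trend <- shape(colMeans(slopes))
  variability <- shape(colMeans(sds))
  gtm <- mean(use$global_rate)
  if (gtm == 0) stop("global_trend_mean is zero; cannot pattern-scale")
  scaled <- trend / (gtm / 100)
  zero_var <- !is.na(variability) & variability < 1e-12  # noise-free degenerate
  if (any(zero_var))
    warning(sum(zero_var), " cell(s) with zero variability; SNR set missing")
  snr <- abs(scaled) / variability
  snr_raw <- abs(trend) / variability
  snr[zero_var] <- NA_real_
  snr_raw[zero_var] <- NA_real_
  structure(list(era = series$era, grid = grid,
                 trend = trend, variability = variability,
                 scaled_trend = scaled, snr = snr, snr_raw = snr_raw,
                 global_trend_mean = gtm, windows = use),
            class = "cell_climate_stats")
}

#' @export
print.cell_climate_stats <- function(x, ...) {
  cat(sprintf(paste0("<cell_climate_stats> era=%s, %d extreme window(s), ",
                     "era-mean global rate %.3f degC/century\n"),
              x$era, nrow(x$windows), x$global_trend_mean))
  v <- x$snr[!is.na(x$snr)]
  if (length(v)) cat(sprintf("  snr: median %.3g, range %.3g..%.3g\n",
                             stats::median(v), min(v), max(v)))
  invisible(x)
}

#' Change in SNR between eras (exposure field)
#'
#' `delta_snr = snr_future - snr_past` per cell; positive values mark
#' post-industrial warming rates that surpass the most extreme rates of the
#' past. Missing wherever either era's SNR is missing.
#'
#' @param past,future `cell_climate_stats` for the two eras.
#' @param scenario tag recorded on the result.
#' @return object of class `exposure_field` with matrix `delta_snr`.
#' @export
delta_snr <- function(past, future, scenario = future$era) {
  stopifnot(inherits(past, "cell_climate_stats"),
            inherits(future, "cell_climate_stats"))
  structure(list(grid = past$grid, scenario = scenario,
                 delta_snr = future$snr - past$snr),
            class = "exposure_field")
}
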