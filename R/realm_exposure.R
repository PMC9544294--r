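#' Collect per-realm past/future SNR samples
#'
#' Intersects the realm raster with the SNR fields and returns, per retained
#' realm, the vectors of defined past and future SNR values over its ocean
#' cells. Realms with fewer than `min_cells` ocean cells are excluded.
#'
#' @param snr_past,snr_future `cell_climate_stats` (or bare matrices).
#' @param realm_ids [gridded_field()] of integer realm ids (`NA` on land).
#' @param min_cells exclusion threshold (default 3: realms with fewer ocean
#'   cells are dropped).
#' @return named list per realm id: `past`, `future` (numeric vectors),
#'   `cells` (row-major cell ids), `n_cells`, `centroid_lat` (area-weighted),
#'   `area` (sum of cell-area weights), `latitude_band`
#'   (`"tropical_mid"` if `|centroid| <= 50`, else `"high"`).
#' @export
collect_realm_samples <- function(snr_past, snr_future, realm_ids,
                                  min_cells = 3L) {
  sp <- if (inherits(snr_past, "cell_climate_stats")) snr_past$snr else snr_past
  sf <- if (inherits(snr_future, "cell_climate_stats")) snr_future$snr else snr_future
  grid <- realm_ids$grid
  ids <- realm_ids$values
  out <- list()
  for (r in sort(unique(ids[!is.na(ids)]))) {
    in_realm <- !is.na(ids) & ids == r & !grid$land_mask
    n <- sum(in_realm)
    if (n < min_cells) next
    w <- grid$cell_area[in_realm]
    latm <- matrix(grid$lat_centers, nrow(ids), ncol(ids))
    centroid <- sum(w * latm[in_realm]) / sum(w)
    rows <- which(in_realm, arr.ind = TRUE)
    out[[as.character(r)]] <- list(
      realm_id = r,
      past = sp[in_realm][!is.na(sp[in_realm])],
      future = sf[in_realm][!is.na(sf[in_realm])],
      cells = cell_id(grid, rows[, 1], rows[, 2]),
      n_cells = n,
      centroid_lat = centroid,
      area = sum(w),
      latitude_band = if (abs(centroid) <= 50) "tropical_mid" else "high")
  }
  out
}

#' Two-sample Kolmogorov--Smirnov comparison
#'
#' Two-sided two-sample KS statistic `D = sup |F_past - F_future|` with the
#' asymptotic p-value.
#'
#' @param past_sample,future_sample numeric vectors (length >= 3).
#' @return list `D`, `p_raw`.
#' @export
ks_compare <- function(past_sample, future_sample) {
  if (length(past_sample) < 3 || length(future_sample) < 3)
    stop("both samples need at least 3 values")
  kt <- suppressWarnings(stats::ks.test(past_sample, future_sample,
                                        alternative = "two.sided",
                                        exact = FALSE))
  list(D = as.numeric(kt$statistic), p_raw = kt$p.value)
}

#' Benjamini--Yekutieli adjusted p-values
#'
#' Step-up FDR adjustment valid under arbitrary dependence:
#' `p_adj(i) = min over j >= rank(i) of min(1, p(j) * m * c(m) / j)` with
#' `c(m) = sum_{k=1..m} 1/k`.
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
adjust_benjamini_yekutieli <- function(p_values) {
  stats::p.adjust(p_values, method = "BY")
}

#' Proportional overlap of two kernel density estimates
#'
#' Gaussian KDEs with Silverman's bandwidth for each sample, evaluated
#' exactly on a shared `n_grid`-point grid spanning `[min - 3h, max + 3h]` of
#' the pooled data (`h` the larger bandwidth); overlap is the trapezoid-rule
#' integral of the pointwise minimum, in `[0, 1]`. Low overlap means high
#' exposure. A zero-variance sample falls back to a tiny bandwidth
#' (`1e-6 |mean| + 1e-9`) with a warning.
#'
#' @param past_sample,future_sample numeric vectors (length >= 3).
#' @param n_grid number of grid points (default 512).
#' @return overlap proportion in `[0, 1]`.
#' @export
density_overlap <- function(past_sample, future_sample, n_grid = 512L) {
  x <- as.numeric(past_sample); y <- as.numeric(future_sample)
  if (length(x) < 3 || length(y) < 3)
    stop("both samples need at least 3 values")
  bw_of <- function(v) {
    if (stats::sd(v) == 0 || length(unique(v)) < 2) {
      warning("zero-variance sample; falling back to a tiny bandwidth")
      1e-6 * abs(mean(v)) + 1e-9
    } else stats::bw.nrd0(v)
  }
  hx <- bw_of(x); hy <- bw_of(y)
  h <- max(hx, hy)
  pooled <- c(x, y)
  grid <- seq(min(pooled) - 3 * h, max(pooled) + 3 * h, length.out = n_grid)
  kde <- function(v, bw) {
    # exact Gaussian KDE, evaluated column-block-wise to bound memory
    sapply(grid, function(g) mean(stats::dnorm(g, mean = v, sd = bw)))
  }
  fx <- kde(x, hx); fy <- kde(y, hy)
  fmin <- pmin(fx, fy)
  dx <- diff(grid)
  ov <- sum((fmin[-1] + fmin[-length(fmin)]) / 2 * dx)
  min(1, max(0, ov))
}

#' Hotspot exceedance of realm-level past-SNR thresholds
#'
#' For each realm the threshold is the stated percentile of past SNR over
#' all the realm's cells; a hotspot cell counts as exceeding when its future
#' SNR is strictly greater than the threshold. Reports per-realm and global
#' percentages, an area-weighted realm mean (realm areas as weights), and the
#' SD of the global percentage as the percentile sweeps
#' `sensitivity_range` (step 1).
#'
#' @param snr_past,snr_future `cell_climate_stats` (or matrices).
#' @param realm_ids [gridded_field()] of realm ids.
#' @param hotspots logical hotspot matrix on the same grid
#'   (see [hotspot_mask()]).
#' @param percentile realm threshold percentile of past SNR (default 95).
#' @param min_cells realm exclusion threshold (see
#'   [collect_realm_samples()]).
#' @param sensitivity_range percentile sweep for the sensitivity SD.
#' @return list with `realms` (data frame: realm_id, latitude_band, n_cells,
#'   n_hotspot, n_exceed, snr_threshold, pct_hotspot_exceeding, area_weight)
#'   and `global` (list: pct_global_hotspot_exceeding, unweighted_mean_pct,
#'   area_weighted_mean_pct, sensitivity_sd, n_hotspot_total).
#' @export
hotspot_exceedance <- function(snr_past, snr_future, realm_ids, hotspots,
                               percentile = 95, min_cells = 3L,
                               sensitivity_range = 90:100) {
  sp <- if (inherits(snr_past, "cell_climate_stats")) snr_past$snr else snr_past
  sf <- if (inherits(snr_future, "cell_climate_stats")) snr_future$snr else snr_future
  samples <- collect_realm_samples(sp, sf, realm_ids, min_cells = min_cells)
  grid <- realm_ids$grid
  ids <- realm_ids$values

  one_pass <- function(pct) {
    rows <- lapply(samples, function(s) {
      in_realm <- !is.na(ids) & ids == s$realm_id
      hot <- in_realm & hotspots
      past_vals <- sp[in_realm]
      past_vals <- past_vals[!is.na(past_vals)]
      n_hot <- sum(hot, na.rm = TRUE)
      if (n_hot > 0 && length(past_vals) == 0) {
        # hotspots present but no defined past SNR anywhere in the realm
        return(data.frame(realm_id = s$realm_id,
                          latitude_band = s$latitude_band,
                          n_cells = s$n_cells, n_hotspot = n_hot,
                          n_exceed = NA_integer_, snr_threshold = NA_real_,
                          pct_hotspot_exceeding = NA_real_,
                          area_weight = s$area))
      }
      thr <- if (length(past_vals)) {
        as.numeric(stats::quantile(past_vals, pct / 100, type = 7,
                                   names = FALSE))
      } else NA_real_
      fut_hot <- sf[hot]
      n_exc <- sum(fut_hot > thr, na.rm = TRUE)
      data.frame(realm_id = s$realm_id, latitude_band = s$latitude_band,
                 n_cells = s$n_cells, n_hotspot = n_hot,
                 n_exceed = if (n_hot) n_exc else NA_integer_,
                 snr_threshold = thr,
                 pct_hotspot_exceeding = if (n_hot) 100 * n_exc / n_hot
                                         else NA_real_,
                 area_weight = s$area)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  realms <- one_pass(percentile)
  global_pct <- function(tab) {
    tot <- sum(tab$n_hotspot, na.rm = TRUE)
    if (tot == 0) return(NA_real_)
    100 * sum(tab$n_exceed, na.rm = TRUE) / tot
  }
  with_hot <- !is.na(realms$pct_hotspot_exceeding)
  unweighted <- if (any(with_hot)) mean(realms$pct_hotspot_exceeding[with_hot])
                else NA_real_
  weighted <- if (any(with_hot)) {
    stats::weighted.mean(realms$pct_hotspot_exceeding[with_hot],
                         realms$area_weight[with_hot])
  } else NA_real_
  sweep_pct <- vapply(sensitivity_range,
                      function(p) global_pct(one_pass(p)), numeric(1))
  list(realms = realms,
       global = list(pct_global_hotspot_exceeding = global_pct(realms),
                     unweighted_mean_pct = unweighted,
                     area_weighted_mean_pct = weighted,
                     sensitivity_sd = stats::sd(sweep_pct),
                     sensitivity_pct = stats::setNames(sweep_pct,
                                                       sensitivity_range),
                     n_hotspot_total = sum(realms$n_hotspot, na.rm = TRUE)))
}

#' Realm-level exposure summary
#'
#' Runs the KS comparison, Benjamini--Yekutieli correction and kernel-density
#' overlap for every retained realm and merges the hotspot exceedance
#' accounting into one table.
#'
#' @inheritParams hotspot_exceedance
#' @return list with `summary` (data frame: one row per realm with ks_D,
#'   p_raw, p_adjusted, overlap, latitude_band, exceedance columns) and
#'   `global` (as in [hotspot_exceedance()]).
#' @export
realm_exposure_summary <- function(snr_past, snr_future, realm_ids, hotspots,
                                   percentile = 95, min_cells = 3L,
                                   sensitivity_range = 90:100) {
  samples <- collect_realm_samples(snr_past, snr_future, realm_ids,
                                   min_cells = min_cells)
  stats_tab <- do.call(rbind, lapply(samples, function(s) {
    ks <- if (length(s$past) >= 3 && length(s$future) >= 3)
      ks_compare(s$past, s$future) else list(D = NA_real_, p_raw = NA_real_)
    ov <- if (length(s$past) >= 3 && length(s$future) >= 3)
      density_overlap(s$past, s$future) else NA_real_
    data.frame(realm_id = s$realm_id, latitude_band = s$latitude_band,
               centroid_lat = s$centroid_lat, ks_D = ks$D, p_raw = ks$p_raw,
               overlap = ov)
  }))
  rownames(stats_tab) <- NULL
  stats_tab$p_adjusted <- adjust_benjamini_yekutieli(stats_tab$p_raw)
  exc <- hotspot_exceedance(snr_past, snr_future, realm_ids, hotspots,
                            percentile = percentile, min_cells = min_cells,
                            sensitivity_range = sensitivity_range)
  merged <- merge(stats_tab, exc$realms[, setdiff(names(exc$realms),
                                                  "latitude_band")],
                  by = "realm_id", sort = TRUE)
  list(summary = merged, global = exc$global)
}
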