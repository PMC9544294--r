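#' Configuration for the synthetic world generator
#'
#' The generator emulates the statistical structure the exposure analysis
#' assumes: a latitudinally graded SST climatology, a deglacial global warming
#' trajectory with injected abrupt centennial-scale episodes, per-cell AR(1)
#' noise, scenario futures with stronger forced trends and a tropically
#' amplified spatial pattern, tropical-peaked species richness, contiguous
#' latitude-band realms within two ocean basins, and meridional land barriers
#' separating the basins.
#'
#' The forced signal is `sst(cell, t) = climatology(lat) +
#' amplification(cell) * G(t) + eps(cell, t)` with `G` the global forcing
#' trajectory (piecewise-linear ramps through the injected events for the
#' past, a linear trend for futures, zero for the control) and `eps` AR(1)
#' noise with stationary standard deviation `noise_sd`.
#'
#' @param resolution_deg climate grid resolution (degrees).
#' @param species_factor fine (species) grid is `resolution_deg /
#'   species_factor`.
#' @param n_years_past length of the past era, ending at `past_end_year`.
#' @param past_end_year last calendar year of the past era.
#' @param control_years,future_years lengths of the control and future eras;
#'   futures run `1851 .. 1850 + future_years`.
#' @param t_equator,t_pole climatology endpoints (degrees C);
#'   `T(lat) = t_pole + (t_equator - t_pole) * cos^2(lat)`.
#' @param events data frame with columns `start_year`, `duration_yr`,
#'   `delta_t` (global degrees C added linearly over the event).
#' @param future_trend named vector, global trend in degrees C per year for
#'   `future_scenario_A` and `future_scenario_B`.
#' @param amp_coef named vector `c(past = , future = )` of cosine-pattern
#'   coefficients: amplification is `1 + coef * (cos^2(lat) - 2/3)`
#'   (area-mean 1; tropics amplified for positive coef, poles for negative),
#'   floored at 0.05. With the default `past_amp_mode = "variability"` the
#'   past coefficient is ignored: deglacial events are expressed
#'   proportionally to local variability (polar-amplified, like abrupt
#'   glacial events), which makes past SNR roughly uniform; the future
#'   pattern is mildly polar-amplified. Low, flat tropical variability then
#'   makes near-uniform future forcing unprecedented in the tropics but
#'   familiar at high latitudes -- the spatial structure the exposure
#'   analysis is designed to detect.
#' @param past_amp_mode `"variability"` (past amplification proportional to
#'   the noise-SD profile times an extra polar factor of `past_polar_snr`,
#'   normalised to area-mean 1; the future tracks the noise-SD profile
#'   alone) or `"cosine"` (use `amp_coef`).
#' @param past_polar_snr in `"variability"` mode, the ratio of polar to
#'   tropical past signal-to-noise (same flat-then-steep latitude shape as
#'   the noise profile): deglacial abrupt events were polar-amplified beyond
#'   what local variability explains, so high latitudes carry a broad, high
#'   past-SNR distribution that future rates fall inside, while tropical
#'   future rates are unprecedented.
#' @param ar1_phi AR(1) coefficient of the cell noise.
#' @param noise_sd equatorial stationary standard deviation of the cell
#'   noise (degrees C); the innovation SD is scaled by
#'   `sqrt(1 - ar1_phi^2)`.
#' @param noise_polar_amp ratio of polar to equatorial stationary noise SD.
#' @param noise_lat_exponent shape of the SD profile,
#'   `noise_sd * (1 + (noise_polar_amp - 1) * sin(lat)^(2 * exponent))`;
#'   the default 3 keeps variability low and flat through the tropics and
#'   mid-latitudes and rising steeply poleward, as for real interannual SST
#'   variability. `noise_polar_amp = 1` gives a spatially constant SD.
#' @param n_species number of synthetic species.
#' @param richness_peak_lat,richness_lat_sd latitude distribution of species
#'   range centres (degrees).
#' @param species_sd_lat,species_sd_lon Gaussian range half-widths (degrees).
#' @param prob_peak range of per-species peak occurrence probability.
#' @param frac_data_scarce fraction of species flagged data-scarce (excluded
#'   from richness, mimicking a minimum-records filter).
#' @param n_realms number of biogeographic realms (even; half per basin).
#' @param barrier_lon_cols longitude column indices of the two meridional
#'   land strips.
#' @param barrier_gap_rows latitude row indices kept ocean in the second
#'   strip (empty = closed barriers, two disconnected basins).
#' @param eez_width_cells near-shore (EEZ) width in cells from land.
#' @param master_seed integer master seed; every sub-generator derives its
#'   own stream from it.
#' @return a `world_config` list, validated.
#' @export
world_config <- function(resolution_deg = 2.5,
                         species_factor = 5L,
                         n_years_past = 21000L,
                         past_end_year = 1950L,
                         control_years = 500L,
                         future_years = 250L,
                         t_equator = 28, t_pole = 0,
                         events = default_events(),
                         future_trend = c(future_scenario_A = 0.0072,
                                          future_scenario_B = 0.0148),
                         amp_coef = c(past = -0.9, future = -0.3),
                         past_amp_mode = c("variability", "cosine"),
                         past_polar_snr = 4,
                         ar1_phi = 0.4,
                         noise_sd = 0.2,
                         noise_polar_amp = 3,
                         noise_lat_exponent = 3,
                         n_species = 200L,
                         richness_peak_lat = 0, richness_lat_sd = 15,
                         species_sd_lat = 10, species_sd_lon = 25,
                         prob_peak = c(0.5, 0.95),
                         frac_data_scarce = 0,
                         n_realms = 8L,
                         barrier_lon_cols = NULL,
                         barrier_gap_rows = integer(0),
                         eez_width_cells = 1L,
                         master_seed = 1L) {
  cfg <- as.list(environment())
  cfg$past_amp_mode <- match.arg(past_amp_mode)
  nlon <- as.integer(round(360 / resolution_deg))
  if (is.null(cfg$barrier_lon_cols))
    cfg$barrier_lon_cols <- c(max(1L, nlon %/% 4L), max(2L, (3L * nlon) %/% 4L))
  stopifnot(n_years_past >= 1, control_years >= 1, future_years >= 1,
            noise_sd >= 0, noise_polar_amp > 0, ar1_phi > -1, ar1_phi < 1,
            n_species >= 0, n_realms %% 2 == 0, n_realms >= 2,
            frac_data_scarce >= 0, frac_data_scarce <= 1,
            eez_width_cells >= 0)
  if (nrow(cfg$events)) {
    stopifnot(all(c("start_year", "duration_yr", "delta_t") %in% names(cfg$events)),
              all(cfg$events$duration_yr >= 1))
  }
  class(cfg) <- "world_config"
  cfg
}

#' Default deglacial event trajectory
#'
#' Abrupt global warming episodes loosely patterned on the last deglaciation
#' (calendar years; present = 1950 C.E., so 14,700 B.P. is -12750): two large
#' abrupt warmings, a Holocene-thermal-maximum build-up, and a slow late
#' cooling whose centennial rate stays below typical extreme thresholds.
#'
#' @return data frame with `start_year`, `duration_yr`, `delta_t`.
#' @export
default_events <- function() {
  data.frame(start_year = c(-12750L, -9550L, -6050L, -2050L),
             duration_yr = c(200L, 150L, 300L, 500L),
             delta_t = c(1.0, 0.8, 0.5, -0.3))
}

#' Reduced-scale configuration for examples and tests
#'
#' A 10-degree world with a 2000-year past so the full pipeline runs in
#' seconds: three abrupt warming episodes of 0.5 degrees C per century in the
#' deglacial-analogue past, and tropically amplified scenario futures.
#'
#' @param ... overrides passed to [world_config()].
#' @return a `world_config`.
#' @export
demo_world_config <- function(...) {
  defaults <- list(
    resolution_deg = 10, species_factor = 5L,
    n_years_past = 2000L, past_end_year = 1950L,
    control_years = 400L, future_years = 250L,
    events = data.frame(start_year = c(51L, 551L, 1051L),
                        duration_yr = c(100L, 100L, 100L),
                        delta_t = c(0.5, 0.5, 0.5)),
    n_species = 150L, n_realms = 8L)
  args <- utils::modifyList(defaults, list(...))
  do.call(world_config, args)
}

# Named sub-streams derived from the master seed; keeps every generator
# reproducible and independent of call order.
world_seed <- function(config, stream) {
  offsets <- c(sst_past = 1L, sst_control = 2L, sst_future_scenario_A = 3L,
               sst_future_scenario_B = 4L, species = 5L, masks = 6L)
  off <- offsets[[stream]]
  as.integer((as.numeric(config$master_seed) * 7919 + off * 104729) %% 2147483629)
}

climatology_profile <- function(config, lat) {
  config$t_pole + (config$t_equator - config$t_pole) * cos(lat * pi / 180)^2
}

noise_sd_profile <- function(config, lat) {
  config$noise_sd *
    (1 + (config$noise_polar_amp - 1) *
       sin(lat * pi / 180)^(2 * config$noise_lat_exponent))
}

amplification_profile <- function(config, lat, era) {
  past_era <- era %in% c("past", "control")
  if (identical(config$past_amp_mode, "variability")) {
    prof <- 1 + (config$noise_polar_amp - 1) *
      sin(lat * pi / 180)^(2 * config$noise_lat_exponent)
    if (past_era)
      prof <- prof * (1 + (config$past_polar_snr - 1) *
                        sin(lat * pi / 180)^(2 * config$noise_lat_exponent))
    w <- cos(lat * pi / 180)
    return(pmax(0.05, prof / (sum(prof * w) / sum(w))))
  }
  coef <- if (past_era) config$amp_coef[["past"]] else config$amp_coef[["future"]]
  pmax(0.05, 1 + coef * (cos(lat * pi / 180)^2 - 2 / 3))
}

era_years <- function(config, era) {
  switch(era,
         past = seq(config$past_end_year - config$n_years_past + 1L,
                    config$past_end_year),
         control = seq_len(config$control_years),
         future_scenario_A = ,
         future_scenario_B = seq(1851L, 1850L + config$future_years),
         stop("unknown era: ", era))
}

# Global forcing trajectory G(t) on the era's year axis. Past: cumulative
# piecewise-linear ramps through the injected events. Futures: linear trend
# continuing from the past-era end level. Control: zero.
forcing_trajectory <- function(config, era, years) {
  past_level <- function(t) {
    # level at end of year t (events add delta_t linearly over duration)
    g <- numeric(length(t))
    ev <- config$events
    for (i in seq_len(nrow(ev))) {
      s <- ev$start_year[i]; d <- ev$duration_yr[i]; dt <- ev$delta_t[i]
      frac <- pmin(pmax((t - s + 1) / d, 0), 1)
      g <- g + dt * frac
    }
    g
  }
  if (era == "control") return(numeric(length(years)))
  if (era == "past") {
    ev <- config$events
    if (nrow(ev)) {
      if (any(ev$start_year < min(years)) ||
          any(ev$start_year + ev$duration_yr - 1 > max(years)))
        stop("events outside the era's year range")
    }
    return(past_level(years))
  }
  trend <- config$future_trend[[era]]
  past_end <- past_level(config$past_end_year)
  past_end + trend * (years - 1850L)
}

#' Generate a synthetic SST era with ground truth
#'
#' @param config a [world_config()].
#' @param era `"past"`, `"control"`, `"future_scenario_A"` or
#'   `"future_scenario_B"`.
#' @return list with `series` (an [sst_series()]) and `truth`: the analytic
#'   per-cell forced trend inside each event window (`event_trends`, degrees C
#'   per year), the stationary residual SD (`resid_sd`), the forced linear
#'   trend for future eras (`forced_trend`), and the event windows.
#' @export
generate_sst <- function(config, era) {
  stopifnot(inherits(config, "world_config"))
  masks <- generate_masks(config)
  grid <- masks$grid
  years <- era_years(config, era)
  g_t <- forcing_trajectory(config, era, years)
  lat <- grid$lat_centers
  clim_row <- climatology_profile(config, lat)
  amp_row <- amplification_profile(config, lat, era)
  nt <- length(years); nlat <- n_lat(grid); nlon <- n_lon(grid)

  clim <- matrix(clim_row, nlat, nlon)
  amp <- matrix(amp_row, nlat, nlon)

  set.seed(world_seed(config, paste0("sst_", era)))
  sd_row <- noise_sd_profile(config, lat)
  sd_mat <- matrix(sd_row, nlat, nlon)
  phi <- config$ar1_phi
  ncell <- nlat * nlon
  sst <- array(NA_real_, c(nt, nlat, nlon))
  flat <- matrix(0, nt, ncell)
  if (config$noise_sd > 0) {
    sd_cell <- as.vector(sd_mat)
    innov_sd <- sd_cell * sqrt(1 - phi^2)
    eps <- stats::rnorm(ncell, 0, sd_cell)
    flat[1, ] <- eps
    for (t in seq_len(nt)[-1]) {
      eps <- phi * eps + stats::rnorm(ncell, 0, innov_sd)
      flat[t, ] <- eps
    }
  }
  base <- as.vector(clim)          # column-major (lat fastest) cell order
  ampv <- as.vector(amp)
  flat <- flat + rep(base, each = nt) + outer(g_t, ampv)
  land <- as.vector(grid$land_mask)
  flat[, land] <- NA_real_
  sst[] <- flat

  ev <- config$events
  event_trends <- list()
  event_windows <- NULL
  if (era == "past" && nrow(ev)) {
    event_windows <- data.frame(start_year = ev$start_year,
                                end_year = ev$start_year + ev$duration_yr - 1L,
                                delta_t = ev$delta_t)
    event_trends <- lapply(seq_len(nrow(ev)), function(i) {
      tr <- amp * (ev$delta_t[i] / ev$duration_yr[i])
      tr[grid$land_mask] <- NA_real_
      tr
    })
  }
  forced_trend <- NULL
  if (era %in% c("future_scenario_A", "future_scenario_B")) {
    forced_trend <- amp * config$future_trend[[era]]
    forced_trend[grid$land_mask] <- NA_real_
  }
  resid_sd <- sd_mat
  if (config$noise_sd == 0) resid_sd[] <- 0
  resid_sd[grid$land_mask] <- NA_real_

  list(series = sst_series(grid, years, sst, era),
       truth = list(event_windows = event_windows,
                    event_trends = event_trends,
                    forced_trend = forced_trend,
                    resid_sd = resid_sd,
                    amplification = amp,
                    forcing = data.frame(year = years, g = g_t)))
}

#' Generate land, realm and EEZ masks
#'
#' Land is two one-cell-wide meridional strips (the second optionally gapped)
#' separating two ocean basins; realms are contiguous latitude bands within
#' each basin; the EEZ mask marks ocean cells within `eez_width_cells`
#' (8-neighbour) steps of land.
#'
#' @param config a [world_config()].
#' @return list with `grid` (climate [grid_spec()] carrying the land mask),
#'   `realm_id` ([gridded_field()], integer ids, `NA` on land), `eez_mask`
#'   and `land_mask` (logical matrices), and `basin` (integer matrix).
#' @export
generate_masks <- function(config) {
  stopifnot(inherits(config, "world_config"))
  res <- config$resolution_deg
  nlat <- as.integer(round(180 / res)); nlon <- as.integer(round(360 / res))
  land <- matrix(FALSE, nlat, nlon)
  cols <- sort(unique(pmin(pmax(config$barrier_lon_cols, 1L), nlon)))
  land[, cols[1]] <- TRUE
  if (length(cols) > 1) {
    land[, cols[2]] <- TRUE
    gap <- intersect(config$barrier_gap_rows, seq_len(nlat))
    if (length(gap)) land[gap, cols[2]] <- FALSE
  }
  grid <- grid_spec(res, land_mask = land)

  basin <- matrix(2L, nlat, nlon)
  if (length(cols) > 1 && cols[2] > cols[1] + 1L)
    basin[, (cols[1] + 1L):(cols[2] - 1L)] <- 1L

  nb <- config$n_realms %/% 2L
  band_edges <- seq(-90, 90, length.out = nb + 1)
  band <- findInterval(grid$lat_centers, band_edges, rightmost.closed = TRUE)
  realm <- (basin - 1L) * nb + matrix(band, nlat, nlon)
  realm[land] <- NA_integer_
  storage.mode(realm) <- "integer"

  eez <- matrix(FALSE, nlat, nlon)
  if (any(land) && config$eez_width_cells > 0) {
    dist <- chebyshev_distance_to(land, wrap_lon = TRUE)
    eez <- !land & dist <= config$eez_width_cells
  }
  list(grid = grid,
       realm_id = gridded_field(grid, realm, units = "realm id"),
       eez_mask = eez, land_mask = land, basin = basin)
}

# Chebyshev (8-neighbour step) distance from each cell to the nearest TRUE
# cell, with longitude wrap; rows (latitude) do not wrap. Iterative dilation;
# fine for the small number of steps needed here.
chebyshev_distance_to <- function(mask, wrap_lon = TRUE) {
  nlat <- nrow(mask); nlon <- ncol(mask)
  dist <- matrix(Inf, nlat, nlon)
  dist[mask] <- 0
  frontier <- mask
  d <- 0
  while (any(is.infinite(dist)) && d < nlat + nlon) {
    d <- d + 1
    grown <- dilate8(frontier, wrap_lon)
    newly <- grown & is.infinite(dist)
    if (!any(newly)) break
    dist[newly] <- d
    frontier <- grown
  }
  dist
}

dilate8 <- function(m, wrap_lon = TRUE) {
  nlat <- nrow(m); nlon <- ncol(m)
  shift_lon <- function(x, k) {
    if (k == 0) return(x)
    if (wrap_lon) x[, ((seq_len(nlon) - 1 - k) %% nlon) + 1, drop = FALSE]
    else {
      out <- matrix(FALSE, nlat, nlon)
      src <- seq_len(nlon) - k
      ok <- src >= 1 & src <= nlon
      out[, ok] <- x[, src[ok], drop = FALSE]
      out
    }
  }
  shift_lat <- function(x, k) {
    out <- matrix(FALSE, nlat, nlon)
    src <- seq_len(nlat) - k
    ok <- src >= 1 & src <= nlat
    out[ok, ] <- x[src[ok], , drop = FALSE]
    out
  }
  acc <- m
  for (dl in -1:1) for (dc in -1:1) {
    if (dl == 0 && dc == 0) next
    acc <- acc | shift_lat(shift_lon(m, dc), dl)
  }
  acc
}

#' Generate per-species occurrence-probability rasters
#'
#' Each species gets a unimodal Gaussian probability surface on the fine
#' (species) grid, centred at a latitude drawn from a tropical-peaked normal
#' distribution and a longitude drawn uniformly over ocean, with peak
#' probability drawn from `prob_peak`. Probabilities are `NA` on land.
#'
#' @param config a [world_config()].
#' @return list with `grid` (fine [grid_spec()]), `probs` (array
#'   `nlat x nlon x n_species` of probabilities in `[0, 1]`), `data_scarce`
#'   (logical per species), and `truth` (data frame of the drawn centres and
#'   peaks).
#' @export
generate_species <- function(config) {
  stopifnot(inherits(config, "world_config"))
  if (config$n_species < 1) stop("n_species must be >= 1")
  masks <- generate_masks(config)
  fine <- grid_spec(config$resolution_deg / config$species_factor,
                    land_mask = refine_mask(masks$grid,
                                            grid_spec(config$resolution_deg /
                                                        config$species_factor)))
  set.seed(world_seed(config, "species"))
  ns <- config$n_species
  lat0 <- pmin(70, pmax(-70, stats::rnorm(ns, config$richness_peak_lat,
                                          config$richness_lat_sd)))
  ocean_lons <- fine$lon_centers[colSums(!fine$land_mask) > 0]
  lon0 <- sample(ocean_lons, ns, replace = TRUE)
  peak <- stats::runif(ns, config$prob_peak[1], config$prob_peak[2])
  scarce <- stats::runif(ns) < config$frac_data_scarce

  nlat <- n_lat(fine); nlon <- n_lon(fine)
  probs <- array(NA_real_, c(nlat, nlon, ns))
  latm <- matrix(fine$lat_centers, nlat, nlon)
  lonm <- matrix(fine$lon_centers, nlat, nlon, byrow = TRUE)
  for (s in seq_len(ns)) {
    dlon <- ((lonm - lon0[s] + 180) %% 360) - 180
    p <- peak[s] * exp(-0.5 * ((latm - lat0[s]) / config$species_sd_lat)^2 -
                         0.5 * (dlon / config$species_sd_lon)^2)
    p[fine$land_mask] <- NA_real_
    probs[, , s] <- p
  }
  list(grid = fine, probs = probs, data_scarce = scarce,
       truth = data.frame(lat0 = lat0, lon0 = lon0, peak = peak,
                          data_scarce = scarce))
}

#' Generate a complete synthetic world
#'
#' Runs [generate_masks()], [generate_species()] and [generate_sst()] for the
#' past, control and both future scenarios.
#'
#' @param config a [world_config()].
#' @param eras which SST eras to generate.
#' @return list with `config`, `masks`, `species`, and `sst` (named list of
#'   `generate_sst()` results per era).
#' @export
generate_world <- function(config,
                           eras = c("past", "control",
                                    "future_scenario_A", "future_scenario_B")) {
  list(config = config,
       masks = generate_masks(config),
       species = generate_species(config),
       sst = stats::setNames(lapply(eras, function(e) generate_sst(config, e)),
                             eras))
}
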