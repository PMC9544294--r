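#' Pipeline configuration
#'
#' Houses every analysis constant in one validated place: the extreme-warming
#' threshold (0.18 degrees C/century, or `"calibrate"` to take the control
#' run's percentile), the occurrence threshold (0.4), the hotspot and
#' exceedance percentiles (95), the realm exclusion size (3 cells), the
#' exceedance sensitivity sweep (90--100), the bias-correction overlap
#' window, the HTM and end-of-century windows, and the analogue settings.
#' Unknown keys are rejected.
#'
#' @param world a [world_config()] describing the synthetic inputs.
#' @param window_yr,step_yr centennial window length and stride (years).
#' @param warming_threshold degrees C/century, or `"calibrate"`.
#' @param calibrate_percentile percentile of control rates when calibrating.
#' @param occurrence_tau occurrence-probability threshold in `[0, 1]`.
#' @param hotspot_percentile richness hotspot percentile.
#' @param realm_min_cells realm exclusion threshold (cells).
#' @param exceedance_percentile realm past-SNR threshold percentile.
#' @param sensitivity_range percentile sweep for the exceedance sensitivity.
#' @param past_era_end last window start year assigned to the past era.
#' @param overlap_years bias-correction overlap window (calendar years).
#' @param htm_window HTM window (calendar years; 9000--5000 B.P. by default).
#' @param future_window end-of-century window (calendar years).
#' @param tol_degC analogue temperature tolerance (degrees C).
#' @param connectivity sea-graph connectivity (4 or 8).
#' @param horizon_years redistribution horizon (default 70: 2020--2090).
#' @param scenarios future scenario eras to analyse.
#' @param master_seed overrides the world's master seed when not `NULL`.
#' @param output_dir default output directory for [run_pipeline()].
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(world = demo_world_config(),
                            window_yr = 100L, step_yr = 10L,
                            warming_threshold = 0.18,
                            calibrate_percentile = 95,
                            occurrence_tau = 0.4,
                            hotspot_percentile = 95,
                            realm_min_cells = 3L,
                            exceedance_percentile = 95,
                            sensitivity_range = 90:100,
                            past_era_end = 1850L,
                            overlap_years = c(1851L, 1950L),
                            htm_window = c(-7050L, -3050L),
                            future_window = c(2080L, 2100L),
                            tol_degC = 0,
                            connectivity = 8L,
                            horizon_years = 70,
                            scenarios = c("future_scenario_A",
                                          "future_scenario_B"),
                            master_seed = NULL,
                            output_dir = tempfile("oceanexposure_run_")) {
  cfg <- as.list(environment())
  stopifnot(inherits(world, "world_config"),
            window_yr >= 2, step_yr >= 1,
            connectivity %in% c(4L, 8L), horizon_years > 0,
            tol_degC >= 0)
  chk_pct <- function(p, what) {
    if (any(p < 0) || any(p > 100)) stop(what, " must lie in [0, 100]")
  }
  if (occurrence_tau < 0 || occurrence_tau > 1)
    stop("occurrence_tau must lie in [0, 1]")
  chk_pct(calibrate_percentile, "calibrate_percentile")
  chk_pct(hotspot_percentile, "hotspot_percentile")
  chk_pct(exceedance_percentile, "exceedance_percentile")
  chk_pct(sensitivity_range, "sensitivity_range")
  if (!identical(warming_threshold, "calibrate") &&
      !(is.numeric(warming_threshold) && warming_threshold >= 0))
    stop("warming_threshold must be a non-negative rate or \"calibrate\"")
  if (!is.null(master_seed)) cfg$world$master_seed <- as.integer(master_seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; the nested `world`
#' block maps to [world_config()] (and its `events` block to the events data
#' frame). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$world)) {
    w <- raw$world
    if (!is.null(w$events)) w$events <- as.data.frame(w$events)
    raw$world <- do.call(world_config, w)
  }
  do.call(pipeline_config, raw)
}

#' Run the full exposure pipeline
#'
#' Simulate world -> detect extreme windows -> per-cell SNR -> richness and
#' hotspots -> realm exposure -> thermal analogues -> report. Every output
#' table is written under `output_dir` and listed, with an MD5 content hash,
#' in `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param output_dir overrides `config$output_dir`.
#' @return (invisibly) a list with `report`, `manifest`, `paths`, and the
#'   intermediate objects (`windows`, `stats`, `hotspots`, `realms`,
#'   `analogues`).
#' @export
run_pipeline <- function(config, output_dir = config$output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  world <- stage("simulate", generate_world(config$world,
                                            eras = c("past", "control",
                                                     config$scenarios)))
  grid <- world$masks$grid

  # --- extreme windows -----------------------------------------------------
  win <- config$window_yr; step <- config$step_yr
  windows <- stage("detect-extremes", {
    w <- lapply(world$sst, function(e) centennial_rates(e$series, win, step))
    thr <- if (identical(config$warming_threshold, "calibrate"))
      calibrate_threshold(w$control, config$calibrate_percentile)
    else config$warming_threshold
    list(threshold = thr,
         per_era = lapply(w, classify_extreme, threshold = thr))
  })

  # --- per-cell stats and delta SNR ---------------------------------------
  stats_list <- stage("snr", {
    past <- cell_stats_for_era(world$sst$past$series, windows$per_era$past,
                               era_range = c(-Inf, config$past_era_end))
    fut <- lapply(config$scenarios, function(sc)
      cell_stats_for_era(world$sst[[sc]]$series, windows$per_era[[sc]],
                         era_range = c(config$past_era_end + 1L, Inf)))
    names(fut) <- config$scenarios
    list(past = past, future = fut,
         delta = lapply(fut, function(f) delta_snr(past, f)))
  })

  # --- richness and hotspots ----------------------------------------------
  hotspots <- stage("richness", {
    rich_fine <- richness_from_probs(world$species, config$occurrence_tau)
    rich_coarse <- aggregate_mean(rich_fine, grid)
    mask <- hotspot_mask(rich_coarse, config$hotspot_percentile)
    sens <- threshold_sensitivity(world$species,
                                  reference_tau = config$occurrence_tau)
    list(fine = rich_fine, coarse = rich_coarse, mask = mask,
         sensitivity = sens)
  })

  # --- realm exposure ------------------------------------------------------
  realms <- stage("realms", {
    lapply(stats_list$future, function(f)
      realm_exposure_summary(stats_list$past, f, world$masks$realm_id,
                             hotspots$mask,
                             percentile = config$exceedance_percentile,
                             min_cells = config$realm_min_cells,
                             sensitivity_range = config$sensitivity_range))
  })

  # --- thermal analogues ---------------------------------------------------
  analogues <- stage("analogues", {
    graph <- build_sea_graph(grid, connectivity = config$connectivity)
    rc <- which(hotspots$mask, arr.ind = TRUE)
    focal <- sort(cell_id(grid, rc[, 1], rc[, 2]))
    out <- list()
    for (sc in config$scenarios) {
      ref <- world$sst[[sc]]$series
      past_corr <- delta_bias_correct(world$sst$past$series, ref,
                                      overlap = config$overlap_years)
      htm <- htm_upper_temperature(past_corr, config$htm_window)
      fut_up <- future_upper_temperature(ref, config$future_window)
      for (variant in c("all_ocean", "eez")) {
        cand <- if (variant == "eez") world$masks$eez_mask else NULL
        res <- nearest_analogue(focal, htm, fut_up, graph,
                                candidate_mask = cand,
                                tol_degC = config$tol_degC)
        res <- redistribution_rate(res, config$horizon_years)
        cross <- realm_crossing_summary(res, world$masks$realm_id)
        out[[paste(sc, variant, sep = ".")]] <-
          list(scenario = sc, variant = variant, results = cross$results,
               pct_crossing = cross$pct_crossing,
               pct_no_analogue = cross$pct_no_analogue)
      }
    }
    out$hovmoller <- {
      sc1 <- config$scenarios[1]
      past_corr <- delta_bias_correct(world$sst$past$series,
                                      world$sst[[sc1]]$series,
                                      overlap = config$overlap_years)
      list(past = hovmoller(past_corr, hotspots$mask),
           future = lapply(stats::setNames(config$scenarios,
                                           config$scenarios),
                           function(sc) hovmoller(world$sst[[sc]]$series,
                                                  hotspots$mask)))
    }
    out
  })

  rep <- stage("report",
               build_report(config, grid, windows, hotspots, realms,
                            analogues))
  paths <- stage("write-outputs",
                 write_pipeline_outputs(output_dir, config, world, windows,
                                        stats_list, hotspots, realms,
                                        analogues, rep))
  manifest <- list(
    package = "oceanexposure",
    config = unclass_config(config),
    threshold_deg_c_per_century = windows$threshold,
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(report = rep, manifest = manifest,
                 manifest_path = manifest_path, paths = paths,
                 windows = windows, stats = stats_list, hotspots = hotspots,
                 realms = realms, analogues = analogues, world = world))
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$world <- unclass(cfg$world)
  cfg$world$events <- as.list(cfg$world$events)
  cfg
}

# Assemble the report: global exceedance (plain / unweighted / weighted),
# per-realm rows, analogue summaries per scenario and candidate mask, and
# hotspot area share by latitude band.
build_report <- function(config, grid, windows, hotspots, realms, analogues) {
  hot <- hotspots$mask
  latm <- matrix(grid$lat_centers, n_lat(grid), n_lon(grid))
  hot_area <- sum(grid$cell_area[hot])
  area_share <- if (hot_area > 0) {
    list(tropical_mid = 100 * sum(grid$cell_area[hot & abs(latm) <= 50]) /
           hot_area,
         high = 100 * sum(grid$cell_area[hot & abs(latm) > 50]) / hot_area)
  } else list(tropical_mid = NA_real_, high = NA_real_)

  exposure <- lapply(realms, function(r) {
    band_means <- tapply(r$summary$overlap, r$summary$latitude_band, mean,
                         na.rm = TRUE)
    c(r$global,
      list(mean_overlap_tropical_mid =
             unname(band_means["tropical_mid"]),
           mean_overlap_high = unname(band_means["high"])))
  })

  ana <- list()
  for (nm in setdiff(names(analogues), "hovmoller")) {
    a <- analogues[[nm]]
    d <- a$results$sea_distance_km[!a$results$no_analogue]
    ana[[nm]] <- list(scenario = a$scenario, candidate_mask = a$variant,
                      mean_distance_km = if (length(d)) mean(d) else NA_real_,
                      sd_distance_km = if (length(d) > 1) stats::sd(d)
                                       else NA_real_,
                      mean_rate_km_per_yr = if (length(d))
                        mean(d) / config$horizon_years else NA_real_,
                      pct_crossing_realm = a$pct_crossing,
                      pct_no_analogue = a$pct_no_analogue)
  }
  list(n_hotspot_cells = sum(hot),
       hotspot_area_share_pct = area_share,
       threshold_deg_c_per_century = windows$threshold,
       n_extreme_windows = lapply(windows$per_era, function(w)
         sum(w$is_extreme, na.rm = TRUE)),
       exposure = exposure,
       analogues = ana)
}

write_pipeline_outputs <- function(output_dir, config, world, windows,
                                   stats_list, hotspots, realms, analogues,
                                   rep) {
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }
  num <- function(x) round(x, 10)  # stabilise text output across runs

  for (era in names(windows$per_era)) {
    p <- put(file.path(output_dir, paste0("windows_", era, ".csv")))
    w <- windows$per_era[[era]]
    w$global_rate <- num(w$global_rate)
    utils::write.csv(w, p, row.names = FALSE)
  }
  fields <- c(list(trend = gridded_field(stats_list$past$grid,
                                         stats_list$past$trend, "degC/yr"),
                   variability = gridded_field(stats_list$past$grid,
                                               stats_list$past$variability,
                                               "degC"),
                   snr_past = gridded_field(stats_list$past$grid,
                                            stats_list$past$snr, "1")),
              stats::setNames(lapply(config$scenarios, function(sc)
                gridded_field(stats_list$past$grid,
                              stats_list$future[[sc]]$snr, "1")),
                paste0("snr_", config$scenarios)),
              stats::setNames(lapply(config$scenarios, function(sc)
                gridded_field(stats_list$past$grid,
                              stats_list$delta[[sc]]$delta_snr, "1")),
                paste0("delta_snr_", config$scenarios)))
  write_netcdf(fields, put(file.path(output_dir, "snr_fields.nc")))
  write_netcdf(list(richness = hotspots$coarse,
                    hotspot_mask = gridded_field(
                      hotspots$coarse$grid,
                      matrix(as.integer(hotspots$mask),
                             nrow(hotspots$mask), ncol(hotspots$mask)),
                      "1"),
                    realm_id = world$masks$realm_id),
               put(file.path(output_dir, "richness_hotspots.nc")))
  utils::write.csv(transform(hotspots$sensitivity, I = num(I)),
                   put(file.path(output_dir, "threshold_sensitivity.csv")),
                   row.names = FALSE)
  for (sc in names(realms)) {
    s <- realms[[sc]]$summary
    s[sapply(s, is.numeric)] <- lapply(s[sapply(s, is.numeric)], num)
    utils::write.csv(s, put(file.path(output_dir,
                                      paste0("realm_summary_", sc, ".csv"))),
                     row.names = FALSE)
  }
  for (nm in setdiff(names(analogues), "hovmoller")) {
    r <- analogues[[nm]]$results
    r[sapply(r, is.numeric)] <- lapply(r[sapply(r, is.numeric)], num)
    utils::write.csv(r, put(file.path(output_dir,
                                      paste0("analogues_", nm, ".csv"))),
                     row.names = FALSE)
  }
  hov <- analogues$hovmoller$past
  hov_df <- data.frame(band_mid = hov$band_mid, num(hov$values))
  names(hov_df) <- c("band_mid_deg", paste0("y", hov$years))
  utils::write.csv(hov_df, put(file.path(output_dir, "hovmoller_past.csv")),
                   row.names = FALSE)
  jsonlite::write_json(rapply(rep, num, classes = "numeric", how = "replace"),
                       put(file.path(output_dir, "report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths
}
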