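test_that("a noise-free ramp with uniform amplification yields exactly 0.005 degC/yr everywhere", {
  cfg <- noise_free_config(past_amp_mode = "cosine",
                           amp_coef = c(past = 0, future = 0))
  s <- generate_sst(cfg, "past")$series
  idx <- which(s$years >= 1701 & s$years <= 1800)
  flat <- matrix(s$sst, nrow = length(s$years))
  ocean <- which(!as.vector(s$grid$land_mask))
  slopes <- vapply(ocean, function(cell)
    bf_ols_slope(s$years[idx], flat[idx, cell]), numeric(1))
  expect_equal(slopes, rep(0.005, length(ocean)), tolerance = 1e-12)
})

test_that("ground-truth event trends match noise-free regeneration to machine precision", {
  out <- generate_sst(noise_free_config(), "past")
  s <- out$series
  tr <- out$truth$event_trends[[1]]
  idx <- which(s$years >= 1701 & s$years <= 1800)
  flat <- matrix(s$sst, nrow = length(s$years))
  ocean <- which(!as.vector(s$grid$land_mask))
  for (cell in ocean[c(1, 50, 100, length(ocean))]) {
    expect_equal(bf_ols_slope(s$years[idx], flat[idx, cell]),
                 as.vector(tr)[cell], tolerance = 1e-12)
  }
})

test_that("the same seed regenerates a bitwise-identical series", {
  cfg <- world_config(resolution_deg = 30, n_years_past = 120L,
                      events = data.frame(start_year = 1850L,
                                          duration_yr = 50L, delta_t = 0.4),
                      n_species = 2L, master_seed = 77)
  a <- generate_sst(cfg, "past")$series
  b <- generate_sst(cfg, "past")$series
  expect_identical(a$sst, b$sst)
  c1 <- generate_species(cfg)
  c2 <- generate_species(cfg)
  expect_identical(c1$probs, c2$probs)
})

test_that("events outside the era's year range are rejected", {
  cfg <- world_config(resolution_deg = 30, n_years_past = 50L,
                      events = data.frame(start_year = 100L,
                                          duration_yr = 100L, delta_t = 0.5),
                      n_species = 2L)
  expect_error(generate_sst(cfg, "past"), "outside the era")
})

test_that("control-era centennial rates are centred on zero", {
  cfg <- world_config(resolution_deg = 15, n_years_past = 120L,
                      control_years = 600L, events = default_events()[0, ],
                      n_species = 2L, master_seed = 3)
  ctrl <- generate_sst(cfg, "control")$series
  w <- centennial_rates(ctrl)
  se <- sd(w$global_rate) / sqrt(nrow(w))
  expect_lt(abs(mean(w$global_rate)), 3 * se + 1e-6)
})

test_that("a stronger scenario trend increases every ocean cell's forced slope", {
  base <- list(resolution_deg = 30, n_years_past = 150L, noise_sd = 0,
               noise_polar_amp = 1,
               events = data.frame(start_year = 1851L, duration_yr = 50L,
                                   delta_t = 0.2),
               n_species = 2L, master_seed = 1)
  cfg_lo <- do.call(world_config, c(base, list(
    future_trend = c(future_scenario_A = 0.005, future_scenario_B = 0.01))))
  cfg_hi <- do.call(world_config, c(base, list(
    future_trend = c(future_scenario_A = 0.009, future_scenario_B = 0.01))))
  slope_of <- function(cfg) {
    s <- generate_sst(cfg, "future_scenario_A")$series
    idx <- which(s$years >= 1951 & s$years <= 2050)
    flat <- matrix(s$sst, nrow = length(s$years))
    ocean <- which(!as.vector(s$grid$land_mask))
    vapply(ocean, function(cell) bf_ols_slope(s$years[idx], flat[idx, cell]),
           numeric(1))
  }
  expect_true(all(slope_of(cfg_hi) > slope_of(cfg_lo)))
})

test_that("species probabilities are valid and richness peaks in the tropics", {
  highs <- lows <- numeric(0)
  for (seed in 1:20) {
    cfg <- world_config(resolution_deg = 30, species_factor = 3L,
                        n_years_past = 50L,
                        events = default_events()[0, ],
                        n_species = 40L, master_seed = seed)
    sp <- generate_species(cfg)
    expect_true(all(sp$probs >= 0 & sp$probs <= 1, na.rm = TRUE))
    rich <- richness_from_probs(sp, 0.4)
    latm <- matrix(sp$grid$lat_centers, nrow(rich$values), ncol(rich$values))
    lows <- c(lows, mean(rich$values[abs(latm) <= 30], na.rm = TRUE))
    highs <- c(highs, mean(rich$values[abs(latm) >= 60], na.rm = TRUE))
  }
  expect_gt(mean(lows), mean(highs))
})

test_that("a single species' thresholded presence contains its peak cell", {
  cfg <- world_config(resolution_deg = 30, species_factor = 3L,
                      n_years_past = 50L, events = default_events()[0, ],
                      n_species = 1L, prob_peak = c(0.9, 0.9),
                      master_seed = 4)
  sp <- generate_species(cfg)
  p <- sp$probs[, , 1]
  peak <- which(p == max(p, na.rm = TRUE), arr.ind = TRUE)[1, ]
  pres <- !is.na(p) & p >= 0.4
  expect_true(pres[peak[1], peak[2]])
  expect_gt(sum(pres), 1)  # a blob, not a point
})

test_that("generated masks satisfy their construction rules", {
  cfg <- world_config(resolution_deg = 10, n_years_past = 50L,
                      events = default_events()[0, ], n_species = 2L,
                      n_realms = 8L, eez_width_cells = 1L)
  m <- generate_masks(cfg)
  land <- m$land_mask

  # EEZ with width 1 is exactly the ocean cells 8-adjacent to land
  nlat <- nrow(land); nlon <- ncol(land)
  adj <- matrix(FALSE, nlat, nlon)
  for (r in seq_len(nlat)) for (c in seq_len(nlon)) {
    if (land[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- ((c + dc - 1) %% nlon) + 1
      if (r2 >= 1 && r2 <= nlat && land[r2, c2]) adj[r, c] <- TRUE
    }
  }
  expect_identical(m$eez_mask, adj)

  # realm ids partition ocean exactly once, with the configured count
  ids <- m$realm_id$values
  expect_true(all(is.na(ids[land])))
  expect_true(all(!is.na(ids[!land])))
  expect_equal(length(unique(ids[!land])), 8L)

  # closed barriers split the ocean into two disconnected basins
  sg <- build_sea_graph(m$grid)
  comp <- igraph::components(sg$graph)
  rc <- which(!land, arr.ind = TRUE)
  ocean_ids <- oceanexposure:::cell_id(m$grid, rc[, 1], rc[, 2])
  expect_equal(length(unique(comp$membership[ocean_ids])), 2L)
})
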