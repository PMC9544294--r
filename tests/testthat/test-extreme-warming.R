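series_of <- function(y, years = seq_along(y)) {
  structure(as.numeric(y), years = as.integer(years))
}

test_that("centennial rates recover exact linear slopes and reject short series", {
  t <- 1:300
  w <- centennial_rates(series_of(0.001 * t, t))
  expect_equal(w$global_rate, rep(0.1, nrow(w)), tolerance = 1e-10)
  expect_equal(w$end_year - w$start_year + 1, rep(100, nrow(w)))

  wc <- centennial_rates(series_of(rep(5, 150)))
  expect_equal(wc$global_rate, rep(0, nrow(wc)))

  set.seed(8)
  y <- 0.002 * (1:100) + rnorm(100, 0, 0.1)
  w1 <- centennial_rates(series_of(y))
  expect_equal(w1$global_rate[1], bf_ols_slope(1:100, y) * 100,
               tolerance = 1e-10)

  expect_error(centennial_rates(series_of(1:50)), "shorter than one window")
})

test_that("threshold calibration matches the sort-and-interpolate percentile oracle", {
  expect_equal(calibrate_threshold(rep(0, 25)), 0)
  rates <- seq(0, 0.19, by = 0.01)
  expect_equal(calibrate_threshold(rates, percentile = 95),
               bf_percentile(rates, 95), tolerance = 1e-12)
  set.seed(4)
  r2 <- rnorm(50, 0, 0.05)
  expect_equal(calibrate_threshold(r2, percentile = 95),
               bf_percentile(r2, 95), tolerance = 1e-12)
  expect_error(calibrate_threshold(rnorm(10)), "at least 20")
})

test_that("extreme classification is inclusive at the threshold", {
  w <- data.frame(start_year = 1:3, end_year = 100:102,
                  global_rate = c(0.18, 0.17999, 0.5), is_extreme = NA)
  out <- classify_extreme(w, 0.18)
  expect_identical(out$is_extreme, c(TRUE, FALSE, TRUE))

  set.seed(12)
  w2 <- data.frame(start_year = 1:40, end_year = 101:140,
                   global_rate = rnorm(40, 0.18, 0.05), is_extreme = NA)
  out2 <- classify_extreme(w2, 0.18)
  expect_identical(which(out2$is_extreme),
                   which(w2$global_rate >= 0.18))
})

# A two-window piecewise-linear one-profile world: every cell follows y(t).
piecewise_series <- function(y, years) {
  g <- grid_spec(90)  # 2 x 4 cells
  sst <- array(rep(y, times = 8), c(length(years), 2, 4))
  sst_series(g, years, sst, era = "past")
}

test_that("per-cell stats average window slopes and flag zero variability", {
  years <- 1:200
  y <- c(0.002 * (1:100), 0.002 * 100 + 0.004 * (1:100))
  s <- piecewise_series(y, years)
  wins <- data.frame(start_year = c(1, 101), end_year = c(100, 200),
                     global_rate = c(0.2, 0.4), is_extreme = TRUE)
  expect_warning(st <- cell_stats_for_era(s, wins), "zero variability")
  expect_equal(unique(as.vector(st$trend)), 0.003, tolerance = 1e-12)
  expect_equal(st$global_trend_mean, 0.3)
  expect_equal(unique(as.vector(st$scaled_trend)), 0.003 / 0.003,
               tolerance = 1e-12)
  expect_true(all(is.na(st$snr)))
  expect_error(cell_stats_for_era(s, wins[0, ]), "no extreme windows")
})

test_that("SNR is invariant to a sign flip of the trend", {
  years <- 1:100
  set.seed(21)
  y <- 0.003 * years + rnorm(100, 0, 0.05)
  g <- grid_spec(90)
  up <- sst_series(g, years, array(rep(y, each = 1, times = 8),
                                   c(100, 2, 4)), era = "past")
  dn <- sst_series(g, years, array(rep(-y, times = 8), c(100, 2, 4)),
                   era = "past")
  wins <- data.frame(start_year = 1, end_year = 100, global_rate = 0.3,
                     is_extreme = TRUE)
  wins_dn <- data.frame(start_year = 1, end_year = 100, global_rate = -0.3,
                        is_extreme = TRUE)
  expect_equal(cell_stats_for_era(up, wins)$snr,
               cell_stats_for_era(dn, wins_dn)$snr, tolerance = 1e-12)
})

test_that("scaling the era's SST by c leaves scaled trends invariant and divides SNR by c", {
  cfg <- world_config(resolution_deg = 30, n_years_past = 150L,
                      noise_sd = 0.1, noise_polar_amp = 1,
                      events = data.frame(start_year = 1830L,
                                          duration_yr = 100L, delta_t = 0.5),
                      n_species = 2L, master_seed = 6)
  s <- generate_sst(cfg, "past")$series
  wins <- classify_extreme(centennial_rates(s), 0.18)
  st1 <- cell_stats_for_era(s, wins)
  c_ <- 2.5
  s2 <- sst_series(s$grid, s$years, s$sst * c_, s$era)
  wins2 <- classify_extreme(centennial_rates(s2), 0.18 * c_)
  st2 <- cell_stats_for_era(s2, wins2)
  expect_equal(st2$scaled_trend, st1$scaled_trend, tolerance = 1e-10)
  expect_equal(st2$snr, st1$snr / c_, tolerance = 1e-10)
})

test_that("doubling the residual noise SD halves the mean SNR", {
  base <- list(resolution_deg = 15, n_years_past = 150L,
               noise_polar_amp = 1, ar1_phi = 0,
               events = data.frame(start_year = 1830L, duration_yr = 100L,
                                   delta_t = 0.5),
               n_species = 2L, master_seed = 19)
  snr_at <- function(sd) {
    cfg <- do.call(world_config, c(base, list(noise_sd = sd)))
    s <- generate_sst(cfg, "past")$series
    wins <- data.frame(start_year = 1830L, end_year = 1929L,
                       global_rate = 0.5, is_extreme = TRUE)
    mean(cell_stats_for_era(s, wins)$snr, na.rm = TRUE)
  }
  ratio <- snr_at(0.1) / snr_at(0.2)
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("noise-free injected events above threshold are recovered exactly", {
  cfg <- noise_free_config()
  s <- generate_sst(cfg, "past")$series
  wins <- classify_extreme(centennial_rates(s), 0.18)
  flagged <- wins[wins$is_extreme, ]
  overlaps_event <- function(a, b) a <= 1800 && b >= 1701
  expect_true(all(mapply(overlaps_event, flagged$start_year,
                         flagged$end_year)))
  # a window that fully covers the event is certainly flagged
  expect_true(any(flagged$start_year == 1701))
})

test_that("delta SNR is the elementwise difference with the documented sign", {
  g <- grid_spec(90)
  set.seed(31)
  mk <- function(snr) structure(list(grid = g, era = "x", snr = snr),
                                class = "cell_climate_stats")
  a <- matrix(runif(8), 2, 4); b <- matrix(runif(8), 2, 4)
  d <- delta_snr(mk(a), mk(b))
  expect_equal(d$delta_snr, b - a, tolerance = 1e-15)
  expect_equal(delta_snr(mk(a), mk(a))$delta_snr, matrix(0, 2, 4))
  expect_equal(delta_snr(mk(matrix(0.5, 2, 4)),
                         mk(matrix(2, 2, 4)))$delta_snr[1, 1], 1.5)
})
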