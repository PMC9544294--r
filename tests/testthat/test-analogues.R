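flat_series <- function(g, years, fun) {
  nt <- length(years)
  sst <- array(NA_real_, c(nt, length(g$lat_centers), length(g$lon_centers)))
  for (t in seq_len(nt)) {
    slice <- fun(years[t])
    slice[g$land_mask] <- NA_real_
    sst[t, , ] <- slice
  }
  structure(list(grid = g, years = as.integer(years), sst = sst,
                 era = "past"), class = "sst_series")
}

test_that("delta bias correction applies the per-cell two-mean difference", {
  g <- grid_spec(45)
  years <- 1840:1960
  set.seed(18)
  base <- matrix(rnorm(32, 10), 4, 8)
  past <- flat_series(g, years, function(t) base + 0.01 * (t - 1900))
  ref_same <- past; ref_same$era <- "historical"
  out <- delta_bias_correct(past, ref_same, c(1850, 1950))
  expect_equal(out$sst, past$sst, tolerance = 1e-12)

  ref_plus <- past; ref_plus$sst <- past$sst + 1
  out2 <- delta_bias_correct(past, ref_plus, c(1850, 1950))
  expect_equal(out2$sst, past$sst + 1, tolerance = 1e-12)

  # random fields: deltas equal the independent two-mean-difference oracle
  ref_r <- past
  ref_r$sst <- past$sst + array(rnorm(length(past$sst), 0.3, 0.2),
                                dim(past$sst))
  out3 <- delta_bias_correct(past, ref_r, c(1850, 1950))
  sel <- years >= 1850 & years <= 1950
  cell <- c(2, 5)
  dlt <- mean(ref_r$sst[sel, cell[1], cell[2]]) -
    mean(past$sst[sel, cell[1], cell[2]])
  expect_equal(out3$sst[1, cell[1], cell[2]],
               past$sst[1, cell[1], cell[2]] + dlt, tolerance = 1e-12)

  expect_error(delta_bias_correct(past, ref_same, c(3000, 3100)),
               "not covered")
})

test_that("upper temperatures are window maxima with inclusive bounds", {
  g <- grid_spec(45)
  years <- 1:50
  s <- flat_series(g, years, function(t) matrix(4, 4, 8))
  expect_true(all(htm_upper_temperature(s, c(10, 20))$values == 4))

  spike <- flat_series(g, years, function(t)
    matrix(ifelse(t == 15, 9, 1), 4, 8))
  expect_true(all(htm_upper_temperature(spike, c(10, 20))$values == 9))
  expect_true(all(htm_upper_temperature(spike, c(16, 30))$values == 1))

  set.seed(19)
  vals <- sin(seq(0, 8, length.out = 50)) + rnorm(50, 0, 0.1)
  rnd <- flat_series(g, years, function(t) matrix(vals[t], 4, 8))
  win <- c(7, 33)
  expect_equal(future_upper_temperature(rnd, win)$values[1, 1],
               max(vals[years >= 7 & years <= 33]), tolerance = 1e-12)
})

test_that("an all-ocean 3x3 grid yields 20 edges and exact haversine weights", {
  g <- local_grid(c(-5, 0, 5), c(0, 5, 10))
  sg <- build_sea_graph(g, wrap_lon = FALSE)
  expect_equal(nrow(sg$edges), 20)
  expect_equal(igraph::ecount(sg$graph), 20)

  # adjacent equatorial cells at 2.5 deg spacing
  g2 <- local_grid(c(-1.25, 1.25), c(0, 2.5, 5), res = 2.5)
  sg2 <- build_sea_graph(g2, wrap_lon = FALSE)
  i <- oceanexposure:::cell_id(g2, 2, 1)  # not at lat 0; use explicit formula
  w_eq <- bf_haversine(0, 0, 0, 2.5)
  expect_equal(w_eq, 2 * 6371 * asin(abs(sin(2.5 / 2 * pi / 180))),
               tolerance = 1e-9)
  expect_equal(round(w_eq, 1), 278.0)

  g3 <- local_grid(0, c(0, 2.5), res = 2.5)
  sg3 <- build_sea_graph(g3, wrap_lon = FALSE)
  expect_equal(sg3$edges$weight, w_eq, tolerance = 1e-9)
})

test_that("diagonal edges cannot corner-cut through diagonal land pairs", {
  land <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  g <- local_grid(c(0, 5), c(0, 5), land = land)
  sg <- build_sea_graph(g, wrap_lon = FALSE)
  expect_equal(nrow(sg$edges), 0)

  land2 <- matrix(FALSE, 2, 2); land2[1, 2] <- TRUE
  g2 <- local_grid(c(0, 5), c(0, 5), land = land2)
  sg2 <- build_sea_graph(g2, wrap_lon = FALSE)
  expect_equal(nrow(sg2$edges), 3)  # two orthogonal + one allowed diagonal
})

test_that("a closed land barrier separates components and forces no-analogue", {
  land <- matrix(FALSE, 3, 5); land[, 3] <- TRUE
  g <- local_grid(c(-5, 0, 5), seq(0, 20, by = 5), land = land)
  sg <- build_sea_graph(g, wrap_lon = FALSE)
  comp <- igraph::components(sg$graph)
  left <- oceanexposure:::cell_id(g, 2, 1)
  right <- oceanexposure:::cell_id(g, 2, 5)
  expect_false(comp$membership[left] == comp$membership[right])

  # qualifying analogues only on the far side -> flagged no-analogue
  htm <- gridded_field(g, matrix(10, 3, 5))
  fut <- matrix(20, 3, 5); fut[, 4:5] <- 5
  futf <- gridded_field(g, fut)
  res <- nearest_analogue(left, htm, futf, sg)
  expect_true(res$no_analogue)

  # self-analogue when the focal cell itself qualifies
  fut2 <- matrix(5, 3, 5)
  res2 <- nearest_analogue(left, htm, gridded_field(g, fut2), sg)
  expect_equal(res2$target_cell, left)
  expect_equal(res2$sea_distance_km, 0)
})

test_that("nearest analogues match the brute-force oracle on a peninsula grid", {
  set.seed(23)
  nlat <- 10; nlon <- 10
  lat <- seq(-22.5, 22.5, by = 5); lon <- seq(0, 45, by = 5)
  land <- matrix(FALSE, nlat, nlon)
  land[3:8, 5] <- TRUE   # a peninsula jutting from the southern edge
  g <- local_grid(lat, lon, land = land)
  sg <- build_sea_graph(g, wrap_lon = FALSE)
  htm <- matrix(runif(100, 8, 12), nlat, nlon); htm[land] <- NA
  fut <- matrix(runif(100, 6, 14), nlat, nlon); fut[land] <- NA
  rc <- which(!land, arr.ind = TRUE)
  ocean_ids <- sort(oceanexposure:::cell_id(g, rc[, 1], rc[, 2]))
  focal <- sample(ocean_ids, 12)
  res <- nearest_analogue(focal, gridded_field(g, htm), gridded_field(g, fut),
                          sg)
  D <- bf_sea_distances(g, land, wrap = FALSE)
  htm_vec <- as.vector(t(htm)); fut_vec <- as.vector(t(fut))
  oracle <- bf_nearest_analogue(D, focal, ocean_ids, htm_vec, fut_vec)
  expect_equal(res$target_cell, unname(oracle[, "target"]))
  expect_equal(res$sea_distance_km, unname(oracle[, "dist"]),
               tolerance = 1e-9)
})

test_that("opening a strait never increases a sea distance", {
  lat <- seq(-10, 10, by = 5); lon <- seq(0, 30, by = 5)
  land_closed <- matrix(FALSE, 5, 7); land_closed[, 4] <- TRUE
  land_open <- land_closed; land_open[3, 4] <- FALSE
  g1 <- local_grid(lat, lon, land = land_closed)
  g2 <- local_grid(lat, lon, land = land_open)
  D1 <- igraph::distances(build_sea_graph(g1, wrap_lon = FALSE)$graph)
  D2 <- igraph::distances(build_sea_graph(g2, wrap_lon = FALSE)$graph)
  expect_true(all(D2 <= D1 + 1e-9))
})

test_that("warming the future field never decreases analogue distances", {
  set.seed(24)
  lat <- seq(-10, 10, by = 5); lon <- seq(0, 30, by = 5)
  land <- matrix(runif(35) < 0.2, 5, 7)
  g <- local_grid(lat, lon, land = land)
  sg <- build_sea_graph(g, wrap_lon = FALSE)
  rc <- which(!land, arr.ind = TRUE)
  ocean_ids <- sort(oceanexposure:::cell_id(g, rc[, 1], rc[, 2]))
  htm <- matrix(runif(35, 8, 12), 5, 7); htm[land] <- NA
  fut <- matrix(runif(35, 7, 13), 5, 7); fut[land] <- NA
  r1 <- nearest_analogue(ocean_ids, gridded_field(g, htm),
                         gridded_field(g, fut), sg)
  r2 <- nearest_analogue(ocean_ids, gridded_field(g, htm),
                         gridded_field(g, fut + 0.5), sg)
  d1 <- ifelse(r1$no_analogue, Inf, r1$sea_distance_km)
  d2 <- ifelse(r2$no_analogue, Inf, r2$sea_distance_km)
  expect_true(all(d2 >= d1 - 1e-9))
})

test_that("realm crossing percentages follow the hand count", {
  g <- grid_spec(45)
  ids <- matrix(1L, 4, 8); ids[3:4, ] <- 2L
  rf <- gridded_field(g, ids)
  self_res <- data.frame(focal_cell = c(1L, 2L), target_cell = c(1L, 2L),
                         no_analogue = FALSE)
  expect_equal(realm_crossing_summary(self_res, rf)$pct_crossing, 0)
  cross_res <- data.frame(focal_cell = c(1L, 2L),
                          target_cell = c(25L, 26L),  # rows 4 -> realm 2
                          no_analogue = FALSE)
  expect_equal(realm_crossing_summary(cross_res, rf)$pct_crossing, 100)
  mixed <- data.frame(focal_cell = c(1L, 2L, 3L, 4L),
                      target_cell = c(25L, 2L, 26L, NA),
                      no_analogue = c(FALSE, FALSE, FALSE, TRUE))
  out <- realm_crossing_summary(mixed, rf)
  expect_equal(out$pct_crossing, 100 * 2 / 3)
  expect_equal(out$pct_no_analogue, 25)
})

test_that("redistribution rates divide distance by the horizon", {
  expect_equal(redistribution_rate(1625), 1625 / 70, tolerance = 1e-12)
  expect_equal(redistribution_rate(0), 0)
  df <- data.frame(sea_distance_km = c(700, NA))
  out <- redistribution_rate(df, horizon_years = 70)
  expect_equal(out$rate_km_per_yr, c(10, NA))
  expect_error(redistribution_rate(100, horizon_years = 0))
})

test_that("Hovmoller rows are area-weighted means over hotspot cells per band", {
  g <- grid_spec(45)
  years <- 1:5
  s <- flat_series(g, years, function(t) matrix(3, 4, 8))
  hot <- matrix(TRUE, 4, 8)
  hv <- hovmoller(s, hot, band_width_deg = 45)
  expect_equal(dim(hv$values), c(4, 5))
  expect_equal(hv$values, matrix(3, 4, 5), tolerance = 1e-12)

  # two cells in one band with different values: weighted two-value mean
  vals <- matrix(0, 4, 8); vals[1, 1] <- 2; vals[1, 2] <- 4
  s2 <- flat_series(g, 1:2, function(t) vals)
  hot2 <- matrix(FALSE, 4, 8); hot2[1, 1:2] <- TRUE
  hv2 <- hovmoller(s2, hot2, band_width_deg = 45)
  w <- g$cell_area[1, 1:2]
  expect_equal(hv2$values[1, 1], sum(w * c(2, 4)) / sum(w), tolerance = 1e-12)
  expect_true(all(is.na(hv2$values[2:4, ])))
})
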