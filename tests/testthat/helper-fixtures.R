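# Shared fixtures and independent oracles. Oracles are written as plain
# loops/closed forms so they stay independent of the package internals they
# check.

# Arbitrary (possibly non-global) regular grid for toy cases.
local_grid <- function(lat, lon, land = NULL, res = NULL) {
  if (is.null(land)) land <- matrix(FALSE, length(lat), length(lon))
  if (is.null(res)) res <- if (length(lat) > 1) diff(lat)[1] else 1
  structure(list(resolution_deg = res, lat_centers = lat, lon_centers = lon,
                 land_mask = land,
                 cell_area = matrix(cos(lat * pi / 180),
                                    length(lat), length(lon)),
                 area_method = "coslat"),
            class = "grid_spec")
}

# One-cell-at-a-time weighted mean oracle.
bf_weighted_mean <- function(values, weights, ocean) {
  num <- 0; den <- 0
  for (i in seq_along(values)) {
    if (ocean[i] && !is.na(values[i])) {
      num <- num + weights[i] * values[i]
      den <- den + weights[i]
    }
  }
  num / den
}

# Closed-form OLS slope oracle.
bf_ols_slope <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  sum((t - tb) * (y - yb)) / sum((t - tb)^2)
}

# Sort-and-interpolate percentile oracle (type-7 linear interpolation).
bf_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Direct Benjamini-Yekutieli step-up formula.
bf_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cand <- Inf
    for (j in seq_len(m)) {
      rank_j <- which(ord == j)
      if (rank_j >= rank_i)
        cand <- min(cand, min(1, p[j] * m * cm / rank_j))
    }
    padj[i] <- cand
  }
  padj
}

# Two-sample KS statistic by an explicit ECDF sweep over pooled points.
bf_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (p in pts) {
    d <- max(d, abs(mean(x <= p) - mean(y <= p)))
  }
  d
}

# Haversine closed form (R = 6371 km), scalar.
bf_haversine <- function(lat1, lon1, lat2, lon2) {
  d2r <- pi / 180
  a <- sin((lat2 - lat1) * d2r / 2)^2 +
    cos(lat1 * d2r) * cos(lat2 * d2r) * sin((lon2 - lon1) * d2r / 2)^2
  2 * 6371 * asin(min(1, sqrt(a)))
}

# Brute-force sea-distance oracle: adjacency by explicit double loop with the
# same connectivity rules, then Floyd-Warshall all-pairs shortest paths.
bf_sea_distances <- function(grid, land, connectivity = 8, wrap = TRUE) {
  nlat <- length(grid$lat_centers); nlon <- length(grid$lon_centers)
  n <- nlat * nlon
  id <- function(r, c) (r - 1) * nlon + c
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  offs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (connectivity == 8)
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  for (r in seq_len(nlat)) for (c in seq_len(nlon)) {
    if (land[r, c]) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nlat) next
      if (wrap) c2 <- ((c2 - 1) %% nlon) + 1
      else if (c2 < 1 || c2 > nlon) next
      if (land[r2, c2]) next
      if (o[1] != 0 && o[2] != 0) {
        cc <- if (wrap) ((c + o[2] - 1) %% nlon) + 1 else c + o[2]
        if (land[r, cc] && land[r2, c]) next  # corner-cut blocked
      }
      w <- bf_haversine(grid$lat_centers[r], grid$lon_centers[c],
                        grid$lat_centers[r2], grid$lon_centers[c2])
      D[id(r, c), id(r2, c2)] <- w
    }
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# Brute-force nearest-analogue: filter candidates, pick minimum distance with
# the tie order (distance, lowest future upper, lowest cell index).
bf_nearest_analogue <- function(D, focal, cand_ids, htm_vec, fut_vec) {
  t(sapply(focal, function(i) {
    ok <- cand_ids[!is.na(fut_vec[cand_ids]) &
                     fut_vec[cand_ids] <= htm_vec[i] &
                     is.finite(D[i, cand_ids])]
    if (!length(ok)) return(c(target = NA_real_, dist = NA_real_))
    o <- ok[order(D[i, ok], fut_vec[ok], ok)][1]
    c(target = o, dist = D[i, o])
  }))
}

# Deterministic single-event past era (noise-free unless overridden).
noise_free_config <- function(...) {
  args <- utils::modifyList(
    list(resolution_deg = 30, n_years_past = 300L,
         past_end_year = 1950L, control_years = 150L,
         noise_sd = 0, noise_polar_amp = 1,
         events = data.frame(start_year = 1701L, duration_yr = 100L,
                             delta_t = 0.5),
         n_species = 3L, master_seed = 1),
    list(...))
  do.call(world_config, args)
}

# Small complete world for end-to-end tests.
tiny_world_config <- function(seed = 1, ...) {
  demo_world_config(master_seed = seed,
                    n_years_past = 1000L, control_years = 300L,
                    events = data.frame(start_year = c(1001L, 1301L, 1601L),
                                        duration_yr = 100L, delta_t = 0.5),
                    n_species = 60L, ...)
}

demo_pipeline_config <- function(seed = 1, ...) {
  pipeline_config(world = demo_world_config(master_seed = seed),
                  overlap_years = c(1851, 1950),
                  htm_window = c(1151, 1550), ...)
}
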