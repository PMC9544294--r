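#' Delta bias-correction of a past SST series against a reference
#'
#' Shifts every cell of `past` by the difference of its mean against the
#' reference over the overlap window (a per-cell constant shift):
#' `corrected(cell, t) = past(cell, t) + [mean_ref(cell) - mean_past(cell)]`.
#'
#' @param past,reference [sst_series()] on the same grid, both covering the
#'   overlap window.
#' @param overlap inclusive year range, default `c(1850, 1950)`.
#' @return the corrected past [sst_series()]; the per-cell delta matrix is
#'   attached as `attr(,"delta")`.
#' @export
delta_bias_correct <- function(past, reference, overlap = c(1850, 1950)) {
  stopifnot(inherits(past, "sst_series"), inherits(reference, "sst_series"))
  sel_p <- past$years >= overlap[1] & past$years <= overlap[2]
  sel_r <- reference$years >= overlap[1] & reference$years <= overlap[2]
  if (!any(sel_p) || !any(sel_r))
    stop("overlap window ", overlap[1], "-", overlap[2],
         " not covered by both series")
  mean_over <- function(s, sel) {
    m <- matrix(s$sst, nrow = length(s$years))[sel, , drop = FALSE]
    matrix(colMeans(m), n_lat(s$grid), n_lon(s$grid))
  }
  delta <- mean_over(reference, sel_r) - mean_over(past, sel_p)
  corrected <- past$sst + rep(as.vector(delta), each = length(past$years))
  out <- sst_series(past$grid, past$years, corrected, past$era)
  attr(out, "delta") <- delta
  out
}

upper_temperature <- function(series, window) {
  stopifnot(inherits(series, "sst_series"))
  sel <- series$years >= window[1] & series$years <= window[2]
  if (!any(sel)) stop("window ", window[1], "..", window[2],
                      " outside the series years")
  m <- matrix(series$sst, nrow = length(series$years))[sel, , drop = FALSE]
  vals <- suppressWarnings(apply(m, 2L, max, na.rm = TRUE))
  vals[!is.finite(vals)] <- NA_real_
  gridded_field(series$grid,
                matrix(vals, n_lat(series$grid), n_lon(series$grid)),
                units = "degC")
}

#' Upper cell temperatures of the Holocene thermal maximum
#'
#' Per cell, the maximum annual-mean SST within the HTM window (inclusive
#' bounds; default 9000--5000 B.P., i.e. calendar years -7050 to -3050 with
#' present = 1950 C.E.).
#'
#' @param past_corrected bias-corrected past [sst_series()].
#' @param window inclusive calendar-year bounds.
#' @return [gridded_field()] of upper temperatures (degrees C).
#' @export
htm_upper_temperature <- function(past_corrected, window = c(-7050, -3050)) {
  upper_temperature(past_corrected, window)
}

#' Upper cell temperatures of the end-of-century window
#'
#' Per cell, the maximum annual-mean SST within the 21-year window centred
#' on 2090 (2080--2100 C.E. by default); the same statistic as the HTM side.
#'
#' @param future a future-scenario [sst_series()].
#' @param window inclusive calendar-year bounds.
#' @return [gridded_field()] of upper temperatures (degrees C).
#' @export
future_upper_temperature <- function(future, window = c(2080, 2100)) {
  upper_temperature(future, window)
}

#' Build the sea-only movement graph
#'
#' Nodes are grid cells (row-major ids); edges connect neighbouring ocean
#' cells with weight equal to the haversine distance (km, R = 6371) between
#' cell centres. With 8-connectivity a diagonal edge additionally requires at
#' least one of the two shared orthogonal neighbours to be ocean, so paths
#' cannot corner-cut through diagonal land pairs. Longitude wraps at the
#' dateline; the poles are not connected across the top/bottom rows.
#'
#' @param grid a [grid_spec()].
#' @param land_mask logical land matrix (default the grid's own).
#' @param connectivity 4 or 8 (default 8).
#' @param wrap_lon wrap longitude at the dateline (default `TRUE`).
#' @return object of class `sea_graph`: the igraph `graph` (one vertex per
#'   grid cell; isolated vertices allowed), the `grid`, and the edge table.
#' @export
build_sea_graph <- function(grid, land_mask = grid$land_mask,
                            connectivity = 8L, wrap_lon = TRUE) {
  stopifnot(inherits(grid, "grid_spec"), connectivity %in% c(4L, 8L))
  nlat <- n_lat(grid); nlon <- n_lon(grid)
  ocean <- !land_mask
  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  rows <- matrix(seq_len(nlat), nlat, nlon)
  cols <- matrix(seq_len(nlon), nlat, nlon, byrow = TRUE)
  wrap_col <- function(cc) ((cc - 1L) %% nlon) + 1L
  for (off in offsets) {
    r2 <- rows + off[1]
    c2raw <- cols + off[2]
    valid <- r2 >= 1L & r2 <= nlat
    if (!wrap_lon) valid <- valid & c2raw >= 1L & c2raw <= nlon
    c2 <- wrap_col(c2raw)
    idx <- which(valid)
    a_r <- rows[idx]; a_c <- cols[idx]; b_r <- r2[idx]; b_c <- c2[idx]
    keep <- ocean[cbind(a_r, a_c)] & ocean[cbind(b_r, b_c)]
    if (all(off != 0L)) {
      # anti-corner-cutting: one of the two shared orthogonal cells is ocean
      s1 <- ocean[cbind(a_r, b_c)]
      s2 <- ocean[cbind(b_r, a_c)]
      keep <- keep & (s1 | s2)
    }
    from <- c(from, cell_id(grid, a_r[keep], a_c[keep]))
    to <- c(to, cell_id(grid, b_r[keep], b_c[keep]))
  }
  ll_from <- cell_latlon(grid, from)
  ll_to <- cell_latlon(grid, to)
  w <- haversine_km(ll_from[, "lat"], ll_from[, "lon"],
                    ll_to[, "lat"], ll_to[, "lon"])
  g <- igraph::make_empty_graph(n = nlat * nlon, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  structure(list(graph = g, grid = grid, land_mask = land_mask,
                 edges = data.frame(from = from, to = to, weight = w),
                 connectivity = connectivity),
            class = "sea_graph")
}

#' @export
print.sea_graph <- function(x, ...) {
  cat(sprintf("<sea_graph> %d cells, %d ocean, %d edges (%d-connectivity)\n",
              n_cells(x$grid), sum(!x$land_mask),
              nrow(x$edges), x$connectivity))
  invisible(x)
}

#' Nearest future thermal analogue by sea-only distance
#'
#' Cell `j` is an analogue of focal cell `i` iff `j` is in the candidate
#' mask and `future_upper(j) <= htm_upper(i) + tol_degC`. Each focal cell is
#' matched to the analogue minimising the shortest-path sea distance
#' (Dijkstra over the sea graph); the focal cell itself is allowed (distance
#' 0). Ties are broken by distance, then lowest future upper temperature,
#' then row-major cell index. Focal cells with no reachable analogue are
#' flagged `no_analogue`.
#'
#' @param focal_cells integer row-major cell ids (must be ocean).
#' @param htm_upper,future_upper [gridded_field()]s of upper temperatures.
#' @param sea_graph a [build_sea_graph()] result.
#' @param candidate_mask logical matrix of admissible target cells (default:
#'   all ocean). Restrict to an EEZ mask for the near-shore variant.
#' @param tol_degC tolerance added to the focal ceiling (default 0).
#' @return data frame of class `analogue_result`: focal/target cell ids and
#'   coordinates, `sea_distance_km`, `no_analogue`, `target_future_upper`.
#' @export
nearest_analogue <- function(focal_cells, htm_upper, future_upper, sea_graph,
                             candidate_mask = NULL, tol_degC = 0) {
  grid <- sea_graph$grid
  land <- sea_graph$land_mask
  focal_cells <- as.integer(focal_cells)
  rc <- cell_rowcol(grid, focal_cells)
  if (any(land[rc]))
    stop("focal cell(s) on land: ",
         paste(focal_cells[land[rc]], collapse = ", "))
  if (is.null(candidate_mask)) candidate_mask <- !land
  cand_rc <- which(!land & candidate_mask, arr.ind = TRUE)
  cand_ids <- sort(cell_id(grid, cand_rc[, 1], cand_rc[, 2]))
  if (!length(cand_ids)) stop("empty candidate mask")
  fut <- future_upper$values
  htm <- htm_upper$values
  fut_flat <- fut[cell_rowcol(grid, cand_ids)]
  D <- igraph::distances(sea_graph$graph, v = focal_cells, to = cand_ids,
                         weights = igraph::E(sea_graph$graph)$weight,
                         algorithm = "dijkstra")
  out <- lapply(seq_along(focal_cells), function(i) {
    fid <- focal_cells[i]
    ceiling_t <- htm[cell_rowcol(grid, fid)]
    ok <- !is.na(fut_flat) & !is.na(ceiling_t) &
      fut_flat <= ceiling_t + tol_degC & is.finite(D[i, ])
    if (!any(ok)) {
      return(data.frame(focal_cell = fid, target_cell = NA_integer_,
                        sea_distance_km = NA_real_, no_analogue = TRUE,
                        target_future_upper = NA_real_))
    }
    idx <- which(ok)
    ord <- idx[order(D[i, idx], fut_flat[idx], cand_ids[idx])][1]
    data.frame(focal_cell = fid, target_cell = cand_ids[ord],
               sea_distance_km = D[i, ord], no_analogue = FALSE,
               target_future_upper = fut_flat[ord])
  })
  res <- do.call(rbind, out)
  fll <- cell_latlon(grid, res$focal_cell)
  res$focal_lat <- fll[, "lat"]; res$focal_lon <- fll[, "lon"]
  res$target_lat <- NA_real_; res$target_lon <- NA_real_
  has <- !res$no_analogue
  if (any(has)) {
    tll <- cell_latlon(grid, res$target_cell[has])
    res$target_lat[has] <- tll[, "lat"]; res$target_lon[has] <- tll[, "lon"]
  }
  class(res) <- c("analogue_result", "data.frame")
  attr(res, "grid") <- grid
  res
}

#' Percentage of analogues falling in a different biogeographic realm
#'
#' Among focal cells with an analogue, the percentage whose target realm
#' differs from the focal realm.
#'
#' @param results an `analogue_result` data frame.
#' @param realm_ids [gridded_field()] of realm ids.
#' @return list: `pct_crossing`, `n_with_analogue`, `n_no_analogue`,
#'   `pct_no_analogue`; the crossing flag is added to the returned `results`.
#' @export
realm_crossing_summary <- function(results, realm_ids) {
  grid <- realm_ids$grid
  ids <- realm_ids$values
  has <- !results$no_analogue
  crosses <- rep(NA, nrow(results))
  if (any(has)) {
    fr <- ids[cell_rowcol(grid, results$focal_cell[has])]
    tr <- ids[cell_rowcol(grid, results$target_cell[has])]
    crosses[has] <- fr != tr
  }
  results$crosses_realm <- crosses
  list(results = results,
       pct_crossing = if (any(has)) 100 * mean(crosses[has]) else NA_real_,
       n_with_analogue = sum(has),
       n_no_analogue = sum(!has),
       pct_no_analogue = 100 * mean(!has))
}

#' Required redistribution rate
#'
#' Distance divided by the movement horizon (default 70 years, 2020--2090).
#'
#' @param x an `analogue_result` data frame or a numeric vector of distances
#'   in km.
#' @param horizon_years years available for the move.
#' @return the data frame with a `rate_km_per_yr` column, or a numeric
#'   vector of rates.
#' @export
redistribution_rate <- function(x, horizon_years = 70) {
  stopifnot(horizon_years > 0)
  if (is.data.frame(x)) {
    x$rate_km_per_yr <- x$sea_distance_km / horizon_years
    x
  } else {
    as.numeric(x) / horizon_years
  }
}

#' Hovmoller matrix of hotspot SST by latitude band
#'
#' For each latitude band, the area-weighted mean SST over hotspot cells in
#' the band, per year. Bands without hotspot cells give missing rows.
#'
#' @param series an [sst_series()] (bias-correct the past first for
#'   cross-era harmonisation).
#' @param hotspot_mask logical matrix of focal cells.
#' @param band_width_deg latitude band width (default 5).
#' @return object of class `hovmoller_matrix`: `band_edges`, `band_mid`,
#'   `years`, and `values` (`n_bands x n_years`).
#' @export
hovmoller <- function(series, hotspot_mask, band_width_deg = 5) {
  stopifnot(inherits(series, "sst_series"))
  grid <- series$grid
  edges <- seq(-90, 90, by = band_width_deg)
  nb <- length(edges) - 1L
  band <- findInterval(grid$lat_centers, edges, rightmost.closed = TRUE)
  nt <- length(series$years)
  flat <- matrix(series$sst, nrow = nt)
  w <- grid$cell_area
  vals <- matrix(NA_real_, nb, nt)
  for (b in seq_len(nb)) {
    in_band <- matrix(band == b, n_lat(grid), n_lon(grid)) &
      hotspot_mask & !grid$land_mask
    if (!any(in_band)) next
    cells <- which(as.vector(in_band))
    wj <- w[as.vector(in_band)]
    sub <- flat[, cells, drop = FALSE]
    vals[b, ] <- apply(sub, 1L, function(v) {
      ok <- !is.na(v)
      if (!any(ok)) NA_real_ else sum(wj[ok] * v[ok]) / sum(wj[ok])
    })
  }
  structure(list(band_edges = edges,
                 band_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 years = series$years, values = vals),
            class = "hovmoller_matrix")
}
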