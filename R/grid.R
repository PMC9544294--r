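#' Regular latitude--longitude grid specification
#'
#' Defines a global regular grid with cell-centre registration: centres at
#' `lon = -180 + res/2 + k*res` and `lat = -90 + res/2 + j*res`. Latitude is
#' stored ascending, longitude in `[-180, 180)`. Matrices attached to the grid
#' (masks, fields) are `nlat x nlon`, rows following `lat_centers`.
#'
#' @param resolution_deg cell size in decimal degrees; must divide 180.
#' @param land_mask logical `nlat x nlon` matrix, `TRUE` on land. Default all
#'   ocean.
#' @param area_method `"coslat"` (weight proportional to `cos(lat)` of the
#'   cell centre) or `"spherical"` (exact spherical band area). Both are
#'   proportional weights, not absolute areas.
#' @return an object of class `grid_spec` with fields `resolution_deg`,
#'   `lat_centers`, `lon_centers`, `land_mask`, `cell_area`.
#' @export
grid_spec <- function(resolution_deg, land_mask = NULL,
                      area_method = c("coslat", "spherical")) {
  area_method <- match.arg(area_method)
  if (resolution_deg <= 0 || abs(180 / resolution_deg - round(180 / resolution_deg)) > 1e-9)
    stop("resolution_deg must be a positive divisor of 180")
  nlat <- as.integer(round(180 / resolution_deg))
  nlon <- as.integer(round(360 / resolution_deg))
  lat <- -90 + resolution_deg / 2 + (seq_len(nlat) - 1) * resolution_deg
  lon <- -180 + resolution_deg / 2 + (seq_len(nlon) - 1) * resolution_deg
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, nlat, nlon)
  } else {
    land_mask <- as.matrix(land_mask)
    if (!identical(dim(land_mask), c(nlat, nlon)))
      stop("land_mask must be ", nlat, " x ", nlon, " for this resolution")
    storage.mode(land_mask) <- "logical"
  }
  w <- if (area_method == "coslat") {
    cos(lat * pi / 180)
  } else {
    half <- resolution_deg / 2
    sin((lat + half) * pi / 180) - sin((lat - half) * pi / 180)
  }
  structure(
    list(resolution_deg = resolution_deg,
         lat_centers = lat, lon_centers = lon,
         land_mask = land_mask,
         cell_area = matrix(w, nlat, nlon),
         area_method = area_method),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %.3g deg, %d x %d cells, %d ocean / %d land (%s weights)\n",
              x$resolution_deg, length(x$lat_centers), length(x$lon_centers),
              sum(!x$land_mask), sum(x$land_mask), x$area_method))
  invisible(x)
}

n_lat <- function(grid) length(grid$lat_centers)
n_lon <- function(grid) length(grid$lon_centers)
n_cells <- function(grid) n_lat(grid) * n_lon(grid)

# Row-major cell index: id = (lat_row - 1) * nlon + lon_col.
cell_id <- function(grid, lat_row, lon_col) (lat_row - 1L) * n_lon(grid) + lon_col
cell_rowcol <- function(grid, id) {
  id <- as.integer(id)
  cbind(row = (id - 1L) %/% n_lon(grid) + 1L, col = (id - 1L) %% n_lon(grid) + 1L)
}
cell_latlon <- function(grid, id) {
  rc <- cell_rowcol(grid, id)
  cbind(lat = grid$lat_centers[rc[, "row"]], lon = grid$lon_centers[rc[, "col"]])
}

#' Single-variable field on a grid
#'
#' Values are `NA` exactly on land for ocean-only variables; finite elsewhere.
#'
#' @param grid a [grid_spec()].
#' @param values numeric `nlat x nlon` matrix.
#' @param units free-text unit string.
#' @return object of class `gridded_field`.
#' @export
gridded_field <- function(grid, values, units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(n_lat(grid), n_lon(grid))))
    stop("values must match the grid (", n_lat(grid), " x ", n_lon(grid), ")")
  structure(list(grid = grid, values = values, units = units),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  v <- x$values[!x$grid$land_mask]
  cat(sprintf("<gridded_field> [%s] %d x %d; ocean range %.4g..%.4g\n",
              x$units, nrow(x$values), ncol(x$values),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Time-stacked annual-mean SST series
#'
#' @param grid a [grid_spec()].
#' @param years strictly increasing integer calendar axis with unit step
#'   (astronomical years: 1 B.C. is year 0, years B.P. are negative C.E.
#'   years relative to no fixed epoch -- the axis is continuous).
#' @param sst numeric array `nyears x nlat x nlon` (degrees C); `NA` on land.
#' @param era one of `"past"`, `"control"`, `"historical"`,
#'   `"future_scenario_A"`, `"future_scenario_B"`.
#' @return object of class `sst_series`.
#' @export
sst_series <- function(grid, years, sst,
                       era = c("past", "control", "historical",
                               "future_scenario_A", "future_scenario_B")) {
  era <- match.arg(era)
  stopifnot(inherits(grid, "grid_spec"))
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be strictly increasing with unit (annual) step")
  if (!is.array(sst) || length(dim(sst)) != 3L ||
      !all(dim(sst) == c(length(years), n_lat(grid), n_lon(grid))))
    stop("sst must be an array [years x nlat x nlon] matching grid and years")
  structure(list(grid = grid, years = years, sst = sst, era = era),
            class = "sst_series")
}

#' @export
print.sst_series <- function(x, ...) {
  cat(sprintf("<sst_series> era=%s, years %d..%d (%d), grid %d x %d\n",
              x$era, min(x$years), max(x$years), length(x$years),
              n_lat(x$grid), n_lon(x$grid)))
  invisible(x)
}

#' Area-weighted global mean over ocean cells
#'
#' Computes `sum(w_i v_i) / sum(w_i)` over ocean cells with non-missing
#' values, `w_i` the grid's cell-area weights.
#'
#' @param field a [gridded_field()].
#' @return scalar mean in the field's units.
#' @export
global_area_weighted_mean <- function(field) {
  stopifnot(inherits(field, "gridded_field"))
  ok <- !field$grid$land_mask & !is.na(field$values)
  if (!any(ok)) stop("no ocean cells")
  sum(field$grid$cell_area[ok] * field$values[ok]) / sum(field$grid$cell_area[ok])
}

# Area-weighted global ocean mean of each year of an sst_series; returns a
# numeric vector along years. Weights renormalised per year over non-missing
# ocean cells.
global_mean_series <- function(series) {
  stopifnot(inherits(series, "sst_series"))
  ocean <- which(!series$grid$land_mask)
  if (length(ocean) == 0) stop("no ocean cells")
  nt <- length(series$years)
  m <- matrix(series$sst, nrow = nt)[, ocean, drop = FALSE]
  w <- series$grid$cell_area[ocean]
  if (anyNA(m)) {
    apply(m, 1L, function(v) {
      ok <- !is.na(v)
      if (!any(ok)) stop("no ocean cells")
      sum(w[ok] * v[ok]) / sum(w[ok])
    })
  } else {
    as.numeric(m %*% w) / sum(w)
  }
}

#' Aggregate a fine field to a coarser nesting grid by block means
#'
#' Each coarse cell is the arithmetic mean of its non-missing fine children;
#' a coarse cell is missing iff all its children are missing. The coarse
#' resolution must be an integer multiple of the fine one so the grids nest
#' exactly.
#'
#' @param fine a [gridded_field()] on the fine grid.
#' @param coarse_spec the target [grid_spec()].
#' @return a [gridded_field()] on `coarse_spec`.
#' @export
aggregate_mean <- function(fine, coarse_spec) {
  stopifnot(inherits(fine, "gridded_field"), inherits(coarse_spec, "grid_spec"))
  f <- fine$grid$resolution_deg
  c_ <- coarse_spec$resolution_deg
  k <- c_ / f
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("grids do not nest: coarse resolution must be an integer multiple of fine")
  k <- as.integer(round(k))
  nlat_c <- n_lat(coarse_spec); nlon_c <- n_lon(coarse_spec)
  out <- matrix(NA_real_, nlat_c, nlon_c)
  v <- fine$values
  for (i in seq_len(nlat_c)) {
    rows <- ((i - 1L) * k + 1L):(i * k)
    for (j in seq_len(nlon_c)) {
      block <- v[rows, ((j - 1L) * k + 1L):(j * k)]
      if (any(!is.na(block))) out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  gridded_field(coarse_spec, out, units = fine$units)
}

# Upsample a coarse logical mask to a nesting fine grid (each fine child
# inherits its parent's value). Used to carry the land mask to the species grid.
refine_mask <- function(coarse_grid, fine_grid) {
  k <- coarse_grid$resolution_deg / fine_grid$resolution_deg
  if (abs(k - round(k)) > 1e-9 || k < 1) stop("grids do not nest")
  k <- as.integer(round(k))
  m <- coarse_grid$land_mask
  m[rep(seq_len(nrow(m)), each = k), rep(seq_len(ncol(m)), each = k)]
}

# Haversine great-circle distance in km between points given as (lat, lon)
# degree matrices/vectors; Earth radius fixed at 6371 km.
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  d2r <- pi / 180
  dlat <- (lat2 - lat1) * d2r / 2
  dlon <- (lon2 - lon1) * d2r / 2
  a <- sin(dlat)^2 + cos(lat1 * d2r) * cos(lat2 * d2r) * sin(dlon)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}
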