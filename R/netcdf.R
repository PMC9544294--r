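# Minimal NetCDF-3 (classic, CDF-1) reader/writer.
#
# Supports what this package writes: fixed (non-record) dimensions, coordinate
# variables lat/lon (+ time for series), NC_BYTE/NC_INT/NC_FLOAT/NC_DOUBLE/
# NC_CHAR data, per-variable `units` and `_FillValue` attributes and free-form
# global attributes. All multi-byte values are big-endian per the format;
# variable data are laid out in C order (last dimension fastest).

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L; NC_INT <- 4L
NC_FLOAT <- 5L; NC_DOUBLE <- 6L
NC_FILL_INT <- -2147483647L
NC_SIZES <- c(1L, 1L, 2L, 4L, 4L, 8L)

nc_pad4 <- function(r) {
  rem <- length(r) %% 4L
  if (rem) c(r, raw(4L - rem)) else r
}
nc_int <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")
nc_dbl <- function(x) writeBin(as.double(x), raw(), size = 8L, endian = "big")
nc_name <- function(s) {
  b <- charToRaw(s)
  c(nc_int(length(b)), nc_pad4(b))
}

nc_att_value <- function(v) {
  if (is.character(v)) {
    b <- charToRaw(v[1])
    c(nc_int(NC_CHAR), nc_int(length(b)), nc_pad4(b))
  } else if (is.integer(v)) {
    c(nc_int(NC_INT), nc_int(length(v)), nc_int(v))
  } else {
    c(nc_int(NC_DOUBLE), nc_int(length(v)), nc_dbl(v))
  }
}

nc_att_list <- function(atts) {
  if (length(atts) == 0) return(c(nc_int(0L), nc_int(0L)))
  out <- c(nc_int(12L), nc_int(length(atts)))
  for (nm in names(atts)) out <- c(out, nc_name(nm), nc_att_value(atts[[nm]]))
  out
}

# vars: list of list(name, dimids (0-based ints), type, atts, n_values)
nc_header <- function(dims, global_atts, vars, begins) {
  h <- c(charToRaw("CDF"), as.raw(1L), nc_int(0L))  # magic + numrecs = 0
  if (length(dims)) {
    h <- c(h, nc_int(10L), nc_int(length(dims)))
    for (nm in names(dims)) h <- c(h, nc_name(nm), nc_int(dims[[nm]]))
  } else h <- c(h, nc_int(0L), nc_int(0L))
  h <- c(h, nc_att_list(global_atts))
  if (length(vars)) {
    h <- c(h, nc_int(11L), nc_int(length(vars)))
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      vsize <- v$n_values * NC_SIZES[v$type]
      vsize <- as.integer(ceiling(vsize / 4) * 4)
      h <- c(h, nc_name(v$name), nc_int(length(v$dimids)), nc_int(v$dimids),
             nc_att_list(v$atts), nc_int(v$type), nc_int(vsize),
             nc_int(begins[i]))
    }
  } else h <- c(h, nc_int(0L), nc_int(0L))
  h
}

# vars here additionally carry $values: numeric/integer vector already in
# C (row-major) order.
nc_write_file <- function(path, dims, global_atts, vars) {
  meta <- lapply(vars, function(v) {
    v$n_values <- length(v$values)
    v
  })
  header_len <- length(nc_header(dims, global_atts, meta,
                                 begins = rep(0L, length(vars))))
  vsizes <- vapply(meta, function(v)
    as.integer(ceiling(v$n_values * NC_SIZES[v$type] / 4) * 4), integer(1))
  begins <- header_len + c(0L, cumsum(vsizes))[seq_along(vars)]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(nc_header(dims, global_atts, meta, begins), con)
  for (v in meta) {
    nbytes <- v$n_values * NC_SIZES[v$type]
    if (v$type == NC_DOUBLE) {
      writeBin(as.double(v$values), con, size = 8L, endian = "big")
    } else if (v$type == NC_FLOAT) {
      writeBin(as.double(v$values), con, size = 4L, endian = "big")
    } else if (v$type == NC_INT) {
      writeBin(as.integer(v$values), con, size = 4L, endian = "big")
    } else if (v$type == NC_BYTE) {
      writeBin(as.raw(as.integer(v$values)), con)
    } else if (v$type == NC_CHAR) {
      writeBin(charToRaw(paste(v$values, collapse = "")), con)
    } else stop("unsupported NetCDF type ", v$type)
    pad <- (4L - (nbytes %% 4L)) %% 4L
    if (pad) writeBin(raw(pad), con)
  }
  invisible(path)
}

# --- parsing ---------------------------------------------------------------

nc_cursor <- function(raw_bytes) {
  env <- new.env(parent = emptyenv())
  env$b <- raw_bytes; env$pos <- 1L
  env
}
nc_take <- function(cur, n) {
  if (cur$pos + n - 1L > length(cur$b)) stop("truncated NetCDF file")
  r <- cur$b[cur$pos:(cur$pos + n - 1L)]
  cur$pos <- cur$pos + as.integer(n)
  r
}
nc_read_int <- function(cur, n = 1L)
  readBin(nc_take(cur, 4L * n), "integer", n = n, size = 4L, endian = "big")
nc_read_name <- function(cur) {
  len <- nc_read_int(cur)
  s <- rawToChar(nc_take(cur, len))
  pad <- (4L - (len %% 4L)) %% 4L
  if (pad) nc_take(cur, pad)
  s
}
nc_read_values <- function(cur, type, n) {
  nbytes <- n * NC_SIZES[type]
  b <- nc_take(cur, nbytes)
  pad <- (4L - (nbytes %% 4L)) %% 4L
  if (pad) nc_take(cur, pad)
  switch(as.character(type),
         "1" = as.integer(b),
         "2" = rawToChar(b),
         "3" = readBin(b, "integer", n = n, size = 2L, signed = TRUE, endian = "big"),
         "4" = readBin(b, "integer", n = n, size = 4L, endian = "big"),
         "5" = readBin(b, "double", n = n, size = 4L, endian = "big"),
         "6" = readBin(b, "double", n = n, size = 8L, endian = "big"),
         stop("unsupported NetCDF type ", type))
}
nc_read_atts <- function(cur) {
  tag <- nc_read_int(cur); n <- nc_read_int(cur)
  if (tag == 0L && n == 0L) return(list())
  if (tag != 12L) stop("malformed attribute list (tag ", tag, ")")
  atts <- list()
  for (i in seq_len(n)) {
    nm <- nc_read_name(cur)
    type <- nc_read_int(cur); nv <- nc_read_int(cur)
    atts[[nm]] <- nc_read_values(cur, type, nv)
  }
  atts
}

nc_parse <- function(path) {
  b <- readBin(path, "raw", n = file.info(path)$size)
  if (length(b) < 8 || rawToChar(b[1:3]) != "CDF")
    stop("not a NetCDF classic file: ", path)
  version <- as.integer(b[4])
  if (version != 1L) stop("only NetCDF classic (CDF-1) is supported")
  cur <- nc_cursor(b)
  nc_take(cur, 4L)                      # magic
  numrecs <- nc_read_int(cur)
  tag <- nc_read_int(cur); ndims <- nc_read_int(cur)
  dims <- list()
  if (!(tag == 0L && ndims == 0L)) {
    if (tag != 10L) stop("malformed dimension list")
    for (i in seq_len(ndims)) {
      nm <- nc_read_name(cur); len <- nc_read_int(cur)
      if (len == 0L) stop("unlimited (record) dimensions are not supported")
      dims[[nm]] <- len
    }
  }
  global_atts <- nc_read_atts(cur)
  tag <- nc_read_int(cur); nvars <- nc_read_int(cur)
  vars <- list()
  if (!(tag == 0L && nvars == 0L)) {
    if (tag != 11L) stop("malformed variable list")
    for (i in seq_len(nvars)) {
      nm <- nc_read_name(cur)
      nd <- nc_read_int(cur)
      dimids <- if (nd > 0) nc_read_int(cur, nd) else integer(0)
      atts <- nc_read_atts(cur)
      type <- nc_read_int(cur)
      vsize <- nc_read_int(cur)
      begin <- nc_read_int(cur)
      vars[[nm]] <- list(name = nm, dimids = dimids, atts = atts,
                         type = type, begin = begin)
    }
  }
  dim_names <- names(dims)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dlens <- unlist(dims[v$dimids + 1L], use.names = FALSE)
    n <- if (length(dlens)) prod(dlens) else 1L
    cur2 <- nc_cursor(b); cur2$pos <- v$begin + 1L
    vals <- nc_read_values(cur2, v$type, n)
    if (length(dlens) > 1L && v$type != NC_CHAR) {
      # file is C order (last dim fastest); restore natural R order
      vals <- aperm(array(vals, dim = rev(dlens)), rev(seq_along(dlens)))
    }
    vars[[nm]]$values <- vals
    vars[[nm]]$dim_names <- dim_names[v$dimids + 1L]
  }
  list(dims = dims, global_atts = global_atts, vars = vars)
}

# --- public interface ------------------------------------------------------

# row-major (C order) flattening helpers
c_order_mat <- function(m) as.vector(t(m))
c_order_arr3 <- function(a) as.vector(aperm(a, c(3L, 2L, 1L)))

#' Write a gridded object to a NetCDF-3 classic file
#'
#' Writes CF-style dimension order `(time, lat, lon)`. An [sst_series()]
#' yields variables `time`, `lat`, `lon`, `sst` and `land_mask`, plus a
#' global `era` attribute. A [gridded_field()] (or a named list of fields on
#' one grid) yields one data variable per field. Integer-valued matrices are
#' stored as `NC_INT` (fill `-2147483647`), doubles as `NC_DOUBLE` with a
#' `NaN` fill value standing for missing (land) cells.
#'
#' @param x an [sst_series()], a [gridded_field()], or a named list of
#'   `gridded_field`s sharing a grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_netcdf <- function(x, path) {
  if (inherits(x, "sst_series")) {
    g <- x$grid
    dims <- list(time = length(x$years), lat = n_lat(g), lon = n_lon(g))
    vars <- list(
      list(name = "time", dimids = 0L, type = NC_INT,
           atts = list(units = "calendar year"), values = x$years),
      list(name = "lat", dimids = 1L, type = NC_DOUBLE,
           atts = list(units = "degrees_north"), values = g$lat_centers),
      list(name = "lon", dimids = 2L, type = NC_DOUBLE,
           atts = list(units = "degrees_east"), values = g$lon_centers),
      list(name = "sst", dimids = c(0L, 1L, 2L), type = NC_DOUBLE,
           atts = list(units = "degC", `_FillValue` = NaN),
           values = c_order_arr3(ifelse(is.na(x$sst), NaN, x$sst))),
      list(name = "land_mask", dimids = c(1L, 2L), type = NC_BYTE,
           atts = list(units = "1"), values = c_order_mat(g$land_mask * 1L)))
    nc_write_file(path, dims,
                  list(era = x$era, area_method = g$area_method), vars)
  } else {
    fields <- if (inherits(x, "gridded_field")) list(field = x) else x
    if (!length(fields) || is.null(names(fields)) || any(names(fields) == ""))
      stop("x must be a gridded_field or a named list of gridded_fields")
    g <- fields[[1]]$grid
    dims <- list(lat = n_lat(g), lon = n_lon(g))
    vars <- list(
      list(name = "lat", dimids = 0L, type = NC_DOUBLE,
           atts = list(units = "degrees_north"), values = g$lat_centers),
      list(name = "lon", dimids = 1L, type = NC_DOUBLE,
           atts = list(units = "degrees_east"), values = g$lon_centers),
      list(name = "land_mask", dimids = c(0L, 1L), type = NC_BYTE,
           atts = list(units = "1"), values = c_order_mat(g$land_mask * 1L)))
    for (nm in names(fields)) {
      f <- fields[[nm]]
      stopifnot(inherits(f, "gridded_field"))
      if (!isTRUE(all.equal(f$grid$lat_centers, g$lat_centers)))
        stop("all fields must share one grid")
      v <- f$values
      if (is.integer(v)) {
        vals <- ifelse(is.na(v), NC_FILL_INT, v)
        vars[[length(vars) + 1L]] <-
          list(name = nm, dimids = c(0L, 1L), type = NC_INT,
               atts = list(units = f$units, `_FillValue` = NC_FILL_INT),
               values = c_order_mat(vals))
      } else {
        vars[[length(vars) + 1L]] <-
          list(name = nm, dimids = c(0L, 1L), type = NC_DOUBLE,
               atts = list(units = f$units, `_FillValue` = NaN),
               values = c_order_mat(ifelse(is.na(v), NaN, v)))
      }
    }
    nc_write_file(path, dims, list(area_method = g$area_method), vars)
  }
  invisible(path)
}

#' Read a NetCDF-3 classic file written by this package
#'
#' Returns an [sst_series()] when the file holds an `sst` variable with a
#' time dimension and `era` attribute, otherwise a named list of
#' [gridded_field()]s. Files must carry `lat` and `lon` coordinate variables
#' on a global, centre-registered regular grid.
#'
#' @param path file path.
#' @return [sst_series()] or named list of [gridded_field()]s.
#' @export
read_netcdf <- function(path) {
  nc <- nc_parse(path)
  if (is.null(nc$vars[["lat"]]))
    stop("missing latitude coordinate variable 'lat' in ", path)
  if (is.null(nc$vars[["lon"]]))
    stop("missing longitude coordinate variable 'lon' in ", path)
  lat <- as.numeric(nc$vars[["lat"]]$values)
  res <- if (length(lat) > 1) lat[2] - lat[1] else 180
  area_method <- nc$global_atts[["area_method"]]
  if (is.null(area_method)) area_method <- "coslat"
  lm <- nc$vars[["land_mask"]]
  land <- if (is.null(lm)) NULL else lm$values != 0L
  grid <- grid_spec(res, land_mask = land, area_method = area_method)
  if (max(abs(grid$lat_centers - lat)) > 1e-6)
    stop("latitude axis is not a global centre-registered regular grid")
  coord_names <- c("time", "lat", "lon", "land_mask")
  if (!is.null(nc$vars[["sst"]]) && "time" %in% names(nc$dims)) {
    era <- nc$global_atts[["era"]]
    if (is.null(era)) stop("sst file lacks global attribute 'era'")
    sst <- nc$vars[["sst"]]$values
    sst[is.nan(sst)] <- NA_real_
    return(sst_series(grid, as.integer(nc$vars[["time"]]$values), sst, era))
  }
  out <- list()
  for (nm in setdiff(names(nc$vars), coord_names)) {
    v <- nc$vars[[nm]]
    vals <- v$values
    fill <- v$atts[["_FillValue"]]
    if (is.double(vals)) vals[is.nan(vals)] <- NA_real_
    if (is.integer(vals) && !is.null(fill)) vals[vals == fill] <- NA_integer_
    units <- v$atts[["units"]]
    out[[nm]] <- gridded_field(grid, matrix(vals, length(lat)),
                               units = if (is.null(units)) "" else units)
  }
  out
}
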