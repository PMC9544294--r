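#' Species richness from occurrence probabilities
#'
#' Presence of species `s` in a cell is `p_s >= tau` (inclusive); richness is
#' the number of present species. Species flagged data-scarce are excluded
#' before counting.
#'
#' @param species output of [generate_species()], or a list with `grid`,
#'   `probs` (array `nlat x nlon x n_species`) and optional `data_scarce`.
#' @param tau occurrence-probability threshold in `[0, 1]`.
#' @return a [gridded_field()] of integer richness (class also
#'   `richness_raster`), with the threshold recorded in `attr(,"tau")`.
#' @export
richness_from_probs <- function(species, tau = 0.4) {
  probs <- species$probs
  stopifnot(length(dim(probs)) == 3L)
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  rng <- range(probs, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("occurrence probabilities must lie in [0, 1]")
  keep <- if (is.null(species$data_scarce)) seq_len(dim(probs)[3]) else
    which(!species$data_scarce)
  counts <- apply(probs[, , keep, drop = FALSE] >= tau, c(1, 2),
                  sum, na.rm = TRUE)
  counts[species$grid$land_mask] <- NA_integer_
  storage.mode(counts) <- "integer"
  out <- gridded_field(species$grid, counts, units = "species count")
  class(out) <- c("richness_raster", class(out))
  attr(out, "tau") <- tau
  out
}

#' Hotspot mask at the climate resolution
#'
#' A (coarse) cell is a hotspot iff its aggregated richness is at or above
#' the stated percentile of richness over all ocean cells
#' (linear-interpolation percentile, inclusive).
#'
#' @param richness_coarse a [gridded_field()] of richness already aggregated
#'   to the climate grid with [aggregate_mean()].
#' @param percentile percentile of global ocean values, default 95.
#' @return logical `nlat x nlon` matrix (class `hotspot_mask`), `FALSE` on
#'   land; the cutoff value in `attr(,"cutoff")`.
#' @export
hotspot_mask <- function(richness_coarse, percentile = 95) {
  stopifnot(inherits(richness_coarse, "gridded_field"))
  g <- richness_coarse$grid
  vals <- richness_coarse$values[!g$land_mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no ocean cells with richness values")
  cutoff <- as.numeric(stats::quantile(vals, percentile / 100, type = 7,
                                       names = FALSE))
  mask <- !g$land_mask & !is.na(richness_coarse$values) &
    richness_coarse$values >= cutoff
  structure(mask, class = c("hotspot_mask", class(mask)),
            cutoff = cutoff, percentile = percentile)
}

#' Warren's I similarity between two spatial surfaces
#'
#' Normalises each raster to sum 1 over the shared non-missing cells (p, q)
#' and returns `I = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)`, in `[0, 1]`, with
#' 1 iff the normalised surfaces are identical.
#'
#' @param r1,r2 [gridded_field()]s (or numeric matrices/vectors) on the same
#'   grid.
#' @return scalar in `[0, 1]`.
#' @export
warren_i <- function(r1, r2) {
  v1 <- if (inherits(r1, "gridded_field")) r1$values else r1
  v2 <- if (inherits(r2, "gridded_field")) r2$values else r2
  if (length(v1) != length(v2)) stop("rasters must share a grid")
  ok <- !is.na(v1) & !is.na(v2)
  p <- as.numeric(v1[ok]); q <- as.numeric(v2[ok])
  if (sum(p) <= 0 || sum(q) <= 0) stop("zero-sum raster")
  p <- p / sum(p); q <- q / sum(q)
  i <- 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)
  min(1, max(0, i))
}

#' Sensitivity of richness to the occurrence-probability threshold
#'
#' Recomputes richness at each alternative threshold and reports Warren's I
#' against the reference-threshold map.
#'
#' @param species as for [richness_from_probs()].
#' @param taus thresholds to compare.
#' @param reference_tau the reference threshold (default 0.4).
#' @return data frame `tau_a` (reference), `tau_b`, `I`.
#' @export
threshold_sensitivity <- function(species, taus = seq(0, 0.5, by = 0.1),
                                  reference_tau = 0.4) {
  ref <- richness_from_probs(species, reference_tau)
  data.frame(
    tau_a = reference_tau,
    tau_b = taus,
    I = vapply(taus, function(tb)
      warren_i(ref, richness_from_probs(species, tb)), numeric(1)))
}
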