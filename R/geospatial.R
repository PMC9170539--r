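#' Binarize a suitability map at a cutoff
#'
#' Cell = 1 iff suitability >= cutoff (ties count as suitable, the same
#' convention as [confusion_at()]); nodata propagates.
#'
#' @param suitability Continuous [raster_layer()] in `[0, 1]`.
#' @param cutoff Threshold in `[0, 1]`.
#' @return A binary [raster_layer()] named `"binary_suitability"`.
#' @export
binarize <- function(suitability, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  v <- ifelse(suitability$values >= cutoff, 1, 0)
  v[!is.finite(suitability$values)] <- NA_real_
  raster_layer(suitability$grid, v, name = "binary_suitability")
}

#' Spherical cell-area layer
#'
#' The area of each grid cell on a sphere of radius `earth_radius_km`:
#' `R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))` with `d_lambda` the
#' cell width in radians.  Constant along a row, shrinking toward the poles
#' with the cosine of latitude.  A spherical (not ellipsoidal) Earth with
#' R = 6371 km is used; at the three-significant-figure precision of
#' million-km2 summaries the ellipsoidal refinement is immaterial.
#'
#' @param grid A [grid_spec()].
#' @param earth_radius_km Sphere radius (default 6371).
#' @return A [raster_layer()] named `"cell_area"`, km2.
#' @export
cell_area_layer <- function(grid, earth_radius_km = 6371) {
  d_lambda <- grid$cell_size * pi / 180
  lat_top <- grid$lat_origin - (seq_len(grid$n_rows) - 1) * grid$cell_size
  lat_bot <- lat_top - grid$cell_size
  band <- earth_radius_km^2 * d_lambda *
    (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  v <- matrix(band, nrow = grid$n_rows, ncol = grid$n_cols)
  raster_layer(grid, v, name = "cell_area", units = "km2")
}

#' Total suitable area in million km2
#'
#' Sums the cell areas over cells flagged 1 in the binary map (and, if a
#' region mask is given, also flagged 1 in the mask), reported in 10^6 km2.
#'
#' @param binary Binary [raster_layer()] (1 = suitable).
#' @param areas Cell-area [raster_layer()] from [cell_area_layer()]; computed
#'   from the binary map's grid if omitted.
#' @param mask Optional binary region-mask [raster_layer()] on the same grid.
#' @return Suitable area, million km2.
#' @export
suitable_area <- function(binary, areas = NULL, mask = NULL) {
  if (is.null(areas)) areas <- cell_area_layer(binary$grid)
  stop_if_grid_mismatch(binary$grid, areas$grid)
  sel <- is.finite(binary$values) & binary$values == 1
  if (!is.null(mask)) {
    stop_if_grid_mismatch(binary$grid, mask$grid)
    sel <- sel & is.finite(mask$values) & mask$values == 1
  }
  sum(areas$values[sel]) / 1e6
}

#' Deviation of one scenario's suitability from a baseline
#'
#' Per-cell signed difference `scenario - baseline` of two continuous
#' suitability maps, in `[-1, 1]`: positive where the scenario predicts
#' higher suitability than the baseline.
#'
#' @param scenario,baseline Continuous suitability [raster_layer()]s on one
#'   grid.
#' @return A signed [raster_layer()] named `"deviation"`.
#' @export
deviation_map <- function(scenario, baseline) {
  stop_if_grid_mismatch(scenario$grid, baseline$grid)
  v <- scenario$values - baseline$values
  raster_layer(scenario$grid, v, name = "deviation")
}

#' Gain/loss/stable comparison of two binary maps
#'
#' Optional categorical variant of [deviation_map()] for binary maps:
#' +1 = gained (scenario suitable, baseline not), -1 = lost, 0 = unchanged.
#'
#' @param scenario,baseline Binary [raster_layer()]s on one grid.
#' @return A [raster_layer()] named `"binary_change"` with values -1/0/+1.
#' @export
binary_change_map <- function(scenario, baseline) {
  stop_if_grid_mismatch(scenario$grid, baseline$grid)
  v <- scenario$values - baseline$values
  raster_layer(scenario$grid, v, name = "binary_change")
}
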