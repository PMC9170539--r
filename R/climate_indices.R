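#' Multi-year monthly precipitation on a grid
#'
#' Container for a monthly precipitation record (mm/month) over a contiguous
#' run of calendar years.  A year is "complete" at a cell iff all 12 months
#' are valid there; the derived-index functions use complete years only,
#' dropped per cell rather than globally so coverage is preserved at the edge
#' of the record.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric array `n_rows x n_cols x 12 x n_years`, `NA` = nodata.
#' @param years Integer vector of calendar years (contiguous, increasing).
#' @return An object of class `monthly_precip_series`.
#' @export
monthly_precip_series <- function(grid, values, years) {
  stopifnot(inherits(grid, "grid_spec"))
  years <- as.integer(years)
  if (length(years) < 1L) stop("empty series")
  if (length(years) > 1L && !all(diff(years) == 1L))
    stop("years must form a contiguous increasing range")
  d <- dim(values)
  if (length(d) != 4L || d[1] != grid$n_rows || d[2] != grid$n_cols ||
      d[3] != 12L || d[4] != length(years))
    stop("values must be an n_rows x n_cols x 12 x n_years array")
  if (any(values < 0, na.rm = TRUE)) stop("precipitation must be >= 0")
  structure(list(grid = grid, values = values, years = years),
            class = "monthly_precip_series")
}

#' Annual precipitation totals and the mean-annual layer
#'
#' Sums each calendar year's 12 months per cell.  Only complete years (all 12
#' months valid) contribute; an incomplete year is nodata at that cell, and a
#' cell with no complete year at all is nodata in every output.
#'
#' @param series A [monthly_precip_series()].
#' @return A list of class `annual_totals`: `per_year` (named list of
#'   [raster_layer()], one per year), `mean_annual` (layer, mean over complete
#'   years), `n_complete` (layer, complete-year count), `totals` (the raw
#'   `n_rows x n_cols x n_years` array), `years`.
#' @export
annual_totals <- function(series) {
  stopifnot(inherits(series, "monthly_precip_series"))
  g <- series$grid
  ny <- length(series$years)
  totals <- array(NA_real_, c(g$n_rows, g$n_cols, ny))
  for (y in seq_len(ny)) {
    yr <- series$values[, , , y, drop = FALSE]
    dim(yr) <- c(g$n_rows, g$n_cols, 12L)
    complete <- apply(is.finite(yr), c(1, 2), all)
    s <- apply(yr, c(1, 2), sum)
    s[!complete] <- NA_real_
    totals[, , y] <- s
  }
  n_complete <- apply(is.finite(totals), c(1, 2), sum)
  if (all(n_complete == 0)) stop("no cell has a complete year")
  mean_annual <- apply(totals, c(1, 2), mean, na.rm = TRUE)
  mean_annual[n_complete == 0] <- NA_real_
  per_year <- lapply(seq_len(ny), function(y)
    raster_layer(g, matrix(totals[, , y], g$n_rows, g$n_cols),
                 name = sprintf("annual_precip_%d",
                                                  series$years[y]),
                 units = "mm/yr"))
  names(per_year) <- as.character(series$years)
  structure(list(per_year = per_year,
                 mean_annual = raster_layer(g, mean_annual,
                                            name = "mean_annual_precip",
                                            units = "mm/yr"),
                 n_complete = raster_layer(g, n_complete,
                                           name = "n_complete_years"),
                 totals = totals, years = series$years),
            class = "annual_totals")
}

#' Hellmann-Eberle quotient of inter-annual rainfall variability
#'
#' Per cell, the ratio between the precipitation of the wettest and of the
#' driest complete year: `Q = max(totals) / min(totals)`.  `Q >= 1` wherever
#' defined and equals 1 only when all complete-year totals are equal.  Cells
#' with fewer than two complete years are nodata; so is a cell whose driest
#' year recorded exactly zero rain (the ratio map must stay finite for
#' downstream learners, and an all-dry year is indistinguishable from a data
#' gap at this resolution), hence the quotient is masked there rather than
#' set to infinity.
#'
#' @param at An [annual_totals()] result (or a [monthly_precip_series()],
#'   which is aggregated first).
#' @return A dimensionless [raster_layer()] named `"hellmann_eberle"`.
#' @export
hellmann_eberle <- function(at) {
  if (inherits(at, "monthly_precip_series")) at <- annual_totals(at)
  stopifnot(inherits(at, "annual_totals"))
  mx <- apply(at$totals, c(1, 2), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) return(NA_real_)
    if (min(v) <= 0) return(NA_real_)
    max(v) / min(v)
  })
  raster_layer(at$mean_annual$grid, mx, name = "hellmann_eberle",
               units = "dimensionless")
}

#' Thresholds for the Ellenberg low-and-unpredictable-rainfall flag
#'
#' @param p_threshold Mean annual precipitation threshold, mm/yr (default 500).
#' @param q_threshold Hellmann-Eberle quotient threshold (default 5).
#' @return An object of class `ellenberg_params`.
#' @export
ellenberg_params <- function(p_threshold = 500, q_threshold = 5) {
  stopifnot(p_threshold > 0, q_threshold > 0)
  structure(list(p_threshold = p_threshold, q_threshold = q_threshold),
            class = "ellenberg_params")
}

#' Ellenberg index map
#'
#' Binary flag marking regions where low mean annual rainfall coincides with
#' unpredictable rainfall: cell = 1 iff `mean_annual < p_threshold` AND
#' `quotient > q_threshold`, else 0; nodata in either input is nodata.
#'
#' @param mean_annual Mean annual precipitation [raster_layer()], mm/yr.
#' @param quotient Hellmann-Eberle quotient [raster_layer()].
#' @param params An [ellenberg_params()].
#' @return A binary [raster_layer()] named `"ellenberg_index"`.
#' @export
ellenberg_index <- function(mean_annual, quotient,
                            params = ellenberg_params()) {
  stop_if_grid_mismatch(mean_annual$grid, quotient$grid)
  v <- ifelse(mean_annual$values < params$p_threshold &
                quotient$values > params$q_threshold, 1, 0)
  v[!is.finite(mean_annual$values) | !is.finite(quotient$values)] <- NA_real_
  raster_layer(mean_annual$grid, v, name = "ellenberg_index")
}

#' Aridity index: annual precipitation over potential evapotranspiration
#'
#' `AI = P / PET`; cells where PET is not strictly positive are nodata.
#'
#' @param annual_precip Annual precipitation [raster_layer()], mm/yr.
#' @param pet Potential evapotranspiration [raster_layer()], same units.
#' @return A dimensionless [raster_layer()] named `"aridity_index"`.
#' @export
aridity_index <- function(annual_precip, pet) {
  stop_if_grid_mismatch(annual_precip$grid, pet$grid)
  v <- annual_precip$values / pet$values
  v[!is.finite(pet$values) | pet$values <= 0] <- NA_real_
  raster_layer(annual_precip$grid, v, name = "aridity_index",
               units = "dimensionless")
}

#' R-index: actual over potential evapotranspiration
#'
#' `R = AET / PET`, water supply relative to atmospheric demand.  Values are
#' not clamped; `AET > PET` raises a warning (physically suspect input) but
#' passes through.
#'
#' @param aet Actual evapotranspiration [raster_layer()].
#' @param pet Potential evapotranspiration [raster_layer()], same units.
#' @return A dimensionless [raster_layer()] named `"r_index"`.
#' @export
r_index <- function(aet, pet) {
  stop_if_grid_mismatch(aet$grid, pet$grid)
  v <- aet$values / pet$values
  v[!is.finite(pet$values) | pet$values <= 0 | !is.finite(aet$values)] <-
    NA_real_
  if (any(v > 1, na.rm = TRUE))
    warning("AET exceeds PET at ", sum(v > 1, na.rm = TRUE), " cell(s)")
  raster_layer(aet$grid, v, name = "r_index", units = "dimensionless")
}
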