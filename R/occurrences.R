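#' Create a set of occurrence records
#'
#' @param records Data.frame with columns `record_id`, `lon`, `lat` (decimal
#'   degrees WGS84).  `record_id` defaults to the row number.
#' @param species_label Species name carried through the pipeline.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, species_label = "species") {
  records <- as.data.frame(records)
  if (is.null(records$record_id)) records$record_id <- seq_len(nrow(records))
  stopifnot(all(c("record_id", "lon", "lat") %in% names(records)))
  if (anyDuplicated(records$record_id)) stop("duplicated record_id")
  structure(list(records = records[c("record_id", "lon", "lat")],
                 species_label = species_label),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> '%s': %d records\n",
              x$species_label, nrow(x$records)))
  invisible(x)
}

#' Read occurrences from CSV
#'
#' Accepts plain `lon`/`lat` columns or the Darwin Core names
#' `decimalLongitude`/`decimalLatitude` (and `species` for the label).
#'
#' @param path CSV path.
#' @param species_label Label override; default taken from a `species` column
#'   if present.
#' @return An [occurrence_set()].
#' @export
read_occurrences_csv <- function(path, species_label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lon <- if ("lon" %in% names(df)) df$lon else df$decimalLongitude
  lat <- if ("lat" %in% names(df)) df$lat else df$decimalLatitude
  if (is.null(lon) || is.null(lat))
    stop("CSV must contain lon/lat or decimalLongitude/decimalLatitude")
  if (is.null(species_label))
    species_label <- if ("species" %in% names(df) && nrow(df))
      df$species[1] else "species"
  id <- if ("record_id" %in% names(df)) df$record_id else seq_len(nrow(df))
  occurrence_set(data.frame(record_id = id, lon = lon, lat = lat),
                 species_label)
}

#' Write occurrences to CSV
#' @param occ An [occurrence_set()].
#' @param path Output path.
#' @export
write_occurrences_csv <- function(occ, path) {
  df <- occ$records
  df$species <- occ$species_label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Basic occurrence cleaning
#'
#' A reduced, documented validity filter: drops records with missing or
#' non-finite coordinates, coordinates outside valid lon/lat ranges, the
#' exact `(0, 0)` sentinel point, and exact coordinate duplicates beyond
#' `max_dup_coords` records (keeping the lowest `record_id`s).  Deterministic.
#' Full location-based cleaning (institution coordinates, country centroids,
#' sea tests) is intentionally out of scope.
#'
#' @param occ An [occurrence_set()].
#' @param max_dup_coords Maximum records allowed at one exact coordinate.
#' @return A cleaned [occurrence_set()].
#' @export
basic_clean <- function(occ, max_dup_coords = 1L) {
  stopifnot(inherits(occ, "occurrence_set"), max_dup_coords >= 1L)
  r <- occ$records
  keep <- is.finite(r$lon) & is.finite(r$lat) &
    r$lon >= -180 & r$lon < 180 & r$lat >= -90 & r$lat <= 90 &
    !(r$lon == 0 & r$lat == 0)
  r <- r[keep, , drop = FALSE]
  if (nrow(r)) {
    r <- r[order(r$record_id), , drop = FALSE]
    key <- paste(r$lon, r$lat)
    rank_in_key <- stats::ave(seq_len(nrow(r)), key, FUN = seq_along)
    r <- r[rank_in_key <= max_dup_coords, , drop = FALSE]
  }
  if (!nrow(r)) warning("no records remain after cleaning")
  occurrence_set(r, occ$species_label)
}

#' Thin occurrences to at most a few records per grid cell
#'
#' Geographic sampling filter against collection bias: every `cell_size` x
#' `cell_size` degree cell (lattice anchored at integer degrees) retains at
#' most `max_per_cell` records.  Cells at or below the cap are untouched;
#' over-full cells are thinned by uniform random selection under `seed`, so
#' the result is reproducible and free of source-ordering bias.  Thinning an
#' already-thinned set is a no-op, and output records are always a subset of
#' the input in their original order.
#'
#' @param occ An [occurrence_set()].
#' @param cell_size Thinning cell edge, degrees (default 1).
#' @param max_per_cell Cap per cell (default 5).
#' @param seed Integer seed for the within-cell selection.
#' @return A thinned [occurrence_set()].
#' @export
thin_per_cell <- function(occ, cell_size = 1.0, max_per_cell = 5L, seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"), max_per_cell >= 1L,
            cell_size > 0)
  r <- occ$records
  if (!nrow(r)) return(occ)
  cell <- paste(floor(r$lon / cell_size), floor(r$lat / cell_size))
  keep <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(r)), cell), function(idx) {
      if (length(idx) <= max_per_cell) idx
      else sort(sample(idx, max_per_cell))
    }), use.names = FALSE)
  })
  occurrence_set(r[sort(keep), , drop = FALSE], occ$species_label)
}

#' Extract predictor values at points
#'
#' Reads the value of the cell containing each point from every layer (no
#' interpolation; a point exactly on a shared edge is assigned by the
#' half-open convention, see [cell_of()]).  Points outside the grid or on any
#' nodata cell are dropped and counted.
#'
#' @param points An [occurrence_set()] or data.frame with `lon`, `lat`.
#' @param stack A [raster_stack()].
#' @return A list: `table` (data.frame `lon`, `lat`, one column per layer)
#'   and `n_dropped`.
#' @export
extract_predictors <- function(points, stack) {
  if (inherits(points, "occurrence_set")) points <- points$records
  stopifnot(all(c("lon", "lat") %in% names(points)))
  cc <- cell_of(stack$grid, points$lon, points$lat)
  ok <- !is.na(cc$row)
  vals <- matrix(NA_real_, nrow(points), length(stack$layers),
                 dimnames = list(NULL, stack_names(stack)))
  if (any(ok))
    vals[ok, ] <- stack_values_at(stack, cc$row[ok], cc$col[ok])
  ok <- ok & apply(is.finite(vals), 1, all)
  if (!any(ok)) stop("all points fall outside the stack or on nodata cells")
  tab <- data.frame(lon = points$lon[ok], lat = points$lat[ok])
  tab <- cbind(tab, as.data.frame(vals[ok, , drop = FALSE]))
  list(table = tab, n_dropped = sum(!ok))
}
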