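#' Define a regular lon/lat grid
#'
#' All rasters in the package live on a `grid_spec`: a regular grid of square
#' cells in WGS84 decimal degrees, with cell (1, 1) in the north-west corner.
#' Cells are half-open `[edge, edge + cell_size)`: a point exactly on a shared
#' edge belongs to the cell to its south/east, so every point maps to exactly
#' one cell.
#'
#' @param n_rows,n_cols Grid dimensions (rows run north to south).
#' @param lon_origin Longitude of the west edge, degrees in `[-180, 180)`.
#' @param lat_origin Latitude of the north edge, degrees.
#' @param cell_size Cell edge length in degrees (> 0, square cells).
#' @param nodata Sentinel used when writing files; in memory nodata is `NA`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, lon_origin, lat_origin, cell_size,
                      nodata = -9999) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(is.finite(cell_size), length(cell_size) == 1L)
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (lon_origin < -180 || lon_origin >= 180)
    stop("lon_origin must lie in [-180, 180)")
  if (lat_origin - n_rows * cell_size < -90 - 1e-9)
    stop("grid extends south of -90 degrees latitude")
  if (lat_origin > 90 + 1e-9) stop("lat_origin must be <= 90")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         lon_origin = as.numeric(lon_origin),
         lat_origin = as.numeric(lat_origin),
         cell_size = as.numeric(cell_size),
         nodata = as.numeric(nodata)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g deg, NW corner (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$lon_origin, x$lat_origin))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lon_origin - b$lon_origin) < tol &&
    abs(a$lat_origin - b$lat_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grid_equal(a, b)) stop("layers are not on the same grid")
  invisible(TRUE)
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return `cell_center_lons`/`cell_center_lats`: numeric vectors of the
#'   column-center longitudes / row-center latitudes (row 1 is northernmost).
#' @export
cell_center_lons <- function(grid) {
  grid$lon_origin + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' @rdname cell_center_lons
#' @export
cell_center_lats <- function(grid) {
  grid$lat_origin - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

#' Map points to grid cells
#'
#' Uses the half-open convention: `col = floor((lon - lon_origin)/cell_size) + 1`
#' and `row = floor((lat_origin - lat)/cell_size) + 1`, so a point on a shared
#' south or east edge belongs to the next cell.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Point coordinates, degrees.
#' @return A data.frame with integer columns `row`, `col`; `NA` for points
#'   outside the grid extent.
#' @export
cell_of <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_origin) / grid$cell_size) + 1
  row <- floor((grid$lat_origin - lat) / grid$cell_size) + 1
  outside <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    !is.finite(lon) | !is.finite(lat)
  col[outside] <- NA_integer_
  row[outside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Create a raster layer
#'
#' A named 2-D field on a [grid_spec()].  Nodata cells are `NA` in memory and
#' propagate through all arithmetic; they are never silently imputed.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = north), `NA` = nodata.
#' @param name Predictor label (e.g. `"annual_precip"`).
#' @param units Free-text units.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, name = "layer", units = "") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values shape does not match grid")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values,
                 name = as.character(name), units = as.character(units)),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_layer> '%s' %d x %d, %d valid cells, range [%.4g, %.4g]\n",
              x$name, x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Bundle layers sharing one grid into a stack
#'
#' @param layers List of [raster_layer()] objects on a common grid; names are
#'   taken from each layer's `name` field and must be unique.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  if (inherits(layers, "raster_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L)
  grid <- layers[[1L]]$grid
  for (l in layers) {
    stopifnot(inherits(l, "raster_layer"))
    stop_if_grid_mismatch(grid, l$grid)
  }
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop("layer names must be unique")
  names(layers) <- nms
  structure(list(grid = grid, layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
`[[.raster_stack` <- function(x, i) x$layers[[i]]

stack_names <- function(stack) names(stack$layers)

subset_stack <- function(stack, names) {
  missing <- setdiff(names, stack_names(stack))
  if (length(missing))
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "))
  raster_stack(stack$layers[names])
}

#' Valid-data mask of a stack
#'
#' A cell is valid only where every layer is valid: the stack nodata mask is
#' the union of the per-layer nodata masks.
#'
#' @param stack A [raster_stack()].
#' @return Logical matrix, `TRUE` where all layers have data.
#' @export
stack_valid_mask <- function(stack) {
  m <- matrix(TRUE, stack$grid$n_rows, stack$grid$n_cols)
  for (l in stack$layers) m <- m & is.finite(l$values)
  m
}

# values of every layer at (row, col) index pairs; matrix cells x layers
stack_values_at <- function(stack, row, col) {
  idx <- cbind(row, col)
  out <- vapply(stack$layers, function(l) l$values[idx],
                numeric(length(row)))
  if (length(row) == 1L) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, stack_names(stack)))
  colnames(out) <- stack_names(stack)
  out
}

#' Resample a layer onto a target grid
#'
#' Bilinear interpolation between the four surrounding source cell centers
#' (for continuous fields) or nearest-cell lookup (for categorical/binary
#' fields).  Bilinear weights are renormalized over valid neighbours; a target
#' cell whose entire interpolation support is nodata becomes nodata.  Values
#' outside the source cell-center hull are taken from the clamped border, so
#' bilinear output never leaves the `[min, max]` range of the source.
#'
#' @param layer Source [raster_layer()].
#' @param target Target [grid_spec()]; must overlap the source extent.
#' @param method `"bilinear"` or `"nearest"`.
#' @return A [raster_layer()] on `target`.
#' @export
resample_to <- function(layer, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  src <- layer$grid
  # spatial overlap of the two extents
  lon_lo <- max(src$lon_origin, target$lon_origin)
  lon_hi <- min(src$lon_origin + src$n_cols * src$cell_size,
                target$lon_origin + target$n_cols * target$cell_size)
  lat_hi <- min(src$lat_origin, target$lat_origin)
  lat_lo <- max(src$lat_origin - src$n_rows * src$cell_size,
                target$lat_origin - target$n_rows * target$cell_size)
  if (lon_lo >= lon_hi || lat_lo >= lat_hi)
    stop("source and target grids do not overlap spatially")
  if (grid_equal(src, target))
    return(raster_layer(target, layer$values, layer$name, layer$units))

  tl_lon <- cell_center_lons(target)
  tl_lat <- cell_center_lats(target)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)

  if (method == "nearest") {
    cc <- cell_of(src, rep(tl_lon, each = target$n_rows),
                  rep(tl_lat, times = target$n_cols))
    ok <- !is.na(cc$row)
    vals <- rep(NA_real_, nrow(cc))
    vals[ok] <- layer$values[cbind(cc$row[ok], cc$col[ok])]
    out[] <- vals
  } else {
    # fractional position in source cell-center coordinates, clamped to border
    fx <- (rep(tl_lon, each = target$n_rows) -
             (src$lon_origin + 0.5 * src$cell_size)) / src$cell_size + 1
    fy <- ((src$lat_origin - 0.5 * src$cell_size) -
             rep(tl_lat, times = target$n_cols)) / src$cell_size + 1
    fx <- pmin(pmax(fx, 1), src$n_cols)
    fy <- pmin(pmax(fy, 1), src$n_rows)
    x0 <- pmin(floor(fx), src$n_cols - 1L); x0[src$n_cols == 1L] <- 1L
    y0 <- pmin(floor(fy), src$n_rows - 1L); y0[src$n_rows == 1L] <- 1L
    x1 <- pmin(x0 + 1L, src$n_cols)
    y1 <- pmin(y0 + 1L, src$n_rows)
    wx <- fx - x0
    wy <- fy - y0
    v00 <- layer$values[cbind(y0, x0)]
    v01 <- layer$values[cbind(y0, x1)]
    v10 <- layer$values[cbind(y1, x0)]
    v11 <- layer$values[cbind(y1, x1)]
    w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx
    w10 <- wy * (1 - wx);       w11 <- wy * wx
    num <- den <- numeric(length(fx))
    for (p in list(list(v00, w00), list(v01, w01),
                   list(v10, w10), list(v11, w11))) {
      ok <- is.finite(p[[1]])
      num[ok] <- num[ok] + p[[1]][ok] * p[[2]][ok]
      den[ok] <- den[ok] + p[[2]][ok]
    }
    vals <- ifelse(den > 0, num / den, NA_real_)
    out[] <- vals
  }
  raster_layer(target, out, layer$name, layer$units)
}

#' Pairwise Pearson collinearity screen
#'
#' Computes the Pearson correlation between every pair of layers over cells
#' valid in all layers, and flags pairs at or above `threshold` in absolute
#' value.  Purely advisory: nothing is dropped — which predictors to keep is a
#' configuration decision.
#'
#' @param stack A [raster_stack()] with at least two layers.
#' @param threshold Flagging threshold on `|r|`, in `(0, 1]`.
#' @return A list with `r` (symmetric correlation matrix) and `pairs`
#'   (data.frame: `var1`, `var2`, `r`, `flagged`, one row per unordered pair).
#' @export
collinearity_screen <- function(stack, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(stack$layers) < 2L) stop("need at least two layers")
  mask <- stack_valid_mask(stack)
  if (sum(mask) < 2L) stop("fewer than 2 cells valid in all layers")
  m <- vapply(stack$layers, function(l) l$values[mask], numeric(sum(mask)))
  r <- stats::cor(m)
  nm <- stack_names(stack)
  pr <- t(utils::combn(seq_along(nm), 2))
  pairs <- data.frame(var1 = nm[pr[, 1]], var2 = nm[pr[, 2]],
                      r = r[pr], stringsAsFactors = FALSE)
  pairs$flagged <- abs(pairs$r) >= threshold
  list(r = r, pairs = pairs)
}
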