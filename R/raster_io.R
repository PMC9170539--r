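#' Read and write rasters as ESRI ASCII grids
#'
#' The package exchanges single-layer rasters in the ESRI ASCII grid format
#' (`.asc`): a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values from north to south.
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces a layer bit-exactly, including its grid metadata.
#'
#' @param layer A [raster_layer()].
#' @param path File path (conventionally `.asc`).
#' @param name,units Metadata for the layer created on read (the format itself
#'   carries no layer name).
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_layer()].
#' @export
write_ascii_grid <- function(layer, path) {
  g <- layer$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.17g", g$lon_origin),
    sprintf("yllcorner %.17g", g$lat_origin - g$n_rows * g$cell_size),
    sprintf("cellsize %.17g", g$cell_size),
    sprintf("NODATA_value %.17g", g$nodata)), con)
  v <- layer$values
  v[!is.finite(v)] <- g$nodata
  for (i in seq_len(g$n_rows))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, name = NULL, units = "") {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header: missing ", k)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  grid <- grid_spec(hdr$nrows, hdr$ncols,
                    lon_origin = hdr$xllcorner,
                    lat_origin = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    cell_size = hdr$cellsize, nodata = nodata)
  body <- paste(lines[-(1:6)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != grid$n_rows * grid$n_cols)
    stop("ASCII grid body has wrong number of values")
  m <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  raster_layer(grid, m, name = name, units = units)
}

#' Read a raster stack from a manifest
#'
#' The manifest is a two-column CSV (`name`, `path`) listing one ASCII-grid
#' file per layer; relative paths are resolved against the manifest's
#' directory.  All layers must share one grid.
#'
#' @param path Manifest CSV path.
#' @return A [raster_stack()].
#' @export
read_stack_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "path") %in% names(man)))
  base <- dirname(path)
  layers <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    read_ascii_grid(p, name = man$name[i])
  })
  raster_stack(layers)
}

#' Write every layer of a stack plus a manifest
#'
#' @param stack A [raster_stack()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(stack$layers, function(l) {
    p <- file.path(dir, paste0(l$name, ".asc"))
    write_ascii_grid(l, p)
    basename(p)
  }, character(1))
  man <- data.frame(name = stack_names(stack), path = paths)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Read/write a monthly precipitation series as YYYY-MM grids
#'
#' One ASCII grid per month, named `YYYY-MM.asc`, in one directory.
#'
#' @param series A [monthly_precip_series()].
#' @param dir Directory of `YYYY-MM.asc` files.
#' @return `read_monthly_precip()` returns a [monthly_precip_series()].
#' @export
write_monthly_precip <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (y in seq_along(series$years))
    for (m in 1:12) {
      lay <- raster_layer(series$grid, series$values[, , m, y],
                          name = sprintf("%04d-%02d", series$years[y], m),
                          units = "mm/month")
      write_ascii_grid(lay, file.path(dir, sprintf("%04d-%02d.asc",
                                                   series$years[y], m)))
    }
  invisible(dir)
}

#' @rdname write_monthly_precip
#' @export
read_monthly_precip <- function(dir) {
  files <- list.files(dir, pattern = "^\\d{4}-\\d{2}\\.asc$", full.names = TRUE)
  if (!length(files)) stop("no YYYY-MM.asc files in ", dir)
  ym <- sub("\\.asc$", "", basename(files))
  years <- sort(unique(as.integer(substr(ym, 1, 4))))
  first <- read_ascii_grid(files[1])
  grid <- first$grid
  vals <- array(NA_real_, c(grid$n_rows, grid$n_cols, 12, length(years)))
  for (f in files) {
    base <- sub("\\.asc$", "", basename(f))
    y <- match(as.integer(substr(base, 1, 4)), years)
    m <- as.integer(substr(base, 6, 7))
    lay <- read_ascii_grid(f)
    stop_if_grid_mismatch(grid, lay$grid)
    vals[, , m, y] <- lay$values
  }
  monthly_precip_series(grid, vals, years)
}
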