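#' Fit a surface range envelope (presence-only climate envelope)
#'
#' For each predictor, the envelope bounds are the `q`-th and `(1 - q)`-th
#' empirical quantiles of the presence values, with linear interpolation
#' between order statistics (quantile type 7).  `quantile = 0.025` trims the
#' most extreme 2.5% on each side (roughly a 95% tolerance interval);
#' `quantile = 0` uses the presence min/max, so the envelope then contains
#' every training presence.
#'
#' @param presence_values Data.frame or matrix of presence predictor values,
#'   one column per predictor, at least 2 rows.
#' @param quantile Trimming fraction in `[0, 0.5)`.
#' @return An object of class `sre_model` with `bounds` (data.frame:
#'   `predictor`, `lower`, `upper`) and `quantile`.
#' @export
fit_sre <- function(presence_values, quantile = 0.025) {
  if (quantile < 0 || quantile >= 0.5)
    stop("quantile must lie in [0, 0.5)")
  pv <- as.data.frame(presence_values)
  pv <- pv[, setdiff(names(pv), c("lon", "lat")), drop = FALSE]
  stopifnot(ncol(pv) >= 1L)
  bounds <- do.call(rbind, lapply(names(pv), function(nm) {
    v <- pv[[nm]][is.finite(pv[[nm]])]
    if (length(v) < 2L) stop("need >= 2 presence values for ", nm)
    qs <- stats::quantile(v, c(quantile, 1 - quantile), names = FALSE,
                          type = 7)
    data.frame(predictor = nm, lower = qs[1], upper = qs[2])
  }))
  rownames(bounds) <- NULL
  structure(list(bounds = bounds, quantile = quantile), class = "sre_model")
}

#' @export
print.sre_model <- function(x, ...) {
  cat(sprintf("<sre_model> quantile %.4g\n", x$quantile))
  print(x$bounds)
  invisible(x)
}

#' Project an SRE envelope onto a stack
#'
#' Cell = 1 iff every predictor value lies within its bounds (inclusive);
#' any nodata layer makes the cell nodata.
#'
#' @param stack A [raster_stack()] containing every predictor of `model`.
#' @param model An [sre_model()][fit_sre].
#' @return A binary [raster_layer()] named `"sre_envelope"`.
#' @export
sre_predict <- function(stack, model) {
  need <- model$bounds$predictor
  missing <- setdiff(need, stack_names(stack))
  if (length(missing))
    stop("stack is missing predictor(s): ", paste(missing, collapse = ", "))
  g <- stack$grid
  inside <- matrix(1, g$n_rows, g$n_cols)
  nodata <- matrix(FALSE, g$n_rows, g$n_cols)
  for (i in seq_len(nrow(model$bounds))) {
    v <- stack$layers[[need[i]]]$values
    nodata <- nodata | !is.finite(v)
    ok <- v >= model$bounds$lower[i] & v <= model$bounds$upper[i]
    ok[!is.finite(v)] <- FALSE
    inside[!ok] <- 0
  }
  inside[nodata] <- NA_real_
  raster_layer(g, inside, name = "sre_envelope")
}

#' Sample pseudo-absence realizations outside the envelope
#'
#' Background cells eligible for pseudo-absences (PAs) are those with valid
#' data in every layer, outside the climate envelope, and not occupied by any
#' presence record (occupied cells are excluded even outside the envelope so
#' no cell carries both labels).  Each realization draws
#' `n_per_realization` cells uniformly without replacement and places the PA
#' point at the cell center; realizations use independent sub-seeds derived
#' from `seed`, so the whole set is reproducible and realizations are
#' mutually independent.  With `area_weighted = TRUE` cells are drawn with
#' probability proportional to their spherical area instead of uniformly.
#'
#' @param stack A [raster_stack()] of the scenario predictors.
#' @param envelope Binary [raster_layer()] from [sre_predict()].
#' @param presences An [occurrence_set()] or data.frame with `lon`, `lat`.
#' @param n_per_realization PA count per realization (the presence count, for
#'   the equal-n design).
#' @param n_realizations Number of realizations (default 5).
#' @param seed Master seed.
#' @param area_weighted Latitude-area-weighted sampling flag.
#' @return List of `pa_realization` objects: `index`, `seed`, `points`
#'   (data.frame `lon`, `lat`).
#' @export
sample_pseudoabsences <- function(stack, envelope, presences,
                                  n_per_realization, n_realizations = 5L,
                                  seed = 1L, area_weighted = FALSE) {
  stop_if_grid_mismatch(stack$grid, envelope$grid)
  if (inherits(presences, "occurrence_set")) presences <- presences$records
  g <- stack$grid
  eligible <- stack_valid_mask(stack) & is.finite(envelope$values) &
    envelope$values == 0
  cc <- cell_of(g, presences$lon, presences$lat)
  occ <- !is.na(cc$row)
  eligible[cbind(cc$row[occ], cc$col[occ])] <- FALSE
  idx <- which(eligible)
  if (length(idx) < n_per_realization)
    stop(sprintf(
      "insufficient eligible background cells: need %d, have %d (short by %d)",
      n_per_realization, length(idx), n_per_realization - length(idx)))
  lons <- cell_center_lons(g)
  lats <- cell_center_lats(g)
  prob <- NULL
  if (area_weighted) {
    area <- cell_area_layer(g)$values
    prob <- area[idx]
  }
  lapply(seq_len(n_realizations), function(k) {
    sub_seed <- derive_seed(seed, "pseudo_absence", k)
    pick <- withr::with_seed(sub_seed,
                             sample(idx, n_per_realization, prob = prob))
    row <- (pick - 1L) %% g$n_rows + 1L
    col <- (pick - 1L) %/% g$n_rows + 1L
    structure(list(index = k, seed = sub_seed,
                   points = data.frame(lon = lons[col], lat = lats[row])),
              class = "pa_realization")
  })
}
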