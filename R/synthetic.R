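#' Parameters for smooth correlated random fields
#'
#' Controls the synthetic climate-field generator: each field is spatially
#' smooth (Gaussian-filtered white noise with the given correlation length)
#' with requested mean and standard deviation, and fields share a common
#' latent component so that any pair has approximately the requested
#' correlation — emulating the mutual correlation of real bioclimatic layers.
#'
#' @param grid A [grid_spec()].
#' @param mean,sd Field mean(s) and sd(s) in field units; recycled over the
#'   requested field names.
#' @param correlation_length Gaussian smoothing length in cells (>= 0; 0 is
#'   white noise).
#' @param inter_field_correlation Target pairwise correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `field_params`.
#' @export
field_params <- function(grid, mean = 0, sd = 1, correlation_length = 5,
                         inter_field_correlation = 0, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"), all(sd >= 0),
            correlation_length >= 0,
            inter_field_correlation >= 0, inter_field_correlation < 1)
  structure(list(grid = grid, mean = mean, sd = sd,
                 correlation_length = correlation_length,
                 inter_field_correlation = inter_field_correlation,
                 seed = as.integer(seed)),
            class = "field_params")
}

# Gaussian low-pass filter of a matrix, separable, edge-renormalized
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  smooth_1d <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      kk <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(x[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

standardize_matrix <- function(m) {
  s <- stats::sd(m)
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}

#' Generate a stack of smooth correlated climate fields
#'
#' Each field is standardized Gaussian-filtered noise rescaled to its
#' requested mean/sd; pairwise correlation is induced by mixing a shared
#' latent field with weight `sqrt(rho)`.  `sd = 0` gives a constant field.
#' Fully deterministic under the seed.
#'
#' @param params A [field_params()].
#' @param names Character vector of field names.
#' @return A [raster_stack()] with one layer per name.
#' @export
gen_smooth_fields <- function(params, names) {
  stopifnot(inherits(params, "field_params"), length(names) >= 1L)
  g <- params$grid
  means <- rep_len(params$mean, length(names))
  sds <- rep_len(params$sd, length(names))
  rho <- params$inter_field_correlation
  layers <- withr::with_seed(params$seed, {
    common <- standardize_matrix(
      smooth_field(matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows),
                   params$correlation_length))
    lapply(seq_along(names), function(i) {
      own <- standardize_matrix(
        smooth_field(matrix(stats::rnorm(g$n_rows * g$n_cols), g$n_rows),
                     params$correlation_length))
      z <- standardize_matrix(sqrt(rho) * common + sqrt(1 - rho) * own)
      raster_layer(g, means[i] + sds[i] * z, name = names[i])
    })
  })
  raster_stack(layers)
}

#' Generate multi-year monthly precipitation with controlled variability
#'
#' Per cell and year, the annual total is lognormal with median
#' `mean_annual` and log-sd `interannual_log_sd` (non-negative and
#' right-skewed, like rainfall, with closed-form control of inter-annual
#' variability); the total is spread over months by a cosine seasonal
#' profile peaking in January with relative amplitude `seasonality`.
#' `interannual_log_sd = 0` gives identical years, so the Hellmann-Eberle
#' quotient is exactly 1 everywhere.
#'
#' @param grid A [grid_spec()].
#' @param n_years Number of years (>= 2).
#' @param mean_annual Median annual total, mm; a scalar or an
#'   `n_rows x n_cols` matrix.
#' @param interannual_log_sd Log-scale sd of the yearly totals (>= 0).
#' @param seasonality Seasonal amplitude in `[0, 1)`; 0 is a flat profile.
#' @param seed Integer seed.
#' @param start_year First calendar year label.
#' @return A [monthly_precip_series()].
#' @export
gen_monthly_precip <- function(grid, n_years, mean_annual,
                               interannual_log_sd = 0.4, seasonality = 0.5,
                               seed = 1L, start_year = 1961L) {
  stopifnot(n_years >= 2L, interannual_log_sd >= 0,
            seasonality >= 0, seasonality < 1)
  ma <- if (is.matrix(mean_annual)) mean_annual
        else matrix(mean_annual, grid$n_rows, grid$n_cols)
  stopifnot(all(ma >= 0, na.rm = TRUE))
  profile <- 1 + seasonality * cos(2 * pi * (1:12 - 1) / 12)
  profile <- profile / sum(profile)
  vals <- array(NA_real_, c(grid$n_rows, grid$n_cols, 12L, n_years))
  withr::with_seed(seed, {
    for (y in seq_len(n_years)) {
      z <- matrix(stats::rnorm(grid$n_rows * grid$n_cols), grid$n_rows)
      total <- ma * exp(interannual_log_sd * z)
      for (m in 1:12) vals[, , m, y] <- total * profile[m]
    }
  })
  monthly_precip_series(grid, vals, start_year + seq_len(n_years) - 1L)
}

#' Define a known true niche
#'
#' The true suitability is a product of per-predictor response curves:
#' `logistic(midpoint, slope)` (rising sigmoid), `gaussian(center, width)`
#' (unimodal), or `flat` (no effect), scaled by `prevalence_scale`.  Because
#' the truth is known, pipelines run on synthetic data can be scored for
#' niche recovery (held-out skill, importance ranking, map overlap).
#'
#' @param responses Named list, one entry per predictor:
#'   `list(type = "logistic", midpoint =, slope =)`,
#'   `list(type = "gaussian", center =, width =)`, or
#'   `list(type = "flat")`.
#' @param prevalence_scale Overall scaling in `(0, 1]`.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(responses, prevalence_scale = 1) {
  stopifnot(length(responses) >= 1L, !is.null(names(responses)),
            prevalence_scale > 0, prevalence_scale <= 1)
  types <- vapply(responses, function(r) r$type, character(1))
  stopifnot(all(types %in% c("logistic", "gaussian", "flat")))
  if (all(types == "flat")) stop("at least one response must be non-flat")
  structure(list(responses = responses,
                 prevalence_scale = prevalence_scale),
            class = "synthetic_truth")
}

response_curve <- function(r, x) {
  switch(r$type,
         logistic = 1 / (1 + exp(-r$slope * (x - r$midpoint))),
         gaussian = exp(-0.5 * ((x - r$center) / r$width)^2),
         flat = rep(1, length(x)))
}

#' True suitability map from a stack and a known niche
#'
#' @param stack A [raster_stack()] containing every predictor the truth
#'   references.
#' @param truth A [synthetic_truth()].
#' @return A [raster_layer()] named `"true_suitability"`, values in `[0, 1]`.
#' @export
true_suitability <- function(stack, truth) {
  need <- names(truth$responses)
  missing <- setdiff(need, stack_names(stack))
  if (length(missing))
    stop("stack is missing predictor(s): ", paste(missing, collapse = ", "))
  g <- stack$grid
  s <- matrix(truth$prevalence_scale, g$n_rows, g$n_cols)
  for (nm in need) {
    v <- stack$layers[[nm]]$values
    s <- s * matrix(response_curve(truth$responses[[nm]], as.numeric(v)),
                    g$n_rows, g$n_cols)
    s[!is.finite(v)] <- NA_real_
  }
  raster_layer(g, s, name = "true_suitability")
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' `suitability * bias`; each record is jittered uniformly within its cell,
#' so downstream cell-assignment conventions are exercised off cell centers.
#' The optional bias layer emulates spatially uneven collection effort, the
#' kind of artefact per-cell thinning is meant to correct.
#'
#' @param suitability A [raster_layer()] with non-negative values.
#' @param n_target Number of records to draw.
#' @param bias Optional non-negative effort [raster_layer()] on the same grid.
#' @param seed Integer seed.
#' @param species_label Label for the returned set.
#' @return An [occurrence_set()] of exactly `n_target` records.
#' @export
sample_presences <- function(suitability, n_target, bias = NULL, seed = 1L,
                             species_label = "synthetic_species") {
  g <- suitability$grid
  w <- suitability$values
  if (!is.null(bias)) {
    stop_if_grid_mismatch(g, bias$grid)
    w <- w * bias$values
  }
  w[!is.finite(w) | w < 0] <- 0
  if (sum(w) == 0) stop("all sampling weights are zero")
  lons <- cell_center_lons(g)
  lats <- cell_center_lats(g)
  rec <- withr::with_seed(seed, {
    pick <- sample.int(length(w), n_target, replace = TRUE, prob = as.numeric(w))
    row <- (pick - 1L) %% g$n_rows + 1L
    col <- (pick - 1L) %/% g$n_rows + 1L
    jit_lon <- stats::runif(n_target, -0.5, 0.5) * g$cell_size
    jit_lat <- stats::runif(n_target, -0.5, 0.5) * g$cell_size
    data.frame(record_id = seq_len(n_target),
               lon = lons[col] + jit_lon,
               lat = lats[row] + jit_lat)
  })
  occurrence_set(rec, species_label)
}

#' The standard synthetic niche-recovery fixture
#'
#' One call builds the desk-scale stand-in for a global 2.5-arcmin analysis:
#' a 64 x 64 grid over a 32-degree window with four smooth, mutually
#' correlated bioclim-style predictors (mean diurnal range, minimum
#' temperature of the coldest month, annual precipitation, precipitation
#' seasonality), a known truth in which the minimum temperature of the
#' coldest month dominates (steep rising logistic) and annual precipitation
#' is a secondary unimodal control, a smooth positive collection-effort bias
#' field, and 500 biased presence records sampled from the truth.
#'
#' @param seed Integer master seed.
#' @param n_presences Presence records to draw (default 500).
#' @return List: `stack`, `truth`, `true_map`, `bias`, `occurrences`, `grid`.
#' @export
recovery_fixture <- function(seed = 1L, n_presences = 500L) {
  grid <- grid_spec(64, 64, lon_origin = 0, lat_origin = 16,
                    cell_size = 0.5)
  stack <- gen_smooth_fields(
    field_params(grid,
                 mean = c(12, 5, 800, 50),
                 sd = c(3, 6, 300, 20),
                 correlation_length = 6,
                 inter_field_correlation = 0.3,
                 seed = derive_seed(seed, "fields")),
    names = c("mean_diurnal_range", "min_temp_coldest_month",
              "annual_precip", "precip_seasonality"))
  truth <- synthetic_truth(list(
    min_temp_coldest_month = list(type = "logistic", midpoint = 5,
                                  slope = 1.5),
    annual_precip = list(type = "gaussian", center = 800, width = 500)))
  true_map <- true_suitability(stack, truth)
  bias_field <- gen_smooth_fields(
    field_params(grid, mean = 0, sd = 1, correlation_length = 10,
                 seed = derive_seed(seed, "bias")),
    names = "effort")[["effort"]]
  bias <- raster_layer(grid, exp(bias_field$values), name = "effort")
  occ <- sample_presences(true_map, n_presences, bias = bias,
                          seed = derive_seed(seed, "presences"))
  list(stack = stack, truth = truth, true_map = true_map, bias = bias,
       occurrences = occ, grid = grid)
}
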