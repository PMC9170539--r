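# Small in-code fixtures shared across test files.

toy_grid <- function(n_rows = 4, n_cols = 4, cell_size = 1,
                     lon_origin = 0, lat_origin = 4) {
  grid_spec(n_rows, n_cols, lon_origin, lat_origin, cell_size)
}

constant_layer <- function(grid, value, name = "const") {
  raster_layer(grid, matrix(value, grid$n_rows, grid$n_cols), name = name)
}

# A labeled toy table where x1 separates the classes perfectly.
separable_table <- function(n_per_class = 50, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      lon = 0, lat = 0,
      x1 = c(rnorm(n_per_class, 3, 0.5), rnorm(n_per_class, -3, 0.5)),
      x2 = rnorm(2 * n_per_class),
      label = rep(c(1, 0), each = n_per_class),
      provenance = "toy")
  })
}

# Desk-scale pipeline fixture: 24x24 grid, 3 smooth predictors, truth driven
# by p1 only, ~100 presences.  Small enough that a scenario run takes seconds.
small_pipeline_fixture <- function(seed = 11, n_presences = 100) {
  grid <- grid_spec(24, 24, lon_origin = 0, lat_origin = 12, cell_size = 0.5)
  stack <- gen_smooth_fields(
    field_params(grid, mean = c(0, 10, 100), sd = c(2, 4, 30),
                 correlation_length = 4, inter_field_correlation = 0.2,
                 seed = seed),
    names = c("p1", "p2", "p3"))
  truth <- synthetic_truth(list(p1 = list(type = "logistic", midpoint = 0,
                                          slope = 3)))
  true_map <- true_suitability(stack, truth)
  occ <- sample_presences(true_map, n_presences, seed = seed + 1)
  list(grid = grid, stack = stack, truth = truth, true_map = true_map,
       occurrences = occ)
}

small_scenario_config <- function(scenario_id = 1,
                                  predictors = c("p1", "p2", "p3"),
                                  master_seed = 5, ...) {
  scenario_config(scenario_id, predictors,
                  algorithms = "random_forest",
                  n_pa_realizations = 1, n_repeats = 2,
                  master_seed = master_seed, ...)
}

# Brute-force metric oracles, independent of the package implementations.
brute_auc <- function(pred, lab) {
  pos <- pred[lab == 1]
  neg <- pred[lab == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

grid_scan_best_tss <- function(pred, lab, n_grid = 1001) {
  best <- -Inf
  for (ct in seq(0, 1, length.out = n_grid)) {
    sens <- sum(pred >= ct & lab == 1) / sum(lab == 1)
    spec <- sum(pred < ct & lab == 0) / sum(lab == 0)
    best <- max(best, sens + spec - 1)
  }
  best
}
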