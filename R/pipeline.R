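#' Derive a reproducible sub-seed
#'
#' Every source of randomness in a pipeline run is seeded from one master
#' seed through this function: the stage name and indices are folded into a
#' 31-bit integer by a multiplicative string hash, so sub-streams for
#' different stages/indices are decoupled while the whole run stays
#' reproducible from the single master seed.
#'
#' @param master Integer master seed.
#' @param stage Stage name (e.g. `"split"`, `"pseudo_absence"`).
#' @param ... Further integer indices (PA index, repeat, ...).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage, ...) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  tokens <- c(utf8ToInt(stage), as.numeric(c(...)))
  for (v in tokens) h <- (h * 31 + (v %% m) + 7) %% m
  as.integer(h %% (m - 1) + 1)
}

#' The five standard predictor scenarios
#'
#' Scenario 1 is the bioclim-only set (mean diurnal range, minimum
#' temperature of the coldest month, annual precipitation, precipitation
#' seasonality); scenarios 2-5 add exactly one derived predictor each:
#' the Hellmann-Eberle quotient, the aridity index, cloud cover, or the
#' R-index.
#'
#' @return Named list of character vectors of predictor names.
#' @export
default_scenario_predictors <- function() {
  base <- c("mean_diurnal_range", "min_temp_coldest_month",
            "annual_precip", "precip_seasonality")
  list(`1` = base,
       `2` = c(base, "hellmann_eberle"),
       `3` = c(base, "aridity_index"),
       `4` = c(base, "cloud_cover"),
       `5` = c(base, "r_index"))
}

#' Configure one scenario run
#'
#' @param scenario_id Integer scenario label.
#' @param predictors Character vector of stack layer names to model with.
#' @param species Species label.
#' @param algorithms Learner algorithms to run (default both).
#' @param n_pa_realizations Pseudo-absence realizations (default 5).
#' @param n_repeats Repeats per algorithm per realization (default 10), so
#'   the default full design is 2 x 5 x 10 = 100 runs per ensemble.
#' @param sre_quantile SRE trimming quantile (default 0.025).
#' @param thin_cell_size,thin_max_per_cell Occurrence thinning settings
#'   (default: at most 5 records per 1-degree cell).
#' @param train_fraction Training fraction of the stratified split
#'   (default 0.6; the remaining 0.4 is held out for evaluation).
#' @param weighting_metric `"TSS"` (default) or `"ROC"`.
#' @param min_roc ROC inclusion gate for ensemble members (default 0.5).
#' @param n_importance_shuffles Permutations per predictor for variable
#'   importance (default 10).
#' @param master_seed Single master seed; all sub-seeds derive from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario_id, predictors, species = "species",
                            algorithms = c("boosted_trees", "random_forest"),
                            n_pa_realizations = 5L, n_repeats = 10L,
                            sre_quantile = 0.025,
                            thin_cell_size = 1.0, thin_max_per_cell = 5L,
                            train_fraction = 0.6,
                            weighting_metric = "TSS", min_roc = 0.5,
                            n_importance_shuffles = 10L, master_seed = 1L) {
  stopifnot(length(predictors) >= 1L, n_pa_realizations >= 1L,
            n_repeats >= 1L,
            all(algorithms %in% c("boosted_trees", "random_forest")))
  structure(list(scenario_id = as.integer(scenario_id),
                 predictors = predictors, species = species,
                 algorithms = algorithms,
                 n_pa_realizations = as.integer(n_pa_realizations),
                 n_repeats = as.integer(n_repeats),
                 sre_quantile = sre_quantile,
                 thin_cell_size = thin_cell_size,
                 thin_max_per_cell = as.integer(thin_max_per_cell),
                 train_fraction = train_fraction,
                 weighting_metric = weighting_metric, min_roc = min_roc,
                 n_importance_shuffles = as.integer(n_importance_shuffles),
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

#' Run one predictor scenario end to end
#'
#' The full per-scenario pipeline: clean and thin the occurrences; fit the
#' surface range envelope on all thinned presences; draw the pseudo-absence
#' realizations outside it; for every realization x algorithm x repeat,
#' build the equal-n dataset, split it 60/40 stratified, fit, score on the
#' held-out rows, and project a suitability map; combine the runs into a
#' performance-weighted ensemble with a coefficient-of-variation uncertainty
#' map; evaluate the ensemble on the pooled held-out rows (each run's test
#' rows scored with the full weighted-mean prediction); compute permutation
#' variable importance on the pooled reference table; and binarize the
#' ensemble map at its TSS-optimal cutoff for suitable-area accounting.
#' The run count is exactly
#' `length(algorithms) * n_pa_realizations * n_repeats`.
#'
#' @param config A [scenario_config()].
#' @param stack A [raster_stack()] holding at least the configured predictors.
#' @param occurrences An [occurrence_set()] of raw presence records.
#' @param mask Optional binary region-mask [raster_layer()] for the area
#'   summary.
#' @return An object of class `scenario_report`: `config`, `occurrences`
#'   (thinned), `sre`, `envelope`, `runs`, `ledger` (one data.frame row per
#'   run), `ensemble`, `suitability_map`, `cv_map`, `scores`, `cutoff`,
#'   `binary_map`, `importance`, `area_mkm2`, `datasets`.
#' @export
run_scenario <- function(config, stack, occurrences, mask = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  stack <- subset_stack(stack, config$predictors)
  seed0 <- config$master_seed

  occ <- basic_clean(occurrences)
  occ <- thin_per_cell(occ, config$thin_cell_size, config$thin_max_per_cell,
                       seed = derive_seed(seed0, "thin", config$scenario_id))
  pres <- extract_predictors(occ, stack)
  sre <- fit_sre(pres$table, quantile = config$sre_quantile)
  envelope <- sre_predict(stack, sre)
  pas <- sample_pseudoabsences(
    stack, envelope, occ, n_per_realization = nrow(pres$table),
    n_realizations = config$n_pa_realizations,
    seed = derive_seed(seed0, "pa", config$scenario_id))

  runs <- list()
  datasets <- vector("list", config$n_pa_realizations)
  ledger <- NULL
  for (p in seq_len(config$n_pa_realizations)) {
    datasets[[p]] <- make_dataset(pres$table, pas[[p]], stack)
    for (alg in config$algorithms) {
      for (rep_i in seq_len(config$n_repeats)) {
        split_seed <- derive_seed(seed0, "split", config$scenario_id, p,
                                  match(alg, config$algorithms), rep_i)
        learner_seed <- derive_seed(seed0, "learner", config$scenario_id, p,
                                    match(alg, config$algorithms), rep_i)
        run <- fit_and_score(
          learner_spec(alg, seed = learner_seed), datasets[[p]],
          pa_index = p, repeat_index = rep_i,
          train_fraction = config$train_fraction, split_seed = split_seed)
        runs[[length(runs) + 1L]] <- run
        ledger <- rbind(ledger, data.frame(
          scenario_id = config$scenario_id, species = config$species,
          algorithm = alg, pa_index = p, repeat_index = rep_i,
          split_seed = split_seed, learner_seed = learner_seed,
          TSS = run$scores$TSS, ROC = run$scores$ROC,
          sensitivity = run$scores$sensitivity,
          specificity = run$scores$specificity,
          cutoff = run$scores$cutoff))
      }
    }
  }

  ensemble <- build_ensemble(runs, metric = config$weighting_metric,
                             min_roc = config$min_roc)
  ledger$weight <- ensemble$weights
  maps <- lapply(runs, project_map, stack = stack)
  suit <- weighted_mean_map(maps, ensemble$weights)
  cvm <- cv_map(maps)

  # pooled held-out evaluation: every run's test rows, scored with the
  # full weighted-mean ensemble prediction
  pooled_p <- numeric(0)
  pooled_lab <- numeric(0)
  for (run in runs) {
    d <- datasets[[run$pa_index]]
    rows <- d[run$split$test, , drop = FALSE]
    pooled_p <- c(pooled_p, ensemble_predict(ensemble, rows))
    pooled_lab <- c(pooled_lab, rows$label)
  }
  scores <- score_predictions(pooled_p, pooled_lab)

  # pooled reference table: the presences once, plus every realization's PAs
  ref <- rbind(datasets[[1L]][datasets[[1L]]$provenance == "presence", ],
               do.call(rbind, lapply(datasets, function(d)
                 d[d$provenance != "presence", ])))
  importance <- variable_importance(
    ensemble, ref, n_shuffles = config$n_importance_shuffles,
    seed = derive_seed(seed0, "importance", config$scenario_id))

  binary <- binarize(suit, scores$cutoff)
  area <- suitable_area(binary, cell_area_layer(stack$grid), mask)

  structure(list(config = config, occurrences = occ, sre = sre,
                 envelope = envelope, runs = runs, ledger = ledger,
                 ensemble = ensemble, suitability_map = suit, cv_map = cvm,
                 scores = scores, cutoff = scores$cutoff,
                 binary_map = binary, importance = importance,
                 area_mkm2 = area, datasets = datasets),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf(
    "<scenario_report> scenario %d '%s': %d runs, ensemble TSS %.3f ROC %.3f, cutoff %.3f, suitable area %.3g Mkm2\n",
    x$config$scenario_id, x$config$species, nrow(x$ledger),
    x$scores$TSS, x$scores$ROC, x$cutoff, x$area_mkm2))
  invisible(x)
}

#' Compare scenario reports against the bioclim-only baseline
#'
#' @param reports List of `scenario_report`s including scenario 1 (the
#'   baseline); other scenarios may be missing, gaps are recorded.
#' @param mask Optional region mask for the area table.
#' @return List: `deviations` (named list of [deviation_map()] layers,
#'   scenarios vs baseline), `score_table` (scenario x TSS/ROC with deltas
#'   vs baseline), `area_table` (scenario x million km2), `missing`.
#' @export
compare_scenarios <- function(reports, mask = NULL) {
  ids <- vapply(reports, function(r) r$config$scenario_id, integer(1))
  if (!1L %in% ids) stop("scenario 1 (baseline) report is required")
  species <- unique(vapply(reports, function(r) r$config$species,
                           character(1)))
  if (length(species) != 1L) stop("reports mix species labels")
  base <- reports[[match(1L, ids)]]
  for (r in reports)
    stop_if_grid_mismatch(base$suitability_map$grid, r$suitability_map$grid)
  others <- reports[ids != 1L]
  deviations <- lapply(others, function(r)
    deviation_map(r$suitability_map, base$suitability_map))
  if (length(others))
    names(deviations) <- paste0("scenario_", vapply(others, function(r)
      r$config$scenario_id, integer(1)))
  score_table <- data.frame(
    scenario = ids, species = species,
    TSS = vapply(reports, function(r) r$scores$TSS, numeric(1)),
    ROC = vapply(reports, function(r) r$scores$ROC, numeric(1)))
  score_table$delta_TSS <- score_table$TSS - base$scores$TSS
  score_table$delta_ROC <- score_table$ROC - base$scores$ROC
  score_table <- score_table[order(score_table$scenario), ]
  area_table <- data.frame(
    scenario = ids, species = species,
    region = if (is.null(mask)) "all" else "mask",
    area_mkm2 = vapply(reports, function(r)
      suitable_area(r$binary_map, cell_area_layer(r$binary_map$grid), mask),
      numeric(1)))
  area_table <- area_table[order(area_table$scenario), ]
  list(deviations = deviations, score_table = score_table,
       area_table = area_table, missing = setdiff(2:5, ids))
}

#' Write a scenario report's tables and maps to a directory
#'
#' Emits `ledger.csv` (one row per run), `scores.csv` (ensemble TSS/ROC plus
#' sensitivity, specificity, cutoff, rounded to 3 decimals for display),
#' `importance.csv` (standardized percentages), `area.csv`, and the
#' suitability / CV / binary maps as ASCII grids.
#'
#' @param report A `scenario_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scenario_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  sc <- report$scores
  utils::write.csv(data.frame(
    scenario = report$config$scenario_id, species = report$config$species,
    TSS = round(sc$TSS, 3), ROC = round(sc$ROC, 3),
    sensitivity = round(sc$sensitivity, 3),
    specificity = round(sc$specificity, 3),
    cutoff = round(sc$cutoff, 3)),
    file.path(dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$importance),
                   file.path(dir, "importance.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    scenario = report$config$scenario_id, species = report$config$species,
    area_mkm2 = report$area_mkm2),
    file.path(dir, "area.csv"), row.names = FALSE)
  write_ascii_grid(report$suitability_map, file.path(dir, "suitability.asc"))
  write_ascii_grid(report$cv_map, file.path(dir, "cv.asc"))
  write_ascii_grid(report$binary_map, file.path(dir, "binary.asc"))
  invisible(dir)
}

#' Jaccard overlap of two binary maps
#'
#' `|A intersect B| / |A union B|` over cells valid in both maps; used to
#' compare a recovered binary suitability map with the known true-niche
#' region on synthetic data.
#'
#' @param a,b Binary [raster_layer()]s on one grid.
#' @return Jaccard index in `[0, 1]` (1 if both maps are empty).
#' @export
map_jaccard <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid)
  ok <- is.finite(a$values) & is.finite(b$values)
  ai <- a$values == 1 & ok
  bi <- b$values == 1 & ok
  un <- sum(ai | bi)
  if (un == 0) return(1)
  sum(ai & bi) / un
}
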