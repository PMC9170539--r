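#' Performance-based ensemble weights
#'
#' Members whose ROC AUC is not strictly above `min_roc` (default 0.5, i.e.
#' no better than random) are excluded with weight 0.  The remaining members
#' are weighted proportionally to their score under the chosen metric
#' (negative TSS is clamped to 0 before normalizing); weights are normalized
#' to sum to 1.  If every included member has score 0, included members get
#' equal weight.
#'
#' @param members List of `model_run`s (each with `scores$TSS`, `scores$ROC`).
#' @param metric Weighting metric, `"TSS"` (default) or `"ROC"`.
#' @param min_roc ROC inclusion gate (strict inequality).
#' @return Numeric weight vector over `members`, summing to 1.
#' @export
compute_weights <- function(members, metric = c("TSS", "ROC"),
                            min_roc = 0.5) {
  metric <- match.arg(metric)
  stopifnot(length(members) >= 1L)
  roc <- vapply(members, function(m) m$scores$ROC, numeric(1))
  included <- roc > min_roc
  if (!any(included))
    stop("no member passes the ROC > ", min_roc, " inclusion gate")
  s <- vapply(members, function(m) m$scores[[metric]], numeric(1))
  s <- pmax(s, 0)
  s[!included] <- 0
  if (sum(s) == 0) s[included] <- 1
  s / sum(s)
}

#' Build a weighted ensemble from fitted runs
#'
#' @param members List of `model_run`s.
#' @param metric,min_roc Passed to [compute_weights()].
#' @return An object of class `ensemble_model`: `members`, `weights`,
#'   `weighting_metric`, `min_roc`.
#' @export
build_ensemble <- function(members, metric = c("TSS", "ROC"),
                           min_roc = 0.5) {
  metric <- match.arg(metric)
  w <- compute_weights(members, metric, min_roc)
  structure(list(members = members, weights = w, weighting_metric = metric,
                 min_roc = min_roc),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "<ensemble_model> %d members (%d weighted > 0), metric %s\n",
    length(x$members), sum(x$weights > 0), x$weighting_metric))
  invisible(x)
}

#' Weighted-mean ensemble suitability map
#'
#' Per cell, the convex combination of the member maps under the given
#' weights, so the result always lies within the member min/max.  Nodata in
#' any contributing member makes the cell nodata.
#'
#' @param maps List of member suitability [raster_layer()]s on one grid.
#' @param weights Non-negative weights summing to 1 (within 1e-12).
#' @return A [raster_layer()] named `"ensemble_mean"`.
#' @export
weighted_mean_map <- function(maps, weights) {
  stopifnot(length(maps) == length(weights), length(maps) >= 1L,
            all(weights >= 0), abs(sum(weights) - 1) < 1e-12)
  g <- maps[[1L]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  nodata <- matrix(FALSE, g$n_rows, g$n_cols)
  for (i in seq_along(maps)) {
    stop_if_grid_mismatch(g, maps[[i]]$grid)
    v <- maps[[i]]$values
    nodata <- nodata | !is.finite(v)
    v[!is.finite(v)] <- 0
    acc <- acc + weights[i] * v
  }
  acc[nodata] <- NA_real_
  raster_layer(g, acc, name = "ensemble_mean")
}

#' Coefficient-of-variation uncertainty map
#'
#' Per cell, `100 * sd / mean` across the member maps, using the unweighted
#' sample (n-1) standard deviation — a scale-free measure of between-member
#' disagreement, in percent.  Cells where the member mean is 0 are nodata.
#'
#' @param maps List of at least two member [raster_layer()]s on one grid.
#' @return A [raster_layer()] named `"ensemble_cv"`, units percent.
#' @export
cv_map <- function(maps) {
  if (length(maps) < 2L) stop("CV needs at least 2 member maps")
  g <- maps[[1L]]$grid
  for (m in maps) stop_if_grid_mismatch(g, m$grid)
  arr <- vapply(maps, function(m) m$values, matrix(0, g$n_rows, g$n_cols))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  cv <- 100 * sdv / mu
  cv[!is.finite(cv)] <- NA_real_
  raster_layer(g, cv, name = "ensemble_cv", units = "percent")
}

#' Ensemble prediction on a table of predictor rows
#'
#' The weighted mean of the member predictions, row by row; a convex
#' combination, so each prediction lies within the member min/max.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param table Data.frame containing the predictor columns.
#' @return Numeric suitability vector in `[0, 1]`.
#' @export
ensemble_predict <- function(ensemble, table) {
  p <- vapply(ensemble$members,
              function(m) predict_learner(m$fitted, table),
              numeric(nrow(table)))
  if (nrow(table) == 1L) p <- matrix(p, nrow = 1L)
  as.numeric(p %*% ensemble$weights)
}

#' Evaluate an ensemble on a labeled table
#'
#' Scores the weighted-mean ensemble prediction with the same machinery as
#' individual runs: ROC AUC plus the TSS-optimal binary cutoff.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param table Labeled data.frame (rows held out from member training).
#' @return List: `TSS`, `ROC`, `sensitivity`, `specificity`, `cutoff`.
#' @export
ensemble_evaluate <- function(ensemble, table) {
  p <- ensemble_predict(ensemble, table)
  score_predictions(p, table$label)
}

#' Shuffle-based permutation variable importance
#'
#' For each predictor, its column in the reference table is randomly permuted
#' (`n_shuffles` times, seeded), the ensemble re-predicts, and the Pearson
#' correlation `r` between reference and shuffled predictions is computed.
#' Raw importance is the mean of `max(0, 1 - r)`: a predictor the model never
#' uses leaves predictions unchanged (`r = 1`, importance 0), while a
#' decisive predictor destroys the predictions when shuffled (`r` near 0,
#' importance near 1).  Raw importances are standardized to percentages
#' summing to 100 across the predictors.
#'
#' Note the direction: the correlation itself is high for *unimportant*
#' variables, so importance must be `1 - r`; values above 1 (negative `r`)
#' are passed through to standardization, only the lower side is clamped
#' at 0.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param table Reference data.frame of predictor rows (>= 3 rows).
#' @param n_shuffles Permutations per predictor (default 10).
#' @param seed Integer seed.
#' @return Data.frame of class `importance_table`: `predictor`, `raw`,
#'   `percent` (summing to 100).
#' @export
variable_importance <- function(ensemble, table, n_shuffles = 10L,
                                seed = 1L) {
  stopifnot(nrow(table) >= 3L)
  vars <- ensemble$members[[1L]]$fitted$predictors
  ref <- ensemble_predict(ensemble, table)
  if (stats::sd(ref) == 0)
    stop("reference predictions have zero variance; importance undefined")
  raw <- vapply(seq_along(vars), function(j) {
    drops <- vapply(seq_len(n_shuffles), function(s) {
      shuf <- table
      perm <- withr::with_seed(derive_seed(seed, "shuffle", j, s),
                               sample.int(nrow(table)))
      shuf[[vars[j]]] <- shuf[[vars[j]]][perm]
      p <- ensemble_predict(ensemble, shuf)
      r <- if (stats::sd(p) == 0) 0 else stats::cor(ref, p)
      max(0, 1 - r)
    }, numeric(1))
    mean(drops)
  }, numeric(1))
  if (sum(raw) == 0) {
    percent <- rep(0, length(vars))  # nothing matters; leave all at zero
  } else {
    percent <- raw / sum(raw) * 100
  }
  structure(data.frame(predictor = vars, raw = raw, percent = percent,
                       stringsAsFactors = FALSE),
            class = c("importance_table", "data.frame"))
}

#' Standardize raw importances to percentages
#'
#' The proportional mapping used for reported importance tables:
#' `percent_i = raw_i / sum(raw) * 100`.
#'
#' @param raw Non-negative numeric vector.
#' @return Percentages summing to 100.
#' @export
standardize_importance <- function(raw) {
  stopifnot(all(raw >= 0), sum(raw) > 0)
  raw / sum(raw) * 100
}
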