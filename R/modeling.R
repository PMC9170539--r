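#' Specify a tree-ensemble learner
#'
#' Two algorithms are supported: `"boosted_trees"` (gradient-boosted
#' classification trees via xgboost) and `"random_forest"` (via
#' randomForest).  Hyperparameters not supplied fall back to the package
#' defaults from [default_hyperparameters()]; both learners run
#' single-threaded so fits are bitwise reproducible under their seed.
#'
#' @param algorithm `"boosted_trees"` or `"random_forest"`.
#' @param hyperparameters Named list overriding the defaults.
#' @param seed Integer seed used when fitting.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(algorithm = c("boosted_trees", "random_forest"),
                         hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  hp <- utils::modifyList(default_hyperparameters(algorithm), hyperparameters)
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

#' Default learner hyperparameters
#'
#' Deliberately plain defaults for a presence/pseudo-absence problem with a
#' handful of smooth climatic predictors: 500 trees for the random forest
#' (mtry left at the classification default, floor(sqrt(p))); 200 boosting
#' rounds of depth-3 trees with learning rate 0.1 for the boosted model.
#'
#' @param algorithm `"boosted_trees"` or `"random_forest"`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(algorithm) {
  switch(algorithm,
         random_forest = list(ntree = 500L),
         boosted_trees = list(nrounds = 200L, max_depth = 3L, eta = 0.1,
                              subsample = 0.8),
         stop("unknown algorithm: ", algorithm))
}

#' Assemble a labeled presence / pseudo-absence dataset
#'
#' Binds the presence rows (label 1) to one pseudo-absence realization
#' (label 0) with predictor values extracted from the stack.  Rows landing on
#' nodata are dropped and any resulting class imbalance is reported in the
#' attribute `"n_dropped"` (named counts).
#'
#' @param presence_rows Data.frame of presence predictor rows, as returned in
#'   `extract_predictors()$table`.
#' @param pa A `pa_realization` from [sample_pseudoabsences()].
#' @param stack The scenario [raster_stack()] (defines predictor columns and
#'   their order).
#' @return Data.frame: `lon`, `lat`, predictor columns in stack order,
#'   `label` (1/0), `provenance` (`"presence"` or `"pa<k>"`).
#' @export
make_dataset <- function(presence_rows, pa, stack) {
  stopifnot(inherits(pa, "pa_realization"))
  if (!nrow(presence_rows)) stop("no presence rows")
  if (!nrow(pa$points)) stop("empty pseudo-absence realization")
  vars <- stack_names(stack)
  missing <- setdiff(vars, names(presence_rows))
  if (length(missing))
    stop("presence rows lack predictor(s): ", paste(missing, collapse = ", "))
  pres <- presence_rows[c("lon", "lat", vars)]
  pres_ok <- apply(is.finite(as.matrix(pres[vars])), 1, all)
  pres <- pres[pres_ok, , drop = FALSE]
  ex <- extract_predictors(pa$points, stack)
  abs_tab <- ex$table[c("lon", "lat", vars)]
  if (!nrow(pres) || !nrow(abs_tab))
    stop("one side of the dataset is empty after nodata filtering")
  pres$label <- 1
  pres$provenance <- "presence"
  abs_tab$label <- 0
  abs_tab$provenance <- paste0("pa", pa$index)
  out <- rbind(pres, abs_tab)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- c(presence = sum(!pres_ok), pa = ex$n_dropped)
  out
}

#' Stratified train/test split
#'
#' Splits rows 60/40 (by default) within each label class, so the engineered
#' 1:1 presence:absence balance is preserved in both partitions; per-class
#' train counts are `round(n_class * train_fraction)`.  Deterministic under
#' `seed`.
#'
#' @param table A labeled dataset from [make_dataset()].
#' @param train_fraction Fraction in `(0, 1)` used for training (default 0.6).
#' @param seed Integer seed.
#' @return List with integer row-index vectors `train` and `test`.
#' @export
split_train_test <- function(table, train_fraction = 0.6, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  lab <- table$label
  if (min(table(factor(lab, levels = c(0, 1)))) < 2L)
    stop("each class needs at least 2 rows")
  train <- withr::with_seed(seed, {
    unlist(lapply(c(0, 1), function(cl) {
      idx <- which(lab == cl)
      n_tr <- round(length(idx) * train_fraction)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # neither side empty
      sort(sample(idx, n_tr))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(table)), train))
}

predictor_columns <- function(table) {
  setdiff(names(table), c("lon", "lat", "label", "provenance"))
}

fit_learner <- function(spec, table, rows) {
  vars <- predictor_columns(table)
  x <- as.matrix(table[rows, vars, drop = FALSE])
  y <- table$label[rows]
  if (length(unique(y)) < 2L)
    stop("training labels are single-class; cannot fit")
  if (spec$algorithm == "random_forest") {
    fit <- withr::with_seed(spec$seed,
      randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                                 ntree = spec$hyperparameters$ntree))
  } else {
    hp <- spec$hyperparameters
    fit <- withr::with_seed(spec$seed,
      xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                       objective = "binary:logistic",
                       nrounds = hp$nrounds, max_depth = hp$max_depth,
                       learning_rate = hp$eta, subsample = hp$subsample,
                       nthreads = 1L, seed = spec$seed, verbosity = 0))
  }
  structure(list(spec = spec, fit = fit, predictors = vars),
            class = "fitted_learner")
}

predict_learner <- function(fitted, newdata) {
  x <- as.matrix(newdata[, fitted$predictors, drop = FALSE])
  p <- if (fitted$spec$algorithm == "random_forest") {
    stats::predict(fitted$fit, x, type = "prob")[, "1"]
  } else {
    stats::predict(fitted$fit, x, type = "response")
  }
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Fit one model run and score it on held-out rows
#'
#' One run = one learner x one pseudo-absence realization x one repeat.  The
#' dataset is split 60/40 stratified by label (a fresh split per repeat is
#' what makes repeats informative), the learner is fitted on the training
#' rows, and TSS / ROC AUC / sensitivity / specificity / optimal cutoff are
#' computed on the held-out rows only.
#'
#' @param learner A [learner_spec()].
#' @param table A labeled dataset from [make_dataset()].
#' @param pa_index,repeat_index Bookkeeping indices recorded on the run.
#' @param train_fraction Training fraction (default 0.6).
#' @param split_seed Seed for the train/test split.
#' @return An object of class `model_run`: `learner`, `pa_index`,
#'   `repeat_index`, `split`, `fitted`, `scores` (list with `TSS`, `ROC`,
#'   `sensitivity`, `specificity`, `cutoff`), `test_predictions`.
#' @export
fit_and_score <- function(learner, table, pa_index = 1L, repeat_index = 1L,
                          train_fraction = 0.6, split_seed = 1L) {
  stopifnot(inherits(learner, "learner_spec"))
  split <- split_train_test(table, train_fraction, split_seed)
  fitted <- fit_learner(learner, table, split$train)
  p_test <- predict_learner(fitted, table[split$test, , drop = FALSE])
  scores <- score_predictions(p_test, table$label[split$test])
  structure(list(learner = learner, pa_index = as.integer(pa_index),
                 repeat_index = as.integer(repeat_index), split = split,
                 fitted = fitted, scores = scores,
                 test_predictions = p_test),
            class = "model_run")
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run> %s pa%d rep%d: TSS %.3f, ROC %.3f\n",
              x$learner$algorithm, x$pa_index, x$repeat_index,
              x$scores$TSS, x$scores$ROC))
  invisible(x)
}

#' Project a fitted run onto a predictor stack
#'
#' Predicts continuous habitat suitability in `[0, 1]` for every valid cell;
#' cells with nodata in any predictor stay nodata.
#'
#' @param run A [fit_and_score()] result (or a `fitted_learner`).
#' @param stack A [raster_stack()] containing the run's predictors.
#' @return A [raster_layer()] named `"suitability"`.
#' @export
project_map <- function(run, stack) {
  fitted <- if (inherits(run, "model_run")) run$fitted else run
  missing <- setdiff(fitted$predictors, stack_names(stack))
  if (length(missing))
    stop("stack is missing predictor(s): ", paste(missing, collapse = ", "))
  g <- stack$grid
  mask <- stack_valid_mask(subset_stack(stack, fitted$predictors))
  idx <- which(mask)
  row <- (idx - 1L) %% g$n_rows + 1L
  col <- (idx - 1L) %/% g$n_rows + 1L
  newdata <- as.data.frame(stack_values_at(stack, row, col))
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  out[idx] <- predict_learner(fitted, newdata)
  raster_layer(g, out, name = "suitability")
}
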