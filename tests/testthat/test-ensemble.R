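fake_run <- function(tss, roc) {
  structure(list(scores = list(TSS = tss, ROC = roc)), class = "model_run")
}

layer_of <- function(vals, name = "m") {
  g <- grid_spec(1, length(vals), 0, 1, 1)
  raster_layer(g, matrix(vals, 1), name = name)
}

# a small real ensemble fitted on the separable toy, reused by several tests
toy_ensemble <- local({
  env <- new.env()
  function() {
    if (is.null(env$ens)) {
      tab <- separable_table(60)
      runs <- lapply(c(101, 202), function(s)
        fit_and_score(learner_spec("random_forest", seed = s), tab,
                      split_seed = s + 1))
      env$ens <- build_ensemble(runs)
      env$tab <- tab
    }
    list(ensemble = env$ens, table = env$tab)
  }
})

test_that("ensemble weights are metric-proportional with a strict ROC gate", {
  w <- compute_weights(list(fake_run(0.9, 0.9), fake_run(0.3, 0.9)))
  expect_equal(w, c(0.75, 0.25))
  # ROC exactly at the gate is excluded (strictly better than random required)
  w2 <- compute_weights(list(fake_run(0.9, 0.9), fake_run(0.8, 0.5)))
  expect_equal(w2, c(1, 0))
  w3 <- compute_weights(list(fake_run(0.6, 0.9), fake_run(0.6, 0.8),
                             fake_run(0.6, 0.7)))
  expect_equal(w3, rep(1 / 3, 3))
  expect_equal(sum(w3), 1, tolerance = 1e-12)
  # negative TSS clamps to zero before normalization
  w4 <- compute_weights(list(fake_run(0.5, 0.9), fake_run(-0.2, 0.9)))
  expect_equal(w4, c(1, 0))
  expect_error(compute_weights(list(fake_run(0.9, 0.4))), "inclusion gate")
})

test_that("the weighted mean map is the stated convex combination", {
  m1 <- layer_of(c(0.2, 0.2)); m2 <- layer_of(c(0.8, 0.8))
  expect_equal(as.numeric(weighted_mean_map(list(m1, m2),
                                            c(0.5, 0.5))$values),
               c(0.5, 0.5))
  expect_equal(as.numeric(weighted_mean_map(list(m1, m2),
                                            c(0.75, 0.25))$values),
               c(0.35, 0.35))
  expect_equal(weighted_mean_map(list(m1), 1)$values, m1$values)
  # convexity on random members; nodata propagates
  withr::with_seed(41, {
    maps <- lapply(1:4, function(i) layer_of(runif(10)))
    w <- runif(4); w <- w / sum(w)
    wm <- weighted_mean_map(maps, w)
    lo <- do.call(pmin, lapply(maps, function(m) as.numeric(m$values)))
    hi <- do.call(pmax, lapply(maps, function(m) as.numeric(m$values)))
    expect_true(all(wm$values >= lo - 1e-12 & wm$values <= hi + 1e-12))
  })
  m_na <- layer_of(c(NA, 0.5))
  expect_true(is.na(weighted_mean_map(list(m1, m_na),
                                      c(0.5, 0.5))$values[1, 1]))
})

test_that("the CV map is zero iff members agree, and is scale invariant", {
  m <- layer_of(c(0.3, 0.7))
  expect_true(all(cv_map(list(m, m, m))$values == 0))
  cv <- cv_map(list(layer_of(c(0.4, 0.4)), layer_of(c(0.6, 0.6))))
  expect_equal(cv$values[1, 1], 100 * sqrt(0.02) / 0.5, tolerance = 1e-12)
  expect_equal(cv$values[1, 1], 28.2843, tolerance = 1e-4)
  scaled <- cv_map(list(layer_of(c(0.04, 0.04)), layer_of(c(0.06, 0.06))))
  expect_equal(scaled$values, cv$values)
  expect_error(cv_map(list(m)), "at least 2")
})

test_that("ensemble predictions are convex in members and score perfectly on a separable toy", {
  te <- toy_ensemble()
  ev <- ensemble_evaluate(te$ensemble, te$table)
  expect_equal(ev$TSS, 1)
  expect_equal(ev$ROC, 1)
  p_members <- vapply(te$ensemble$members,
                      function(m) predict_learner(m$fitted, te$table),
                      numeric(nrow(te$table)))
  p_ens <- ensemble_predict(te$ensemble, te$table)
  expect_true(all(p_ens >= apply(p_members, 1, min) - 1e-12))
  expect_true(all(p_ens <= apply(p_members, 1, max) + 1e-12))
})

test_that("permutation importance zeroes unused predictors and sums to 100", {
  tab <- separable_table(60)
  tab$x3 <- 5  # constant: no tree can ever split on it
  runs <- lapply(c(7, 8), function(s)
    fit_and_score(learner_spec("random_forest", seed = s), tab,
                  split_seed = s))
  ens <- build_ensemble(runs)
  imp <- variable_importance(ens, tab, n_shuffles = 5, seed = 3)
  expect_equal(imp$raw[imp$predictor == "x3"], 0)
  expect_equal(sum(imp$percent), 100, tolerance = 1e-9)
  expect_equal(imp$predictor[which.max(imp$percent)], "x1")
})

test_that("raw importances standardize by the proportional percentage mapping", {
  expect_equal(standardize_importance(c(0.02, 0.74, 0.20, 0.04)),
               c(2, 74, 20, 4))
  expect_equal(sum(standardize_importance(runif(7, 0.1, 2))), 100)
  expect_error(standardize_importance(c(-0.1, 0.5)))
})

test_that("importance estimates stabilize as shuffles accumulate", {
  te <- toy_ensemble()
  i1 <- variable_importance(te$ensemble, te$table, n_shuffles = 50, seed = 1)
  i2 <- variable_importance(te$ensemble, te$table, n_shuffles = 50, seed = 2)
  expect_true(all(abs(i1$percent - i2$percent) < 5))
})
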