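test_that("smooth fields honor mean/sd, seeds, and zero-variance degeneracy", {
  g <- grid_spec(40, 40, 0, 20, 0.5)
  p <- field_params(g, mean = c(10, 0), sd = c(2, 0),
                    correlation_length = 3, seed = 5)
  s1 <- gen_smooth_fields(p, c("a", "b"))
  s2 <- gen_smooth_fields(p, c("a", "b"))
  expect_identical(s1$layers$a$values, s2$layers$a$values)
  expect_equal(mean(s1$layers$a$values), 10, tolerance = 1e-9)
  expect_equal(stats::sd(s1$layers$a$values), 2, tolerance = 1e-9)
  expect_true(all(s1$layers$b$values == 0))    # sd = 0 -> constant at mean
})

test_that("requested inter-field correlation is realized empirically", {
  g <- grid_spec(100, 100, 0, 50, 0.5)
  s <- gen_smooth_fields(field_params(g, sd = 1, correlation_length = 4,
                                      inter_field_correlation = 0.9,
                                      seed = 13),
                         c("a", "b"))
  r <- stats::cor(as.numeric(s$layers$a$values),
                  as.numeric(s$layers$b$values))
  expect_gt(r, 0.8)
  expect_lt(r, 0.97)
})

test_that("monthly precipitation respects variability and degenerate limits", {
  g <- grid_spec(8, 8, 0, 4, 0.5)
  flat <- gen_monthly_precip(g, 5, 600, interannual_log_sd = 0, seed = 2)
  q <- hellmann_eberle(flat)
  expect_true(all(q$values == 1))
  zero <- gen_monthly_precip(g, 3, 0, interannual_log_sd = 0.5, seed = 2)
  expect_true(all(zero$values == 0))
  # annual totals recombine to the generated totals
  s <- gen_monthly_precip(g, 4, 500, interannual_log_sd = 0.4,
                          seasonality = 0.8, seed = 3)
  expect_true(all(s$values >= 0))
  at <- annual_totals(s)
  expect_equal(at$n_complete$values, matrix(4, 8, 8))
})

test_that("58-year strongly variable rainfall yields median quotient above 5", {
  g <- grid_spec(20, 20, 0, 10, 0.5)
  s <- gen_monthly_precip(g, 58, 400, interannual_log_sd = 0.8, seed = 19)
  med_q <- stats::median(hellmann_eberle(s)$values)
  expect_gt(med_q, 5)
})

test_that("true suitability composes response curves as a bounded product", {
  g <- toy_grid(1, 1, 1, 0, 1)
  stk <- raster_stack(list(constant_layer(g, 5, "t"),
                           constant_layer(g, 800, "p")))
  flat_truth <- synthetic_truth(
    list(t = list(type = "logistic", midpoint = -99, slope = 10)),
    prevalence_scale = 0.3)
  expect_equal(true_suitability(stk, flat_truth)$values[1, 1], 0.3,
               tolerance = 1e-6)
  mid <- synthetic_truth(list(t = list(type = "logistic", midpoint = 5,
                                       slope = 2)))
  expect_equal(true_suitability(stk, mid)$values[1, 1], 0.5)
  center <- synthetic_truth(list(p = list(type = "gaussian", center = 800,
                                          width = 100)))
  expect_equal(true_suitability(stk, center)$values[1, 1], 1)
  expect_error(synthetic_truth(list(t = list(type = "flat"))), "non-flat")
  expect_error(true_suitability(raster_stack(list(constant_layer(g, 1, "z"))),
                                mid), "missing")
})

test_that("presence sampling follows the suitability surface deterministically", {
  g <- grid_spec(10, 10, 0, 10, 1)
  v <- matrix(1, 10, 10)
  v[6:10, ] <- 0                          # south half unsuitable
  s <- raster_layer(g, v, name = "s")
  occ <- sample_presences(s, 300, seed = 4)
  expect_equal(nrow(occ$records), 300)
  expect_true(all(occ$records$lat > 5))   # no southern records
  occ2 <- sample_presences(s, 300, seed = 4)
  expect_identical(occ$records, occ2$records)
  expect_error(sample_presences(raster_layer(g, v * 0, name = "s"), 10),
               "zero")
})

test_that("uniform suitability gives a spatially uniform sample", {
  g <- grid_spec(10, 10, 0, 10, 1)
  s <- constant_layer(g, 1, "s")
  occ <- sample_presences(s, 5000, seed = 6)
  cc <- cell_of(g, occ$records$lon, occ$records$lat)
  counts <- table(factor(paste(cc$row, cc$col),
                         levels = as.vector(outer(1:10, 1:10, paste))))
  p <- stats::chisq.test(as.numeric(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("effort bias concentrates records where thinning then caps them", {
  g <- grid_spec(10, 10, 0, 10, 0.25)      # whole grid spans 2.5 degrees
  s <- constant_layer(g, 1, "s")
  bias <- raster_layer(g, matrix(c(1000, rep(0.01, 99)), 10), name = "b")
  occ <- sample_presences(s, 200, bias = bias, seed = 7)
  thinned <- thin_per_cell(occ, cell_size = 1, max_per_cell = 5, seed = 8)
  cc <- floor(thinned$records$lon) * 100 + floor(thinned$records$lat)
  expect_true(all(table(cc) <= 5))
  expect_lt(nrow(thinned$records), nrow(occ$records))
})
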