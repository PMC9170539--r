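series_from_totals <- function(totals_by_year, grid = toy_grid(1, 1, 1, 0, 1)) {
  # spread each annual total evenly over 12 months at every cell
  ny <- length(totals_by_year)
  vals <- array(NA_real_, c(grid$n_rows, grid$n_cols, 12, ny))
  for (y in seq_len(ny)) vals[, , , y] <- totals_by_year[y] / 12
  monthly_precip_series(grid, vals, 2000 + seq_len(ny) - 1)
}

test_that("annual totals sum complete years and drop incomplete ones per cell", {
  g <- toy_grid(1, 2, 1, 0, 1)
  vals <- array(10, c(1, 2, 12, 2))
  vals[1, 2, 5, 1] <- NA           # cell 2, year 1 incomplete
  vals[, , , 2] <- 25              # year 2: 300 mm everywhere
  s <- monthly_precip_series(g, vals, c(2000, 2001))
  at <- annual_totals(s)
  expect_equal(at$per_year[["2000"]]$values[1, 1], 120)  # 12 x 10 mm
  expect_true(is.na(at$per_year[["2000"]]$values[1, 2]))
  expect_equal(at$per_year[["2001"]]$values[1, 2], 300)
  # cell 1: complete years 120 and 300 -> mean 210; cell 2: only 300
  expect_equal(at$mean_annual$values[1, 1], 210)
  expect_equal(at$mean_annual$values[1, 2], 300)
  expect_equal(at$n_complete$values[1, ], c(2, 1))
})

test_that("mean annual over two complete years is their mean", {
  at <- annual_totals(series_from_totals(c(300, 500)))
  expect_equal(at$mean_annual$values[1, 1], 400)
})

test_that("Hellmann-Eberle quotient is the wettest/driest-year ratio", {
  expect_equal(hellmann_eberle(series_from_totals(c(300, 600, 450)))$values[1, 1], 2)
  expect_equal(hellmann_eberle(series_from_totals(c(400, 400, 400)))$values[1, 1], 1)
  # a zero-rain driest year is masked, not infinite
  expect_true(is.na(hellmann_eberle(series_from_totals(c(0, 400)))$values[1, 1]))
})

test_that("quotient needs two complete years and respects its invariants", {
  g <- toy_grid(1, 1, 1, 0, 1)
  vals <- array(10, c(1, 1, 12, 2))
  vals[1, 1, 3, 2] <- NA  # only one complete year remains
  q <- hellmann_eberle(monthly_precip_series(g, vals, c(2000, 2001)))
  expect_true(is.na(q$values[1, 1]))
  withr::with_seed(3, {
    for (k in 1:20) {
      totals <- stats::rlnorm(8, log(400), 0.6)
      q1 <- hellmann_eberle(series_from_totals(totals))$values[1, 1]
      expect_gte(q1, 1)
      # invariant to positive rescaling of all years
      q2 <- hellmann_eberle(series_from_totals(totals * 3.7))$values[1, 1]
      expect_equal(q2, q1, tolerance = 1e-12)
    }
  })
})

test_that("median quotient grows with inter-annual log-sd", {
  g <- grid_spec(12, 12, 0, 6, 0.5)
  med_q <- vapply(c(0.2, 0.5, 0.8), function(sig) {
    s <- gen_monthly_precip(g, n_years = 20, mean_annual = 400,
                            interannual_log_sd = sig, seed = 21)
    stats::median(hellmann_eberle(s)$values, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_q) > 0))
})

test_that("the Ellenberg flag marks dry AND unpredictable cells only", {
  g <- toy_grid(1, 3, 3, 0, 1)
  p <- raster_layer(g, matrix(c(400, 400, 600), 1), name = "map")
  q <- raster_layer(g, matrix(c(6, 4, 10), 1), name = "q")
  e <- ellenberg_index(p, q)
  expect_equal(as.numeric(e$values), c(1, 0, 0))
  expect_error(ellenberg_index(p, constant_layer(toy_grid(), 6)), "grid")
  # nodata in either input propagates
  p2 <- raster_layer(g, matrix(c(NA, 400, 600), 1), name = "map")
  expect_true(is.na(ellenberg_index(p2, q)$values[1, 1]))
})

test_that("aridity and R indices are masked ratios", {
  g <- toy_grid(1, 3, 3, 0, 1)
  p <- raster_layer(g, matrix(c(500, 800, 300), 1), name = "p")
  pet <- raster_layer(g, matrix(c(1000, 800, 0), 1), name = "pet")
  ai <- aridity_index(p, pet)
  expect_equal(ai$values[1, 1:2], c(0.5, 1))
  expect_true(is.na(ai$values[1, 3]))          # PET = 0 masked
  aet <- raster_layer(g, matrix(c(300, 800, NA), 1), name = "aet")
  pet2 <- raster_layer(g, matrix(c(1200, 800, 500), 1), name = "pet")
  ri <- r_index(aet, pet2)
  expect_equal(ri$values[1, 1:2], c(0.25, 1))
  expect_true(is.na(ri$values[1, 3]))          # AET nodata propagates
  aet_hi <- raster_layer(g, matrix(c(1300, 800, 400), 1), name = "aet")
  expect_warning(r_index(aet_hi, pet2), "AET exceeds PET")
})

test_that("monthly series round-trip through a YYYY-MM directory", {
  g <- toy_grid(2, 2, 2, 0, 1)
  s <- gen_monthly_precip(g, 3, 500, 0.3, seed = 4, start_year = 1990)
  dir <- withr::local_tempdir()
  write_monthly_precip(s, dir)
  back <- read_monthly_precip(dir)
  expect_equal(back$years, 1990:1992)
  expect_equal(back$values, s$values)
})
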