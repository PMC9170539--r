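test_that("grid_spec validates its invariants", {
  expect_error(grid_spec(4, 4, 0, 4, 0), "cell_size")
  expect_error(grid_spec(0, 4, 0, 4, 1), "n_rows")
  expect_error(grid_spec(4, 4, 200, 4, 1), "lon_origin")
  expect_error(grid_spec(200, 4, 0, 4, 1), "south")
})

test_that("point-to-cell mapping follows the half-open NW-origin convention", {
  g <- toy_grid()
  # NW corner belongs to cell (1,1); a shared south/east edge to the next cell
  expect_equal(cell_of(g, 0, 4), data.frame(row = 1L, col = 1L))
  expect_equal(cell_of(g, 1, 4), data.frame(row = 1L, col = 2L))   # east edge
  expect_equal(cell_of(g, 0, 3), data.frame(row = 2L, col = 1L))   # south edge
  expect_equal(cell_of(g, 0.5, 3.5), data.frame(row = 1L, col = 1L))
  expect_true(is.na(cell_of(g, -0.1, 3.5)$col))
  expect_true(is.na(cell_of(g, 0.5, 0)$row))  # south boundary is outside
})

test_that("resampling a constant layer gives a constant layer", {
  src <- constant_layer(toy_grid(), 7)
  tgt <- grid_spec(8, 8, 0, 4, 0.5)
  for (m in c("bilinear", "nearest")) {
    out <- resample_to(src, tgt, m)
    expect_true(all(out$values == 7))
  }
})

test_that("bilinear refinement of a west-east gradient is monotone and bounded", {
  g <- grid_spec(2, 2, 0, 2, 1)
  src <- raster_layer(g, matrix(c(0, 0, 1, 1), 2, 2), name = "grad")
  fine <- resample_to(src, grid_spec(4, 4, 0, 2, 0.5), "bilinear")
  expect_true(all(fine$values >= 0 & fine$values <= 1))
  for (i in 1:4) expect_true(all(diff(fine$values[i, ]) >= 0))
})

test_that("resampling onto the source grid is the identity, nodata intact", {
  g <- toy_grid()
  v <- matrix(rnorm(16), 4, 4)
  v[(row(v) + col(v)) %% 2 == 0] <- NA  # checkerboard nodata
  src <- raster_layer(g, v, name = "cb")
  for (m in c("bilinear", "nearest"))
    expect_identical(resample_to(src, g, m)$values, v)
})

test_that("bilinear output never leaves the source value range", {
  withr::with_seed(99, {
    for (k in 1:5) {
      g <- grid_spec(6, 6, 0, 6, 1)
      src <- raster_layer(g, matrix(rnorm(36), 6, 6), name = "r")
      out <- resample_to(src, grid_spec(17, 17, -0.5, 6.5, 0.4), "bilinear")
      expect_gte(min(out$values, na.rm = TRUE), min(src$values))
      expect_lte(max(out$values, na.rm = TRUE), max(src$values))
    }
  })
})

test_that("non-overlapping grids are rejected", {
  src <- constant_layer(toy_grid(), 1)
  expect_error(resample_to(src, grid_spec(4, 4, 100, 4, 1)), "overlap")
})

test_that("collinearity screen flags duplicates and negations, not noise", {
  g <- grid_spec(100, 100, 0, 50, 0.5)
  withr::with_seed(7, {
    a <- matrix(rnorm(10000), 100)
    b <- matrix(rnorm(10000), 100)
  })
  stk <- raster_stack(list(raster_layer(g, a, name = "a"),
                           raster_layer(g, a, name = "a_copy"),
                           raster_layer(g, -a, name = "neg_a"),
                           raster_layer(g, b, name = "b")))
  sc <- collinearity_screen(stk, threshold = 0.7)
  pair <- function(x, y) sc$pairs[(sc$pairs$var1 == x & sc$pairs$var2 == y) |
                                    (sc$pairs$var1 == y & sc$pairs$var2 == x), ]
  expect_equal(pair("a", "a_copy")$r, 1)
  expect_true(pair("a", "a_copy")$flagged)
  expect_equal(pair("a", "neg_a")$r, -1)
  expect_true(pair("a", "neg_a")$flagged)
  expect_lt(abs(pair("a", "b")$r), 0.05)   # independent white noise, n = 1e4
  expect_false(pair("a", "b")$flagged)
  expect_equal(sc$r, t(sc$r))
})

test_that("ASCII grid write/read round-trips values and grid metadata exactly", {
  g <- grid_spec(5, 3, -10.25, 42.5, 0.125)
  v <- matrix(rnorm(15), 5, 3)
  v[2, 2] <- NA
  lay <- raster_layer(g, v, name = "rt")
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(lay, path)
  back <- read_ascii_grid(path, name = "rt")
  expect_identical(back$values, v)
  expect_true(sdmensemble:::grid_equal(back$grid, g))
})

test_that("a stack round-trips through a manifest directory", {
  g <- toy_grid()
  stk <- raster_stack(list(constant_layer(g, 1, "one"),
                           constant_layer(g, 2, "two")))
  dir <- withr::local_tempdir()
  man <- write_stack(stk, dir)
  back <- read_stack_manifest(file.path(dir, "manifest.csv"))
  expect_equal(names(back$layers), c("one", "two"))
  expect_identical(back$layers$two$values, stk$layers$two$values)
})
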