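test_that("ASCII grid round trip preserves values and mask", {
  spec <- tiny_spec()
  l <- grid_layer(spec, matrix(1:4, 2, 2, byrow = TRUE), "demo")
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(l, p)
  back <- read_ascii_grid(p)
  expect_equal(back$values, l$values)
  expect_equal(back$spec$cell_size, spec$cell_size)
  expect_identical(back$name, sub("\\.asc$", "", basename(p)))

  # masked cell round trip
  lm <- grid_layer(spec, matrix(c(1, NA, 3, 4), 2, 2, byrow = TRUE))
  write_ascii_grid(lm, p)
  back <- read_ascii_grid(p)
  expect_identical(is.na(back$values), is.na(lm$values))
  expect_equal(back$values[!is.na(back$values)], lm$values[!is.na(lm$values)])

  # degenerate layers survive: constant zero and all-masked
  for (vals in list(matrix(0, 2, 2), matrix(NA_real_, 2, 2))) {
    write_ascii_grid(grid_layer(spec, vals), p)
    expect_equal(read_ascii_grid(p)$values, vals)
  }

  # fractional values survive at printed precision
  set.seed(42)
  lf <- grid_layer(spec, matrix(runif(4), 2, 2))
  write_ascii_grid(lf, p)
  expect_equal(read_ascii_grid(p)$values, lf$values, tolerance = 1e-12)
})

test_that("explicit nodata sentinel cells are masked on read", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 1", "NODATA_value -9999",
               "1 -9999", "3 4"), p)
  l <- read_ascii_grid(p)
  expect_equal(sum(is.finite(l$values)), 3)
  expect_true(is.na(l$values[1, 2]))
})

test_that("malformed ASCII inputs raise informative errors", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("NCOLS 3", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 1", "1 2 3 4 5 6 7 8"), p)
  expect_error(read_ascii_grid(p), "dimension error")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "CELLSIZE 1",
               "1 2", "3 4"), p)
  expect_error(read_ascii_grid(p), "YLLCORNER")
  writeLines(c("NCOLS 2", "NROWS 2", "XLLCORNER 0", "YLLCORNER 0",
               "CELLSIZE 1", "DX 0.5", "DY 1", "1 2", "3 4"), p)
  expect_error(read_ascii_grid(p), "non-square")
})

test_that("grid_spec rejects invalid geometry", {
  expect_error(grid_spec(0, 2, 0, 0, 1), "n_rows")
  expect_error(grid_spec(2, 2, 0, 0, -1), "cell_size")
  expect_error(grid_spec(2, 2, 0, 89.5, 1), "latitude")
  expect_error(grid_spec(2, 2, 179.5, 0, 1), "longitude")
})

test_that("cell areas follow the spherical band formula", {
  R <- 6371
  # 1x1 degree cell with bottom edge on the equator
  spec <- grid_spec(1, 1, 0, 0, 1)
  oracle <- R^2 * (pi / 180) * (sin(1 * pi / 180) - sin(0))
  expect_equal(cell_areas(spec)$values[1, 1], oracle, tolerance = 1e-12)
  expect_equal(oracle, 12364, tolerance = 1e-4)

  # hemispheric symmetry: band [10,11] equals band [-11,-10]
  north <- cell_areas(grid_spec(1, 1, 0, 10, 1))$values[1, 1]
  south <- cell_areas(grid_spec(1, 1, 0, -11, 1))$values[1, 1]
  expect_equal(north, south, tolerance = 1e-12)

  # a full longitude ring sums to the closed-form band area
  spec <- grid_spec(1, 360, -180, 30, 1)
  band <- 2 * pi * R^2 * (sin(31 * pi / 180) - sin(30 * pi / 180))
  expect_equal(sum(cell_areas(spec)$values), band, tolerance = 1e-9)
})

test_that("cell areas shrink towards the poles and sum to the sphere", {
  spec <- grid_spec(45, 10, 0, -90, 4)  # pole to pole, one column band
  a <- cell_areas(spec)$values[, 1]
  lat_mid <- abs(spec$y_max - (seq_len(45) - 0.5) * 4)
  expect_true(all(diff(a[order(lat_mid)]) <= 1e-9))
  # full globe at 4 degrees: total area within 0.1% of 4 pi R^2
  glob <- grid_spec(45, 90, -180, -90, 4)
  expect_equal(sum(cell_areas(glob)$values), 4 * pi * 6371^2,
               tolerance = 1e-3)
  expect_true(all(cell_areas(glob)$values > 0))
})

test_that("point-to-cell mapping uses half-open cells from the north-west", {
  spec <- grid_spec(2, 2, 0, 0, 1)
  # cell ids are column-major with row 1 = north
  expect_equal(cell_of(spec, 0.5, 1.5), 1L)   # NW cell
  expect_equal(cell_of(spec, 0.5, 0.5), 2L)   # SW
  expect_equal(cell_of(spec, 1.5, 1.5), 3L)   # NE
  # an interior edge point belongs to the cell whose index floors it
  expect_equal(cell_of(spec, 1, 0.25), 4L)    # lon edge -> east column
  expect_equal(cell_of(spec, 0.5, 1), 1L)     # lat edge -> upper cell
  expect_true(is.na(cell_of(spec, 2.5, 0.5))) # outside
  # centres invert the mapping
  ctr <- cell_centers(spec)
  expect_equal(cell_of(spec, ctr$lon, ctr$lat), 1:4)
})

test_that("climate stacks enforce co-registration and joint masks", {
  spec <- tiny_spec()
  a <- grid_layer(spec, matrix(c(1, 2, NA, 4), 2, 2), "a")
  b <- grid_layer(spec, matrix(c(NA, 2, 3, 4), 2, 2), "b")
  st <- climate_stack(list(a, b))
  expect_setequal(valid_cells(st), c(2L, 4L))
  m <- stack_matrix(st, c(2L, 4L))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(colnames(m), c("a", "b"))
  expect_error(climate_stack(list(a, grid_layer(tiny_spec(3), matrix(0, 3, 3), "c"))),
               "same grid")
  expect_error(climate_stack(list(a, grid_layer(spec, matrix(0, 2, 2), "a"))),
               "duplicate")
})
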