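write_occ_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                             .local_envir = parent.frame())) {
  writeLines(rows, path)
  path
}

test_that("occurrence CSVs are read, cleaned and reported", {
  p <- write_occ_csv(c(
    "species,decimalLongitude,decimalLatitude,basisOfRecord",
    "spA,10.5,45.2,HUMAN_OBSERVATION",
    "spA,11.0,,PRESERVED_SPECIMEN",   # blank latitude -> dropped
    "spA,12.2,44.0,x",
    "spA,13.1,43.5,x",
    "spA,14.9,42.1,x"))
  occ <- read_occurrences(p, species = "spA")
  expect_s3_class(occ, "occurrence_set")
  expect_equal(nrow(occ$points), 4)
  expect_equal(occ$cleaning$dropped_missing, 1)

  # out-of-range longitude dropped and counted separately
  p2 <- write_occ_csv(c("species,decimalLongitude,decimalLatitude",
                        "spB,200,10", "spB,20,10"))
  occ2 <- read_occurrences(p2, species = "spB")
  expect_equal(nrow(occ2$points), 1)
  expect_equal(occ2$cleaning$dropped_range, 1)

  # header only -> empty set with warning
  p3 <- write_occ_csv("species,decimalLongitude,decimalLatitude")
  expect_warning(occ3 <- read_occurrences(p3, species = "spC"), "no occurrence")
  expect_equal(nrow(occ3$points), 0)

  # column aliases, case-insensitively
  p4 <- write_occ_csv(c("SPECIES,lon,LAT", "spD,1,2"))
  expect_equal(nrow(read_occurrences(p4)$points), 1)

  # missing columns named in the error
  p5 <- write_occ_csv(c("species,decimalLongitude", "spE,1"))
  expect_error(read_occurrences(p5), "decimalLatitude")
})

test_that("cleaning is idempotent", {
  p <- write_occ_csv(c("species,decimalLongitude,decimalLatitude",
                       "sp,10,45", "sp,900,45", "sp,11,notanumber"))
  occ <- read_occurrences(p, species = "sp")
  # re-ingesting the cleaned points drops nothing further
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(species = "sp",
                              decimalLongitude = occ$points$lon,
                              decimalLatitude = occ$points$lat),
                   p2, row.names = FALSE)
  occ2 <- read_occurrences(p2, species = "sp")
  expect_equal(occ2$points, occ$points)
  expect_equal(occ2$cleaning$dropped_missing + occ2$cleaning$dropped_range, 0)
})

test_that("thinning keeps one record per cell and drops masked cells", {
  spec <- tiny_spec()  # 2x2 from (-10,0), cell 1
  occ <- occurrence_set("sp", lon = c(-9.7, -9.6, -8.5, -9.5),
                        lat = c(1.5, 1.4, 0.5, 0.5))
  th <- thin_to_cells(occ, spec)
  expect_equal(nrow(th$points), 3)  # first two share the NW cell
  expect_equal(th$points$lon[1], -9.7)  # first record kept

  # masked cell removal via stack
  st <- random_stack(spec, mask = cell_of(spec, -8.5, 0.5))
  th2 <- thin_to_cells(occ, spec, st)
  expect_equal(nrow(th2$points), 2)

  # identity on distinct valid cells
  spec10 <- grid_spec(10, 10, 0, 0, 1)
  occ10 <- occurrence_set("sp", lon = (1:10) - 0.5, lat = (1:10) - 0.5)
  expect_equal(nrow(thin_to_cells(occ10, spec10)$points), 10)
  # and idempotence
  expect_equal(thin_to_cells(thin_to_cells(occ, spec), spec)$points,
               thin_to_cells(occ, spec)$points)
})

test_that("train/test split is exhaustive, disjoint and seed-stable", {
  occ <- occurrence_set("sp", lon = runif(100, 0, 10), lat = runif(100, 0, 10))
  sp <- split_train_test(occ, 0.75, seed = 11)
  expect_equal(nrow(sp$train$points), 75)
  expect_equal(nrow(sp$test$points), 25)
  all_pts <- rbind(sp$train$points, sp$test$points)
  expect_equal(all_pts[order(all_pts$lon), ],
               occ$points[order(occ$points$lon), ],
               ignore_attr = TRUE)

  # rounding keeps both parts non-empty
  occ4 <- occurrence_set("sp", lon = 1:4, lat = 1:4)
  sp4 <- split_train_test(occ4, 0.75, seed = 1)
  expect_equal(nrow(sp4$train$points), 3)
  expect_equal(nrow(sp4$test$points), 1)
  occ2 <- occurrence_set("sp", lon = 1:2, lat = 1:2)
  sp2 <- split_train_test(occ2, 0.99, seed = 1)
  expect_equal(nrow(sp2$train$points), 1)

  # same seed -> identical membership; error below 2 records
  again <- split_train_test(occ, 0.75, seed = 11)
  expect_identical(again$train$points, sp$train$points)
  expect_error(split_train_test(occurrence_set("sp", 1, 1), seed = 1),
               "at least 2")
})
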