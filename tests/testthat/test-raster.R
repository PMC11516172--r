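test_that("write/read round-trips values, mask and geometry", {
  set.seed(1)
  v <- matrix(runif(120), 10, 12)
  v[c(3, 47, 100)] <- NA
  g <- raster_grid(v, cell_size = 250, origin = c(1000, 5000), crs = "utm-synthetic")
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, path)
  back <- read_raster(path)
  expect_equal(back$values, g$values, tolerance = 1e-9)
  expect_identical(is.na(back$values), is.na(g$values))
  expect_equal(back$cell_size, 250)
  expect_equal(back$origin, c(1000, 5000))
  expect_identical(back$crs, "utm-synthetic")

  # integer (categorical) grids round-trip bit-exactly, with their legend
  vi <- matrix(sample(1:4, 56, replace = TRUE), 7, 8)
  vi[2, 3] <- NA
  gi <- raster_grid(vi * 1.0, cell_size = 30, legend = c("1" = "a", "2" = "b", "3" = "c", "4" = "d"))
  path2 <- withr::local_tempfile(fileext = ".asc")
  write_raster(gi, path2)
  backi <- read_raster(path2)
  expect_identical(backi$values, gi$values)
  expect_identical(backi$legend, gi$legend)
})

test_that("nodata cells are masked on read", {
  v <- matrix(1:25 * 1.0, 5, 5)
  v[c(2, 13, 25)] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(raster_grid(v, 10), path)
  expect_identical(sum(is.na(read_raster(path)$values)), 3L)
})

test_that("missing files, missing georeferencing and degree CRS are rejected", {
  expect_error(read_raster("/nonexistent/file.asc"), "does not exist")
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(grid_of(matrix(1, 4, 4)), path)
  file.remove(paste0(path, ".json"))
  expect_error(read_raster(path), "georeferencing")
  expect_error(raster_grid(matrix(1, 4, 4), 100, crs = "EPSG:4326"), "geographic")
  expect_error(raster_grid(matrix(1, 4, 4), 100, crs = "longlat-wgs84"), "geographic")
})

test_that("stacking rejects misaligned layers", {
  a <- grid_of(matrix(1, 5, 5), cell_size = 100)
  b <- grid_of(matrix(2, 5, 5), cell_size = 50)
  expect_error(raster_stack(list(a = a, b = b)), "not aligned")
  d <- raster_grid(matrix(2, 5, 5), 100, origin = c(10, 500))
  expect_error(raster_stack(list(a = a, d = d)), "not aligned")
  expect_error(raster_stack(list(a, b)), "names")
  expect_silent(raster_stack(list(a = a, b2 = grid_of(matrix(2, 5, 5), 100))))
})

test_that("point extraction samples the containing cell", {
  nr <- 6; nc <- 8; cs <- 100
  rowl <- grid_of(matrix(rep(1:nr, nc), nr, nc), cs)
  coll <- grid_of(matrix(rep(1:nc, each = nr), nr, nc), cs)
  stack <- raster_stack(list(row_idx = rowl, col_idx = coll))
  # random interior points: extracted indices must match direct arithmetic
  set.seed(7)
  pts <- tibble::tibble(x = runif(50, 0, nc * cs), y = runif(50, 0, nr * cs))
  got <- extract_at_points(stack, pts, quiet = TRUE)
  expect_identical(nrow(got), 50L)
  expect_equal(got$col_idx, floor(pts$x / cs) + 1)
  expect_equal(got$row_idx, floor((nr * cs - pts$y) / cs) + 1)
})

test_that("shared-edge points map to the cell right/below (half-open rule)", {
  g <- grid_of(matrix(1:16 * 1.0, 4, 4), cell_size = 100)
  stack <- raster_stack(list(v = g))
  # x = 100 is the edge between columns 1 and 2 -> column 2 (right);
  # y = 300 is the edge between rows 1 and 2 -> row 2 (below)
  got <- extract_at_points(stack, tibble::tibble(x = 100, y = 300), quiet = TRUE)
  expect_equal(got$v, g$values[2, 2])
})

test_that("nodata and out-of-extent points are dropped and counted", {
  v <- matrix(5, 4, 4)
  v[2, 2] <- NA
  stack <- raster_stack(list(v = grid_of(v, 100)))
  pts <- tibble::tibble(
    x = c(150, 250, 5000), # cell (2,2) nodata; valid; outside
    y = c(250, 250, 250)
  )
  got <- extract_at_points(stack, pts, quiet = TRUE)
  expect_identical(nrow(got), 1L)
  expect_equal(got$v, 5)
  dropped <- attr(got, "dropped")
  expect_equal(dropped$n[dropped$reason == "nodata_cell"], 1)
  expect_equal(dropped$n[dropped$reason == "outside_extent"], 1)
  expect_error(
    extract_at_points(stack, tibble::tibble(x = -1000, y = -1000), quiet = TRUE),
    "outside the stack extent"
  )
})

test_that("constant layers extract as constants", {
  stack <- constant_stack(values = c(lyr = 5))
  pts <- tibble::tibble(x = runif(10, 0, 600), y = runif(10, 0, 600))
  expect_true(all(extract_at_points(stack, pts, quiet = TRUE)$lyr == 5))
})

test_that("occurrence validation enforces seasons and labels", {
  expect_error(occurrence_set(1, 1, season = "winter"), "winter is excluded")
  expect_error(
    occurrence_set(1, 1, season = "spring", label = "maybe"),
    "Unsupported label"
  )
  pts <- occurrence_set(c(1, 2), c(3, 4), season = "summer")
  expect_s3_class(pts, "occurrence_set")
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(pts, path)
  expect_equal(read_occurrences(path)$x, c(1, 2))
})
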