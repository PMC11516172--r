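test_that("greedy thinning keeps the first point and drops near neighbors", {
  pts <- occurrence_set(c(0, 250, 600), c(0, 0, 0), season = "spring")
  kept <- thin_points(pts, 300)
  expect_equal(kept$x, c(0, 600))
  expect_identical(attr(kept, "n_dropped"), 1L)
})

test_that("thinning at distance zero is the identity and deduplicates coincident points", {
  pts <- occurrence_set(c(5, 5, 9), c(1, 1, 2), season = "summer")
  expect_equal(thin_points(pts, 0)$x, c(5, 5, 9))
  expect_equal(nrow(thin_points(pts, 1e-6)), 2L)
})

test_that("thinning is invariant to appending points that would be dropped anyway", {
  set.seed(21)
  for (rep in 1:5) {
    pts <- occurrence_set(runif(40, 0, 2000), runif(40, 0, 2000), season = "spring")
    kept <- thin_points(pts, 300)
    # points within 300 m of a kept point would always be dropped
    extra <- kept[sample.int(nrow(kept), 5, replace = TRUE), ]
    extra$x <- extra$x + runif(5, -50, 50)
    extra$y <- extra$y + runif(5, -50, 50)
    again <- thin_points(dplyr::bind_rows(pts, extra), 300)
    expect_equal(again$x, kept$x)
    expect_equal(again$y, kept$y)
  }
})

test_that("thinning respects season grouping", {
  pts <- occurrence_set(c(0, 100), c(0, 0), season = c("spring", "summer"))
  expect_equal(nrow(thin_points(pts, 300)), 2L) # different seasons never collide
})

test_that("identical columns are screened with |r| = 1 recorded", {
  x <- rnorm(50)
  rep <- correlation_screen(tibble::tibble(a = x, b = x, c = rnorm(50)), 0.85)
  expect_length(rep$kept, 2)
  expect_equal(nrow(rep$dropped), 1)
  expect_equal(rep$dropped$abs_r, 1.0)
  expect_true(rep$dropped$layer %in% c("a", "b"))
})

test_that("independent noise columns survive screening", {
  set.seed(8)
  feats <- as.data.frame(matrix(rnorm(500 * 5), 500, 5))
  rep <- correlation_screen(feats, 0.85)
  expect_equal(nrow(rep$dropped), 0)
  expect_length(rep$kept, 5)
})

test_that("three mutually identical columns leave exactly one survivor", {
  x <- rnorm(30)
  rep <- correlation_screen(tibble::tibble(a = x, b = x, c = x), 0.85)
  expect_equal(nrow(rep$dropped), 2)
  expect_length(rep$kept, 1)
})

test_that("constant columns are kept and flagged", {
  rep <- correlation_screen(tibble::tibble(a = rnorm(20), b = rnorm(20), k = rep(1, 20)), 0.85)
  expect_identical(rep$flagged_constant, "k")
  expect_true("k" %in% rep$kept)
})

test_that("no retained pair exceeds the threshold after screening", {
  set.seed(13)
  base <- rnorm(200)
  feats <- tibble::tibble(
    a = base,
    b = 0.95 * base + sqrt(1 - 0.95^2) * rnorm(200),
    c = 0.9 * base + sqrt(1 - 0.9^2) * rnorm(200),
    d = rnorm(200)
  )
  rep <- correlation_screen(feats, 0.8)
  cm <- abs(cor(feats[rep$kept]))
  diag(cm) <- 0
  expect_lte(max(cm), 0.8)
})

test_that("window diversity matches closed forms", {
  # monoclass map: H = 0 everywhere
  mono <- grid_of(matrix(3, 9, 9), legend = c("3" = "x"))
  expect_true(all(window_diversity(mono, 5)$values == 0))

  # 5x5 window holding 25 cells split equally 5 ways: H = ln 5 at the center
  v <- matrix(rep(1:5, each = 5), 5, 5) # each column-block pattern: 5 cells per class
  eq <- grid_of(v)
  expect_equal(window_diversity(eq, 5)$values[3, 3], log(5))

  # class counts (20, 5) in a full window
  v2 <- matrix(1, 5, 5)
  v2[1, ] <- 2 # 5 cells of class 2, 20 of class 1
  h <- window_diversity(grid_of(v2), 5)$values[3, 3]
  expect_equal(h, -(0.8 * log(0.8) + 0.2 * log(0.2)), tolerance = 1e-12)
  expect_equal(round(h, 4), 0.5004)
})

test_that("diversity is bounded by [0, ln K] and zero iff monoclass; nodata handled", {
  set.seed(3)
  for (rep in 1:5) {
    v <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
    g <- grid_of(v)
    h <- window_diversity(g, 3)$values
    expect_true(all(h >= 0 & h <= log(4) + 1e-12))
    # zero exactly where the 3x3 (truncated) window is monoclass
    for (cell in list(c(1, 1), c(5, 5), c(10, 10))) {
      r <- cell[1]; c <- cell[2]
      win <- v[max(1, r - 1):min(10, r + 1), max(1, c - 1):min(10, c + 1)]
      expect_identical(h[r, c] == 0, length(unique(as.vector(win))) == 1L)
    }
  }
  v <- matrix(1, 7, 7)
  v[1:3, 1:3] <- NA
  h <- window_diversity(grid_of(v), 3)$values
  expect_true(is.na(h[2, 2])) # fully-nodata window
  expect_equal(h[5, 5], 0)
})

test_that("window size is validated", {
  g <- grid_of(matrix(1, 5, 5))
  expect_error(window_diversity(g, 4), "odd")
  expect_error(window_diversity(g, 1), "odd|>= 3")
})

test_that("single-class point sets cross-tabulate to 100 percent", {
  lu <- grid_of(matrix(1, 5, 5), legend = c("1" = "A"))
  pts <- occurrence_set(runif(10, 0, 500), runif(10, 0, 500), season = "spring")
  ct <- crosstab_landuse(pts, lu)
  expect_equal(ct$class, "A")
  expect_equal(ct$frequency, 10L)
  expect_equal(ct$percentage, 100.00)
})

test_that("points on nodata cells fall into an explicit unclassified row", {
  v <- matrix(c(1, NA, 2, 2), 2, 2)
  lu <- grid_of(v, legend = c("1" = "A", "2" = "B"))
  pts <- occurrence_set(c(50, 50, 150), c(150, 50, 150), season = "spring")
  ct <- crosstab_landuse(pts, lu)
  expect_true("unclassified" %in% ct$class)
  expect_equal(sum(ct$frequency), 3L)
})

test_that("crosstab percentages follow the 100 * f / sum(f) rule to 2 decimals", {
  ct <- crosstab_table(c("a", "b", "c"), c(3, 1, 1))
  expect_equal(ct$percentage, c(60, 20, 20))
  ct2 <- crosstab_table(c("a", "b"), c(1, 2))
  expect_equal(ct2$percentage, c(33.33, 66.67))
  expect_true(abs(sum(ct2$percentage) - 100) <= 0.1)
})
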