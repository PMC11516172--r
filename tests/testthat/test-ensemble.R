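# a deterministic two-class table with a clean linear boundary
separable_table <- function(n = 200, seed = 1, noise = 0.3) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  x3 <- rnorm(n)
  lab <- as.integer(x1 + x2 + rnorm(n, sd = noise) > 0)
  # guarantee both classes comfortably populated
  feats <- tibble::tibble(x1 = x1, x2 = x2, x3 = x3)
  split_table(feats, lab, seed = seed)
}

test_that("stratified splitting hits the 70/30 arithmetic exactly", {
  feats <- tibble::tibble(a = rnorm(100), b = rnorm(100))
  lab <- rep(c(0L, 1L), each = 50)
  tab <- split_table(feats, lab, seed = 3)
  expect_identical(sum(tab$split == "train"), 70L)
  expect_identical(sum(tab$split == "test"), 30L)
  expect_identical(sum(tab$split == "train" & tab$label == 1), 35L)
  expect_identical(sum(tab$split == "test" & tab$label == 0), 15L)
  tab2 <- split_table(feats, lab, seed = 3)
  expect_identical(tab, tab2)
  expect_error(
    split_table(feats[1:59, ], c(rep(0L, 50), rep(1L, 9)), seed = 1),
    "at least 10 rows per class"
  )
})

test_that("every learner separates a linearly separable table", {
  tab <- separable_table(n = 300, seed = 7, noise = 0.2)
  fit <- suppressWarnings(fit_suite(tab, "fire6", seed = 2))
  aucs <- vapply(fit$members, `[[`, numeric(1), "auc")
  expect_true(all(aucs > 0.9))
  expect_equal(sum(fit$weights), 1)
})

test_that("permuted labels drive member AUCs toward one half", {
  set.seed(11)
  feats <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300), x3 = rnorm(300))
  lab <- sample(rep(c(0L, 1L), c(200, 100))) # labels independent of features
  tab <- split_table(feats, lab, seed = 4)
  fit <- suppressWarnings(fit_suite(tab, "fire6", seed = 5))
  aucs <- vapply(fit$members, `[[`, numeric(1), "auc")
  expect_true(all(abs(aucs - 0.5) < 0.15))
})

test_that("refitting with the same table and seed is deterministic", {
  tab <- separable_table(n = 200, seed = 9)
  f1 <- suppressWarnings(fit_suite(tab, "fire6", seed = 31))
  f2 <- suppressWarnings(fit_suite(tab, "fire6", seed = 31))
  expect_identical(
    vapply(f1$members, `[[`, numeric(1), "auc"),
    vapply(f2$members, `[[`, numeric(1), "auc")
  )
  expect_identical(f1$test_scores, f2$test_scores)
})

test_that("the sdm8 registry fits and its extra learners predict probabilities", {
  tab <- separable_table(n = 250, seed = 15, noise = 0.4)
  fit <- suppressWarnings(fit_suite(tab, "sdm8", seed = 8))
  expect_gte(length(fit$members), 6L)
  p <- predict(fit, tab[tab$split == "test", ])
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auc_score(p, tab$label[tab$split == "test"]), 0.85)
})


test_that("ensemble prediction is the AUC-weighted mean of member maps", {
  stack <- constant_stack(values = c(v = 1))
  # single member: the ensemble map equals the member map
  e1 <- constant_ensemble(0.37, 0.9)
  expect_true(all(predict_ensemble(e1, stack)$values == 0.37))
  # equal AUCs: plain mean
  e2 <- constant_ensemble(c(0.2, 0.6), c(0.8, 0.8))
  expect_equal(unique(as.vector(predict_ensemble(e2, stack)$values)), 0.4)
  # unequal AUCs: (0.9 * 0.2 + 0.6 * 0.6) / 1.5 = 0.36
  e3 <- constant_ensemble(c(0.2, 0.6), c(0.9, 0.6))
  expect_equal(unique(as.vector(predict_ensemble(e3, stack)$values)), 0.36)
})

test_that("ensemble predictions stay within member bounds and propagate nodata", {
  tab <- separable_table(n = 200, seed = 23)
  fit <- suppressWarnings(fit_suite(tab, "fire6", seed = 6))
  set.seed(31)
  nr <- 8; nc <- 8
  mk <- function() {
    v <- matrix(rnorm(nr * nc), nr, nc)
    v[1, 1] <- NA
    grid_of(v)
  }
  stack <- raster_stack(list(x1 = mk(), x2 = mk(), x3 = mk()))
  out <- predict_ensemble(fit, stack)
  expect_true(is.na(out$values[1, 1]))
  cells <- tibble::as_tibble(stack, drop_na = TRUE)
  member_p <- vapply(fit$members, function(m) as.numeric(m$predict(m$model, cells[fit$feature_vars])),
                     numeric(nrow(cells)))
  got <- out$values[cbind(cells$row, cells$col)]
  expect_true(all(got >= apply(member_p, 1, min) - 1e-12))
  expect_true(all(got <= apply(member_p, 1, max) + 1e-12))
})

test_that("a missing stack layer is reported by name", {
  tab <- separable_table(n = 200, seed = 27)
  fit <- suppressWarnings(fit_suite(tab, "fire6", seed = 2))
  stack <- raster_stack(list(x1 = grid_of(matrix(0, 4, 4)), x2 = grid_of(matrix(0, 4, 4))))
  expect_error(predict_ensemble(fit, stack), "x3")
})

test_that("importance weights sum to one and find the signal variable", {
  set.seed(41)
  n <- 400
  feats <- tibble::tibble(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  lab <- as.integer(feats$signal > 0)
  tab <- split_table(feats, lab, seed = 2)
  imp <- variable_importance(tab, seed = 3)
  expect_equal(sum(imp$weight), 1)
  expect_identical(imp$variable[1], "signal")
  expect_gt(imp$weight[1], max(imp$weight[-1]))
})

test_that("importance under a null label spreads roughly uniformly", {
  set.seed(43)
  n <- 500
  p <- 5
  feats <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * p), n, p)),
                                      paste0("v", 1:p)))
  lab <- sample(rep(c(0L, 1L), c(250, 250)))
  tab <- split_table(feats, lab, seed = 5)
  imp <- variable_importance(tab, seed = 6)
  # with AUC drops floored at zero, null weights are noisy but no variable
  # may dominate the ranking
  expect_lt(max(imp$weight), 0.6)
  expect_equal(sum(imp$weight), 1)
})

test_that("tidy and glance summarize a fitted ensemble", {
  tab <- separable_table(n = 200, seed = 3)
  fit <- suppressWarnings(fit_suite(tab, "fire6", seed = 1))
  td <- tidy(fit)
  expect_named(td, c("learner", "auc", "weight"))
  expect_equal(sum(td$weight), 1)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_gt(gl$ensemble_auc, 0.9)
})
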