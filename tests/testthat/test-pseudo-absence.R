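test_that("strict envelope contains its own training presences", {
  set.seed(2)
  feats <- tibble::tibble(a = rnorm(30), b = runif(30))
  env <- fit_envelope(feats)
  expect_true(all(score_envelope(env, feats) == 1))
  outside <- feats[1, ]
  outside$a <- max(feats$a) + 1
  expect_identical(score_envelope(env, outside), 0L)
  expect_error(fit_envelope(feats[1:4, ]), "at least 5")
})

test_that("a 5/95 trim excludes about 10 percent of uniform training values", {
  set.seed(31)
  feats <- tibble::tibble(u = runif(100))
  env <- fit_envelope(feats, trim = c(5, 95))
  frac_out <- mean(score_envelope(env, feats) == 0)
  # order statistics: ~5% below q05 plus ~5% above q95
  expect_gte(frac_out, 0.06)
  expect_lte(frac_out, 0.14)
})

test_that("Gower similarity follows the range-normalized formula", {
  train <- tibble::tibble(v = c(0, 10)) # range 10
  dom <- fit_domain(train, theta = 0.95)
  # x = 6: similarity 1 - 6/10 = 0.4 to the presence at 0 and 1 - 4/10 = 0.6
  # to the presence at 10; the domain score uses the maximum
  expect_equal(domain_similarity(dom, tibble::tibble(v = 6)), 0.6)
  expect_identical(score_domain(dom, tibble::tibble(v = 6)), 0L) # 0.6 < 0.95
  expect_identical(score_domain(dom, tibble::tibble(v = 10)), 1L) # identical cell
  expect_error(fit_domain(train, theta = 0), "in \\(0, 1\\]")
  expect_error(fit_domain(tibble::tibble(v = c(1, 1, 1))), "zero range")
})

test_that("the one-class SVM accepts the training mode and rejects far outliers", {
  set.seed(5)
  feats <- tibble::tibble(a = rnorm(200, sd = 0.5), b = rnorm(200, sd = 0.5))
  nov <- fit_novelty(feats, seed = 10)
  expect_identical(score_novelty(nov, tibble::tibble(a = 0, b = 0)), 1L)
  expect_identical(score_novelty(nov, tibble::tibble(a = 5, b = 5)), 0L)
  # determinism: refit with the same seed scores identically
  nov2 <- fit_novelty(feats, seed = 10)
  grid <- tidyr::expand_grid(a = seq(-2, 2, 0.5), b = seq(-2, 2, 0.5))
  expect_identical(score_novelty(nov, grid), score_novelty(nov2, grid))
  expect_error(fit_novelty(tibble::tibble(a = rep(1, 20), b = rnorm(20))), "Constant")
})

test_that("binary AUC agrees with exhaustive pairwise counting", {
  expect_equal(evaluate_binary_auc(c(1, 1, 1), c(0, 0)), 1.0)
  expect_equal(evaluate_binary_auc(c(1, 1), c(1, 1, 1)), 0.5)
  # presences (1,1,0) vs background (0,0,1,0): Mann-Whitney count 8.5 of 12
  expect_equal(evaluate_binary_auc(c(1, 1, 0), c(0, 0, 1, 0)), 8.5 / 12)
  expect_equal(
    pairwise_auc(c(1, 1, 0, 0, 0, 1, 0), c(1, 1, 1, 0, 0, 0, 0)),
    evaluate_binary_auc(c(1, 1, 0), c(0, 0, 1, 0))
  )
  # randomized agreement with the oracle on small binary inputs
  set.seed(17)
  for (i in 1:50) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    pos <- sample(0:1, n1, replace = TRUE)
    neg <- sample(0:1, n0, replace = TRUE)
    expect_equal(
      evaluate_binary_auc(pos, neg),
      pairwise_auc(c(pos, neg), c(rep(1, n1), rep(0, n0)))
    )
  }
  expect_error(evaluate_binary_auc(numeric(0), c(0, 1)), "non-empty")
})

test_that("the AUC gate excludes weak members and ties vote to 1", {
  m <- function(tag, vals, auc) {
    list(tag = tag, map = grid_of(matrix(vals, 2, 2)), auc = auc)
  }
  ens <- combine_presence_only(list(
    m("a", c(1, 1, 0, 0), 0.9),
    m("b", c(1, 0, 1, 0), 0.85),
    m("c", c(0, 0, 0, 0), 0.6) # below gate: must not influence the vote
  ), gate = 0.8)
  expect_identical(sum(ens$members$passed), 2L)
  # cell-wise votes of the two passing members: (2,1,1,0)/2 -> tie rule gives 1
  expect_equal(as.vector(ens$combined$values), c(1, 1, 1, 0))
  expect_equal(as.vector(ens$zero_region$values), c(0, 0, 0, 1))
  expect_error(
    combine_presence_only(list(m("a", rep(0, 4), 0.7)), gate = 0.8),
    "No presence-only member exceeds"
  )
})

test_that("an exact AUC of the gate value does not pass (strict inequality)", {
  m <- list(tag = "a", map = grid_of(matrix(0, 2, 2)), auc = 0.8)
  expect_error(combine_presence_only(list(m), gate = 0.8), "No presence-only member")
})

test_that("pseudo-absence sampling honors count, exclusions and seed", {
  zero <- grid_of(matrix(1, 20, 10))
  pa <- sample_pseudo_absences(zero, n_presence = 50, multiplier = 2, seed = 3)
  expect_identical(nrow(pa), 100L)
  expect_true(all(pa$label == "pseudo_absence"))
  pa2 <- sample_pseudo_absences(zero, n_presence = 50, multiplier = 2, seed = 3)
  expect_identical(pa, pa2)

  # a region with exactly the required number of cells is taken whole
  v <- matrix(0, 10, 10)
  v[1:20] <- 1
  pa3 <- sample_pseudo_absences(grid_of(v), n_presence = 10, seed = 1)
  expect_identical(nrow(pa3), 20L)
  rc <- firescape:::point_to_cell(grid_of(v), pa3$x, pa3$y)
  expect_true(all(v[cbind(rc$row, rc$col)] == 1))

  expect_error(
    sample_pseudo_absences(grid_of(v), n_presence = 11, seed = 1),
    "shortfall"
  )

  # presence cells are excluded from the eligible pool
  pres <- occurrence_set(c(50), c(950), season = "spring") # cell (1,1)
  v2 <- matrix(1, 10, 10)
  pa4 <- sample_pseudo_absences(grid_of(v2), n_presence = 49, multiplier = 2,
                                seed = 2, presences = pres)
  rc4 <- firescape:::point_to_cell(grid_of(v2), pa4$x, pa4$y)
  expect_false(any(rc4$row == 1 & rc4$col == 1))
})

test_that("two-step selection produces a gated ensemble and a clean sample", {
  land <- medium_landscape()
  pts <- sample_presences(land$truth, 100, "spring", seed = 2)
  sel <- suppressWarnings(
    select_pseudo_absences(land$stacks$spring, pts, seed = 5)
  )
  expect_s3_class(sel$ensemble, "presence_only_ensemble")
  expect_identical(nrow(sel$pseudo_absences), 2L * nrow(sel$presences))
  # samples never fall on a presence cell or in the combined-positive region
  comb <- sel$ensemble$combined
  rc <- firescape:::point_to_cell(comb, sel$pseudo_absences$x, sel$pseudo_absences$y)
  expect_true(all(comb$values[cbind(rc$row, rc$col)] == 0))
  rp <- firescape:::point_to_cell(comb, sel$presences$x, sel$presences$y)
  pres_cells <- paste(rp$row, rp$col)
  pa_cells <- paste(rc$row, rc$col)
  expect_length(intersect(pres_cells, pa_cells), 0)
})

test_that("the predicted-zero region is risk-depleted across seeds", {
  # over 20 seeds, the zero region's mean true risk stays below the
  # landscape mean true risk
  ok <- logical(20)
  for (s in 1:20) {
    land <- medium_landscape(200 + s)
    pts <- sample_presences(land$truth, 100, "spring", seed = 1)
    sel <- suppressWarnings(
      select_pseudo_absences(land$stacks$spring, pts, seed = 2)
    )
    risk <- land$truth$risk$spring$values
    zero <- sel$ensemble$zero_region$values == 1
    ok[s] <- mean(risk[zero]) < mean(risk)
  }
  expect_true(all(ok))
})
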