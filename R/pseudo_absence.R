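#' Climatic envelope (rectilinear) presence-only model
#'
#' Classifies a location as potentially suitable (1) iff every covariate lies
#' within the `[lower, upper]` bounds derived from the presence records at
#' the given percentile trim. The default 0/100 trim is the strict envelope
#' (all training presences score 1); a 5/95 trim discards the tails.
#'
#' @param presence_features Data frame of numeric covariates at presence
#'   locations (>= 5 rows).
#' @param trim Length-2 percentile trim `c(low, high)` in `[0, 100]`.
#' @return An object of class `envelope_model`.
#' @export
fit_envelope <- function(presence_features, trim = c(0, 100)) {
  feats <- numeric_features(presence_features)
  if (nrow(feats) < 5L) abort("Envelope model needs at least 5 presence rows.")
  if (length(trim) != 2L || trim[1] < 0 || trim[2] > 100 || trim[1] >= trim[2]) {
    abort("`trim` must be c(low, high) percentiles with 0 <= low < high <= 100.")
  }
  bounds <- purrr::map_dfr(names(feats), function(nm) {
    q <- quantile(feats[[nm]], probs = trim / 100, names = FALSE)
    tibble(variable = nm, lower = q[1], upper = q[2])
  })
  structure(list(bounds = bounds, trim = trim), class = "envelope_model")
}

#' @rdname fit_envelope
#' @param model A fitted `envelope_model`.
#' @param newdata Data frame containing the model's covariate columns.
#' @return `score_envelope()`: integer 0/1 per row (`NA` where any covariate
#'   is missing).
#' @export
score_envelope <- function(model, newdata) {
  if (!inherits(model, "envelope_model")) abort("`model` must be an envelope_model.")
  check_columns(newdata, model$bounds$variable)
  inside <- rep(1L, nrow(newdata))
  for (i in seq_len(nrow(model$bounds))) {
    v <- newdata[[model$bounds$variable[i]]]
    ok <- v >= model$bounds$lower[i] & v <= model$bounds$upper[i]
    inside <- ifelse(is.na(ok), NA_integer_, pmin(inside, as.integer(ok)))
  }
  inside
}

#' Gower-similarity (domain) presence-only model
#'
#' Scores a location by its maximum Gower similarity to any presence record:
#' `sim(x, p) = 1 - mean_v |x_v - p_v| / range_v`, with ranges taken from the
#' presences. The location scores 1 iff that maximum reaches the similarity
#' threshold `theta` (the conventional cutoff is 0.95). Zero-range variables
#' carry no information for the similarity and are excluded with a warning.
#'
#' @param presence_features Data frame of numeric covariates at presence
#'   locations (>= 2 rows).
#' @param theta Similarity threshold in (0, 1].
#' @return An object of class `domain_model`.
#' @export
fit_domain <- function(presence_features, theta = 0.95) {
  feats <- numeric_features(presence_features)
  if (nrow(feats) < 2L) abort("Domain model needs at least 2 presence rows.")
  assert_scalar_number(theta, "theta")
  if (theta <= 0 || theta > 1) abort("`theta` must be in (0, 1].")
  ranges <- vapply(feats, function(v) diff(range(v)), numeric(1))
  zero <- names(ranges)[ranges == 0]
  if (length(zero) == ncol(feats)) {
    abort("All variables have zero range; Gower similarity is undefined.")
  }
  if (length(zero) > 0L) {
    warn(sprintf(
      "Excluding zero-range variable(s) from the domain model: %s.",
      paste(zero, collapse = ", ")
    ))
    feats <- feats[setdiff(names(feats), zero)]
    ranges <- ranges[setdiff(names(ranges), zero)]
  }
  structure(
    list(presences = as.matrix(feats), ranges = ranges, theta = theta),
    class = "domain_model"
  )
}

#' @rdname fit_domain
#' @param model A fitted `domain_model`.
#' @param newdata Data frame containing the model's covariate columns.
#' @return `score_domain()`: integer 0/1 per row. `domain_similarity()`: the
#'   underlying maximum Gower similarity per row.
#' @export
score_domain <- function(model, newdata) {
  as.integer(domain_similarity(model, newdata) >= model$theta)
}

#' @rdname fit_domain
#' @export
domain_similarity <- function(model, newdata) {
  if (!inherits(model, "domain_model")) abort("`model` must be a domain_model.")
  vars <- colnames(model$presences)
  check_columns(newdata, vars)
  x <- as.matrix(newdata[vars])
  best <- rep(-Inf, nrow(x))
  rng <- model$ranges[vars]
  for (i in seq_len(nrow(model$presences))) {
    d <- abs(sweep(x, 2L, model$presences[i, ], "-"))
    sim <- 1 - rowMeans(sweep(d, 2L, rng, "/"))
    best <- pmax(best, sim)
  }
  best
}

#' One-class SVM novelty detector as a presence-only model
#'
#' A maximum-margin one-class support vector machine (RBF kernel, `nu` =
#' expected training-outlier fraction) over covariates standardized to the
#' training mean and standard deviation. Inliers score 1, outliers 0.
#' Deterministic for a fixed seed and settings.
#'
#' @param presence_features Data frame of numeric covariates (>= 10 rows).
#' @param nu One-class SVM `nu` parameter (default 0.1).
#' @param seed Integer seed fixed before fitting.
#' @return An object of class `novelty_model`.
#' @export
fit_novelty <- function(presence_features, nu = 0.1, seed = 1L) {
  feats <- numeric_features(presence_features)
  if (nrow(feats) < 10L) abort("Novelty model needs at least 10 presence rows.")
  mu <- vapply(feats, mean, numeric(1))
  sdev <- vapply(feats, stats::sd, numeric(1))
  if (any(sdev == 0)) {
    abort(sprintf(
      "Constant feature(s) make the novelty detector degenerate: %s.",
      paste(names(sdev)[sdev == 0], collapse = ", ")
    ))
  }
  z <- scale(as.matrix(feats), center = mu, scale = sdev)
  fit <- with_seed(seed, e1071::svm(
    x = z, y = NULL, type = "one-classification",
    kernel = "radial", nu = nu, scale = FALSE
  ))
  structure(
    list(fit = fit, center = mu, scale = sdev, variables = names(feats)),
    class = "novelty_model"
  )
}

#' @rdname fit_novelty
#' @param model A fitted `novelty_model`.
#' @param newdata Data frame containing the model's covariate columns.
#' @return `score_novelty()`: integer 0/1 per row.
#' @export
score_novelty <- function(model, newdata) {
  if (!inherits(model, "novelty_model")) abort("`model` must be a novelty_model.")
  check_columns(newdata, model$variables)
  z <- scale(as.matrix(newdata[model$variables]),
             center = model$center, scale = model$scale)
  as.integer(as.logical(predict(model$fit, z)))
}

numeric_features <- function(features) {
  if (!is.data.frame(features)) abort("Features must be a data frame.")
  num <- features[vapply(features, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("x", "y", "row", "col"))]
  if (ncol(num) == 0L) abort("No numeric covariate columns found.")
  as_tibble(num[stats::complete.cases(num), , drop = FALSE])
}

check_columns <- function(newdata, vars) {
  missing <- setdiff(vars, names(newdata))
  if (length(missing) > 0L) {
    abort(sprintf("`newdata` is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Gate and combine presence-only binary maps
#'
#' Members whose test AUC exceeds the gate (strictly) are combined by
#' majority vote, with ties resolved to 1. The tie rule is
#' risk-conservative: it shrinks the predicted-zero region from which
#' pseudo-absences are later drawn rather than contaminating it with cells
#' any passing model considers at risk. The `zero_region` is the complement
#' of the combined map within valid cells.
#'
#' @param members List of members, each a list with elements `tag`
#'   (character), `map` (binary `raster_grid`), and `auc` (test AUC).
#' @param gate AUC cutoff (default 0.8); members must exceed it strictly.
#' @return An object of class `presence_only_ensemble`: `members` summary
#'   tibble, `combined` and `zero_region` binary grids, `gate`.
#' @export
combine_presence_only <- function(members, gate = 0.8) {
  if (!is.list(members) || length(members) == 0L) {
    abort("`members` must be a non-empty list.")
  }
  summary <- purrr::map_dfr(members, function(m) {
    tibble(tag = m$tag, auc = m$auc, passed = m$auc > gate)
  })
  passing <- members[summary$passed]
  if (length(passing) == 0L) {
    abort(paste0(
      "No presence-only member exceeds the AUC gate of ", gate,
      "; inspect the member models before proceeding."
    ))
  }
  ref <- passing[[1L]]$map
  for (m in passing[-1L]) assert_aligned(ref, m$map, sprintf("member '%s'", m$tag))
  votes <- Reduce(`+`, lapply(passing, function(m) m$map$values))
  vote_frac <- votes / length(passing)
  combined <- ifelse(is.na(vote_frac), NA_real_, as.numeric(vote_frac >= 0.5))
  comb_grid <- raster_grid(
    matrix(combined, nrow(ref$values), ncol(ref$values)),
    ref$cell_size, ref$origin, ref$crs
  )
  zero <- ifelse(is.na(combined), NA_real_, as.numeric(combined == 0))
  zero_grid <- raster_grid(
    matrix(zero, nrow(ref$values), ncol(ref$values)),
    ref$cell_size, ref$origin, ref$crs
  )
  structure(
    list(members = summary, combined = comb_grid, zero_region = zero_grid, gate = gate),
    class = "presence_only_ensemble"
  )
}

#' @export
print.presence_only_ensemble <- function(x, ...) {
  cat(sprintf(
    "<presence_only_ensemble> gate AUC > %.2f; %d of %d member(s) passing\n",
    x$gate, sum(x$members$passed), nrow(x$members)
  ))
  for (i in seq_len(nrow(x$members))) {
    cat(sprintf(
      "  %s %s (AUC %.3f)\n",
      if (x$members$passed[i]) "+" else "-", x$members$tag[i], x$members$auc[i]
    ))
  }
  invisible(x)
}

#' @export
tidy.presence_only_ensemble <- function(x, ...) x$members

#' Sample pseudo-absence points from the predicted-zero region
#'
#' Draws `multiplier * n_presence` distinct cells uniformly (without
#' replacement) from the zero region, excluding any cell containing a
#' presence point, and places points at cell centers. The default 2x
#' multiplier gives the conventional 1:2 presence:pseudo-absence design.
#'
#' @param zero_region Binary `raster_grid` (1 = eligible) or a
#'   `presence_only_ensemble` (its `zero_region` is used).
#' @param n_presence Number of presence records.
#' @param multiplier Pseudo-absences per presence (default 2).
#' @param seed Integer seed; same seed, same sample.
#' @param season Season tag recorded on the output points.
#' @param presences Optional data frame of presence points whose cells are
#'   excluded from sampling.
#' @return An `occurrence_set` tibble of `pseudo_absence` points.
#' @export
sample_pseudo_absences <- function(zero_region, n_presence, multiplier = 2,
                                   seed = 1L, season = "spring", presences = NULL) {
  if (inherits(zero_region, "presence_only_ensemble")) {
    zero_region <- zero_region$zero_region
  }
  if (!is_raster_grid(zero_region)) {
    abort("`zero_region` must be a raster_grid or presence_only_ensemble.")
  }
  assert_scalar_number(n_presence, "n_presence", lower = 1)
  assert_scalar_number(multiplier, "multiplier", lower = 1)
  n <- as.integer(round(multiplier * n_presence))
  eligible <- which(!is.na(zero_region$values) & zero_region$values == 1)
  if (!is.null(presences) && nrow(presences) > 0L) {
    rc <- point_to_cell(zero_region, presences$x, presences$y)
    pres_idx <- (rc$col[rc$inside] - 1L) * nrow(zero_region$values) + rc$row[rc$inside]
    eligible <- setdiff(eligible, pres_idx)
  }
  if (length(eligible) < n) {
    abort(sprintf(
      "Zero region has %d eligible cell(s) but %d pseudo-absences were requested (shortfall %d).",
      length(eligible), n, n - length(eligible)
    ))
  }
  idx <- with_seed(seed, sample(eligible, n))
  nr <- nrow(zero_region$values)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  ctr <- cell_center(zero_region, row, col)
  occurrence_set(
    ctr$x, ctr$y, season = season,
    label = "pseudo_absence", source = "two_step_sampler"
  )
}

#' Two-step pseudo-absence selection
#'
#' Step one fits the three presence-only models (climatic envelope, Gower
#' domain, one-class SVM) on a 70% training share of the presences, scores
#' the whole landscape with each, and assesses each member's AUC on the
#' held-out presences against an equally sized uniform random background
#' sample. Members exceeding the AUC gate are combined by majority vote
#' (ties to 1). Step two samples pseudo-absences uniformly from the
#' resulting predicted-zero region, excluding presence cells, at
#' `multiplier` times the presence count.
#'
#' @param stack Covariate `raster_stack` for the season.
#' @param presences Presence points (data frame with `x`, `y`; a `season`
#'   column tags the output).
#' @param seed Integer seed driving the split, the background sample, the
#'   SVM fit and the pseudo-absence draw.
#' @param gate AUC gate for presence-only members (default 0.8).
#' @param multiplier Pseudo-absences per presence (default 2).
#' @param train_fraction Share of presences used to fit the presence-only
#'   models (default 0.7).
#' @param trim,theta,nu Member-model settings (see [fit_envelope()],
#'   [fit_domain()], [fit_novelty()]).
#' @return A list of class `pseudo_absence_selection`: `ensemble`
#'   (`presence_only_ensemble`), `pseudo_absences` (occurrence tibble),
#'   `presences` (the rows used, with features), and `seed`.
#' @export
select_pseudo_absences <- function(stack, presences, seed = 1L, gate = 0.8,
                                   multiplier = 2, train_fraction = 0.7,
                                   trim = c(0, 100), theta = 0.95, nu = 0.1) {
  if (!inherits(stack, "raster_stack")) abort("`stack` must be a raster_stack.")
  season <- if ("season" %in% names(presences) && nrow(presences) > 0L) {
    presences$season[1L]
  } else {
    "spring"
  }
  feats <- extract_at_points(stack, presences, quiet = TRUE)
  vars <- names(stack$layers)
  n <- nrow(feats)
  if (n < 15L) abort("Two-step selection needs at least 15 usable presences.")
  n_train <- round(train_fraction * n)
  train_idx <- with_seed(seed, sample.int(n, n_train))
  train <- feats[train_idx, vars]
  test <- feats[-train_idx, vars]

  cells <- as_tibble(stack, drop_na = TRUE)
  bg_idx <- with_seed(seed + 1L, sample.int(nrow(cells), min(nrow(test), nrow(cells))))
  background <- cells[bg_idx, vars]

  env <- fit_envelope(train, trim = trim)
  dom <- fit_domain(train, theta = theta)
  nov <- fit_novelty(train, nu = nu, seed = seed + 2L)

  score_grid <- function(score_fun) {
    v <- rep(NA_real_, prod(dim(stack)))
    lin <- (cells$col - 1L) * nrow(stack$layers[[1L]]$values) + cells$row
    v[lin] <- as.numeric(score_fun(cells))
    ref <- stack$layers[[1L]]
    raster_grid(matrix(v, nrow(ref$values), ncol(ref$values)),
                ref$cell_size, ref$origin, ref$crs)
  }

  members <- list(
    list(
      tag = "envelope",
      map = score_grid(function(d) score_envelope(env, d)),
      auc = evaluate_binary_auc(score_envelope(env, test), score_envelope(env, background))
    ),
    list(
      tag = "domain",
      map = score_grid(function(d) score_domain(dom, d)),
      auc = evaluate_binary_auc(score_domain(dom, test), score_domain(dom, background))
    ),
    list(
      tag = "one_class_svm",
      map = score_grid(function(d) score_novelty(nov, d)),
      auc = evaluate_binary_auc(score_novelty(nov, test), score_novelty(nov, background))
    )
  )

  ensemble <- combine_presence_only(members, gate = gate)
  pa <- sample_pseudo_absences(
    ensemble, n_presence = n, multiplier = multiplier,
    seed = seed + 3L, season = season, presences = feats
  )
  structure(
    list(ensemble = ensemble, pseudo_absences = pa, presences = feats, seed = seed),
    class = "pseudo_absence_selection"
  )
}
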