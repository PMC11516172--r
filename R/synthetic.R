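#' Specification of a synthetic seasonal landscape
#'
#' Defines the study conditions the generator emulates: spatially
#' autocorrelated continuous covariates (elevation-, distance-to-road-,
#' land-surface-temperature-, vegetation-index-, heat-load-like layers plus a
#' moving-window landscape-diversity layer), a categorical land-use map, and
#' per-season logistic risk and habitat-suitability surfaces with known
#' coefficients. Continuous layers are rescaled to ranges typical of the
#' mountainous semi-arid landscapes this workflow targets (elevation
#' 113–3317 m; seasonal LST roughly 284–339 K; NDVI roughly −0.17–0.84).
#'
#' @param shape `c(rows, cols)`, each at least 16. Default 128 x 128.
#' @param cell_size Cell edge in meters. Default 500.
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   landscapes.
#' @param n_landuse_classes Number of land-use classes (2–26). Default 8.
#' @param smoothness Correlation length of the generated fields, in cells.
#' @param season_effects List with numeric vectors `lst` (Kelvin) and `ndvi`
#'   (index units), each named by season, giving additive seasonal shifts.
#'   Defaults echo seasonal LST ranges of warm semi-arid systems:
#'   spring +0, summer +16, autumn −5 K, with matching small NDVI declines.
#' @param risk_coefficients Named vector of logistic coefficients on
#'   standardized layers (plus `"(Intercept)"`) defining the true wildfire
#'   risk surface. The defaults carve out a sharply delimited fire-prone
#'   zone (a small share of the landscape) concentrated near roads, at low
#'   elevation and high temperature, with vegetation as fuel — the strongly
#'   clustered structure of satellite-detected fire points.
#' @param suitability_coefficients Same, for the focal-species habitat
#'   suitability surface (defaults: a vegetation-associated generalist with
#'   mild elevation preference, whose habitat partly overlaps the fire-prone
#'   zone).
#'
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(shape = c(128L, 128L),
                           cell_size = 500,
                           seed = 1L,
                           n_landuse_classes = 8L,
                           smoothness = 16,
                           season_effects = list(
                             lst = c(spring = 0, summer = 16, autumn = -5),
                             ndvi = c(spring = 0, summer = -0.04, autumn = -0.10)
                           ),
                           risk_coefficients = c(
                             "(Intercept)" = -13,
                             elevation = -4,
                             dist_road = -6,
                             lst = 4,
                             ndvi = 3,
                             diversity = 3,
                             hli = 2
                           ),
                           suitability_coefficients = c(
                             "(Intercept)" = -5,
                             elevation = 0.5,
                             dist_road = 0.5,
                             ndvi = 3,
                             diversity = 1,
                             hli = -1
                           )) {
  if (length(shape) != 2L || any(shape < 16)) {
    abort("`shape` must be c(rows, cols) with both dimensions >= 16.")
  }
  assert_scalar_number(cell_size, "cell_size")
  if (cell_size <= 0) abort("`cell_size` must be > 0.")
  assert_scalar_number(seed, "seed")
  if (n_landuse_classes < 2 || n_landuse_classes > 26) {
    abort("`n_landuse_classes` must be between 2 and 26.")
  }
  assert_scalar_number(smoothness, "smoothness", lower = 1)
  layer_names <- c("elevation", "dist_road", "lst", "ndvi", "diversity", "hli")
  for (coefs in list(risk = risk_coefficients, suitability = suitability_coefficients)) {
    bad <- setdiff(names(coefs), c("(Intercept)", layer_names))
    if (length(bad) > 0L) {
      abort(sprintf(
        "Coefficient(s) %s name no generated layer (layers: %s).",
        paste(bad, collapse = ", "), paste(layer_names, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      shape = as.integer(shape),
      cell_size = as.numeric(cell_size),
      seed = as.integer(seed),
      n_landuse_classes = as.integer(n_landuse_classes),
      smoothness = as.numeric(smoothness),
      season_effects = season_effects,
      risk_coefficients = risk_coefficients,
      suitability_coefficients = suitability_coefficients,
      layer_names = layer_names
    ),
    class = "landscape_spec"
  )
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat(sprintf(
    "<landscape_spec> %d x %d cells @ %g m, %d land-use classes, seed %d\n",
    x$shape[1], x$shape[2], x$cell_size, x$n_landuse_classes, x$seed
  ))
  invisible(x)
}

# Smoothed standard-normal random field: white noise convolved with a
# Gaussian kernel on the torus (FFT), then standardized. `range_cells` is the
# kernel sd, i.e. the correlation length in cells.
gaussian_field <- function(nr, nc, range_cells) {
  noise <- matrix(rnorm(nr * nc), nr, nc)
  dr <- pmin(0:(nr - 1), nr - (0:(nr - 1)))
  dc <- pmin(0:(nc - 1), nc - (0:(nc - 1)))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * range_cells^2))
  k <- k / sum(k)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (f - mean(f)) / stats::sd(f)
}

rescale_to <- function(m, lo, hi) {
  r <- range(m, na.rm = TRUE)
  if (r[1] == r[2]) {
    return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  }
  lo + (m - r[1]) / (r[2] - r[1]) * (hi - lo)
}

# Random west-east polyline (a "road"): one column step at a time, the row
# drifting by -1/0/+1. Returns a logical mask of road cells.
road_mask <- function(nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  r <- sample.int(nr, 1L)
  for (cc in seq_len(nc)) {
    mask[r, cc] <- TRUE
    r <- min(max(r + sample(c(-1L, 0L, 1L), 1L), 1L), nr)
  }
  mask
}

# Euclidean distance (meters) from every cell center to the nearest TRUE cell.
distance_transform <- function(mask, cell_size) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  src <- which(mask, arr.ind = TRUE)
  if (nrow(src) == 0L) abort("Distance transform needs at least one source cell.")
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(src))) {
    d2 <- pmin(d2, (rows - src[k, 1])^2 + (cols - src[k, 2])^2)
  }
  sqrt(d2) * cell_size
}

standardize_layer <- function(v) {
  mu <- mean(v, na.rm = TRUE)
  s <- stats::sd(v, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    return(v * 0)
  }
  (v - mu) / s
}

logistic_surface <- function(stack, coefs) {
  ref <- stack$layers[[1L]]
  eta <- matrix(unname(coefs["(Intercept)"] %||% 0), nrow(ref$values), ncol(ref$values))
  for (nm in setdiff(names(coefs), "(Intercept)")) {
    eta <- eta + coefs[[nm]] * standardize_layer(stack$layers[[nm]]$values)
  }
  raster_grid(plogis(eta), ref$cell_size, ref$origin, ref$crs)
}

default_landuse_legend <- function(n) {
  base <- c(
    "agriculture", "rainfed_agriculture", "orchards", "dense_forest",
    "semidense_forest", "dense_rangeland", "poor_rangeland", "urban",
    "water", "bare_land"
  )
  nm <- if (n <= length(base)) base[seq_len(n)] else c(base, paste0("class_", seq_len(n - length(base))))
  setNames(nm[seq_len(n)], as.character(seq_len(n)))
}

#' Generate a synthetic seasonal landscape with known ground truth
#'
#' Produces one covariate stack per season (layers `elevation`, `dist_road`,
#' `lst`, `ndvi`, `diversity`, `hli`), a categorical land-use grid, and the
#' true per-season wildfire-risk and habitat-suitability probability surfaces
#' from which occurrence points can be sampled. Elevation, road distance,
#' heat load and diversity are static across seasons; temperature- and
#' vegetation-index-like layers shift by season. The land-use map is a
#' thresholded smooth field with an agriculture class stamped preferentially
#' at low elevation, so land-use cross-tabulations of fire points show the
#' concentration in agricultural classes that motivates the analysis. The
#' diversity layer is the 5x5 moving-window Shannon entropy of that land-use
#' map, computed with [window_diversity()].
#'
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `landscape` with elements `stacks` (named list of
#'   per-season `raster_stack`s), `landuse` (categorical `raster_grid`), and
#'   `truth` (class `ground_truth`: per-season `risk` and `suitability`
#'   probability grids plus the generating coefficients).
#' @export
make_landscape <- function(spec = landscape_spec()) {
  if (!inherits(spec, "landscape_spec")) abort("`spec` must be a landscape_spec.")
  nr <- spec$shape[1]
  nc <- spec$shape[2]
  cs <- spec$cell_size
  with_seed(spec$seed, {
    elev_f <- gaussian_field(nr, nc, spec$smoothness)
    # temperature falls with elevation (lapse rate) and vegetation rises with
    # it in semi-arid mountain systems; the residual fields keep |r| below
    # the screening cutoffs so the default landscape exercises screening
    # without forcing a drop
    lst_f <- -0.8 * elev_f + 0.6 * gaussian_field(nr, nc, spec$smoothness)
    ndvi_f <- 0.7 * elev_f + 0.714 * gaussian_field(nr, nc, spec$smoothness)
    hli_f <- gaussian_field(nr, nc, spec$smoothness * 0.5)
    lu_f <- gaussian_field(nr, nc, spec$smoothness)
    ag_f <- gaussian_field(nr, nc, spec$smoothness)
    season_noise <- lapply(
      setNames(modeled_seasons, modeled_seasons),
      function(s) list(
        lst = gaussian_field(nr, nc, spec$smoothness),
        ndvi = gaussian_field(nr, nc, spec$smoothness)
      )
    )
    road <- road_mask(nr, nc)

    grid_of <- function(m, legend = NULL) raster_grid(m, cs, crs = "synthetic-metric", legend = legend)

    elevation <- rescale_to(elev_f, 113, 3317)
    dist_road <- distance_transform(road, cs)
    hli <- rescale_to(hli_f, 0.3, 1.12)

    # land use: quantile-sliced smooth field; agriculture (class 1) stamped
    # where elevation is low and a second field favors it
    n_cls <- spec$n_landuse_classes
    qs <- quantile(lu_f, probs = seq(0, 1, length.out = n_cls + 1L))
    lu <- matrix(
      as.numeric(cut(lu_f, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)),
      nr, nc
    )
    lu[is.na(lu)] <- 1
    ag <- elevation < quantile(elevation, 0.35) & ag_f > 0
    lu[ag] <- 1
    landuse <- grid_of(lu, legend = default_landuse_legend(n_cls))

    diversity <- window_diversity(landuse, window = 5L)

    stacks <- list()
    for (s in modeled_seasons) {
      lst_s <- 0.85 * lst_f + 0.15 * season_noise[[s]]$lst
      ndvi_s <- 0.85 * ndvi_f + 0.15 * season_noise[[s]]$ndvi
      lst_m <- rescale_to(lst_s, 289.59, 322.96) + spec$season_effects$lst[[s]]
      ndvi_m <- rescale_to(ndvi_s, -0.07, 0.84) + spec$season_effects$ndvi[[s]]
      stacks[[s]] <- raster_stack(list(
        elevation = grid_of(elevation),
        dist_road = grid_of(dist_road),
        lst = grid_of(lst_m),
        ndvi = grid_of(ndvi_m),
        diversity = diversity,
        hli = grid_of(hli)
      ))
    }

    truth <- structure(
      list(
        risk = lapply(stacks, logistic_surface, coefs = spec$risk_coefficients),
        suitability = lapply(stacks, logistic_surface, coefs = spec$suitability_coefficients),
        risk_coefficients = spec$risk_coefficients,
        suitability_coefficients = spec$suitability_coefficients
      ),
      class = "ground_truth"
    )

    structure(
      list(stacks = stacks, landuse = landuse, truth = truth, spec = spec),
      class = "landscape"
    )
  })
}

#' @export
print.landscape <- function(x, ...) {
  ref <- x$stacks[[1L]]$layers[[1L]]
  cat(sprintf(
    "<landscape> %d x %d cells @ %g m; seasons: %s; %d land-use classes\n",
    nrow(ref$values), ncol(ref$values), ref$cell_size,
    paste(names(x$stacks), collapse = ", "), length(x$landuse$legend)
  ))
  invisible(x)
}

#' Sample presence points from a true probability surface
#'
#' Cells are drawn with probability proportional to the surface value,
#' without replacement by default (each cell contributes at most one point);
#' points are placed at cell centers. `replace = TRUE` is a testing mode for
#' checking sampling frequencies against the underlying probabilities.
#'
#' @param truth A `ground_truth` object (from [make_landscape()]) or a
#'   probability `raster_grid`.
#' @param n Number of points (>= 1).
#' @param season Season tag (selects the surface when `truth` is a
#'   `ground_truth`; recorded on the output either way).
#' @param seed Integer seed; same seed, same sample.
#' @param surface For `ground_truth` input, `"risk"` (default) or
#'   `"suitability"`.
#' @param replace Sample cells with replacement (testing mode).
#' @return An `occurrence_set` tibble of presence points.
#' @export
sample_presences <- function(truth, n, season, seed,
                             surface = c("risk", "suitability"),
                             replace = FALSE) {
  surface <- match.arg(surface)
  if (inherits(truth, "ground_truth")) {
    if (!season %in% names(truth[[surface]])) {
      abort(sprintf("No %s surface for season '%s'.", surface, season))
    }
    grid <- truth[[surface]][[season]]
  } else if (is_raster_grid(truth)) {
    grid <- truth
  } else {
    abort("`truth` must be a ground_truth or a raster_grid.")
  }
  assert_scalar_number(n, "n", lower = 1)
  w <- as.vector(grid$values)
  ok <- which(!is.na(w) & w > 0)
  if (!replace && length(ok) < n) {
    abort(sprintf(
      "Requested %d points but only %d cells have positive probability.", n, length(ok)
    ))
  }
  idx <- with_seed(seed, sample(ok, size = n, prob = w[ok], replace = replace))
  nr <- nrow(grid$values)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  ctr <- cell_center(grid, row, col)
  occurrence_set(ctr$x, ctr$y, season = season, label = "presence", source = "synthetic")
}
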