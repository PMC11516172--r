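#' Distance-based occurrence thinning
#'
#' Greedy sequential thinning in input order: a point is kept iff its
#' Euclidean distance to every already-kept point is at least
#' `min_distance`. This mirrors the standard GIS near-point filtering used to
#' reduce spatial autocorrelation in occurrence data (1000 m for species
#' records, 300 m for satellite fire detections, matching the detection
#' resolution). Greedy-by-order is deterministic; pass `shuffle_seed` to
#' permute the input first as a sensitivity check.
#'
#' When a `season` column is present, thinning is applied within each season
#' separately (records from different seasons never exclude one another).
#'
#' @param points Data frame with `x` and `y` (projected meters); `season`
#'   optional.
#' @param min_distance Minimum pairwise distance in meters (>= 0; 0 returns
#'   the input unchanged).
#' @param shuffle_seed Optional integer; if given, rows are randomly permuted
#'   (within season) before the greedy scan.
#' @return The retained subset of `points`, in input order. Attribute
#'   `n_dropped` records the number of removed points.
#' @export
thin_points <- function(points, min_distance, shuffle_seed = NULL) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    abort("`points` must be a data frame with `x` and `y` columns.")
  }
  assert_scalar_number(min_distance, "min_distance", lower = 0)
  out <- as_tibble(points)
  if (nrow(out) == 0L || min_distance == 0) {
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  groups <- if ("season" %in% names(out)) out$season else rep("all", nrow(out))
  keep <- logical(nrow(out))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (!is.null(shuffle_seed)) {
      idx <- with_seed(shuffle_seed, sample(idx))
    }
    kx <- numeric(0)
    ky <- numeric(0)
    for (i in idx) {
      xi <- out$x[i]
      yi <- out$y[i]
      if (length(kx) == 0L ||
            min(sqrt((kx - xi)^2 + (ky - yi)^2)) >= min_distance) {
        keep[i] <- TRUE
        kx <- c(kx, xi)
        ky <- c(ky, yi)
      }
    }
  }
  res <- out[keep, , drop = FALSE]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Pairwise-correlation screening of covariates
#'
#' Iteratively removes one member of the most-correlated offending pair until
#' no pair of retained columns has `|r|` above `threshold` (Pearson, computed
#' on complete rows). Within an offending pair, the member with the larger
#' mean `|r|` against all other retained columns is dropped (ties: the
#' later-named column), keeping the more independent covariate. Conventional
#' cutoffs are 0.85 for species-habitat covariates and 0.75 for fire-risk
#' covariates.
#'
#' Constant columns have undefined correlations; they are kept and flagged.
#'
#' @param features Data frame of numeric covariate columns (>= 2 columns,
#'   >= 3 complete rows). Non-numeric columns are ignored.
#' @param threshold Absolute-correlation cutoff in (0, 1].
#' @return An object of class `screening_report`: list with `kept` (layer
#'   names), `dropped` (tibble `layer`, `partner`, `abs_r`), `threshold`,
#'   and `flagged_constant`.
#' @export
correlation_screen <- function(features, threshold) {
  if (!is.data.frame(features)) abort("`features` must be a data frame.")
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  num <- features[vapply(features, is.numeric, logical(1))]
  if (ncol(num) < 2L) abort("Need at least 2 numeric columns to screen.")
  num <- num[stats::complete.cases(num), , drop = FALSE]
  if (nrow(num) < 3L) abort("Need at least 3 complete rows to screen.")
  constant <- names(num)[vapply(num, function(v) stats::sd(v) == 0, logical(1))]
  active <- setdiff(names(num), constant)
  dropped <- tibble(layer = character(), partner = character(), abs_r = numeric())
  while (length(active) >= 2L) {
    cm <- abs(stats::cor(num[active]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    hit <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- active[c(hit[["row"]], hit[["col"]])]
    # mean |r| of each pair member against everything else still active
    mean_r <- vapply(pair, function(p) mean(cm[p, setdiff(active, p)]), numeric(1))
    loser <- if (mean_r[1] > mean_r[2]) {
      pair[1]
    } else if (mean_r[2] > mean_r[1]) {
      pair[2]
    } else {
      pair[which.max(match(pair, names(num)))] # tie: later-named column
    }
    partner <- setdiff(pair, loser)
    dropped <- dplyr::bind_rows(
      dropped,
      tibble(layer = loser, partner = partner, abs_r = max(cm))
    )
    active <- setdiff(active, loser)
  }
  structure(
    list(
      kept = c(active, constant),
      dropped = dropped,
      threshold = threshold,
      flagged_constant = constant
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "<screening_report> |r| threshold %.2f: kept %d layer(s), dropped %d\n",
    x$threshold, length(x$kept), nrow(x$dropped)
  ))
  if (nrow(x$dropped) > 0L) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf(
        "  - %s (|r| = %.3f with %s)\n",
        x$dropped$layer[i], x$dropped$abs_r[i], x$dropped$partner[i]
      ))
    }
  }
  if (length(x$flagged_constant) > 0L) {
    cat("  constant (kept, flagged):", paste(x$flagged_constant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.screening_report <- function(x, ...) x$dropped

# clamped summed-area box sum; NA treated as 0 (pair with a validity count)
box_sum <- function(m, half) {
  nr <- nrow(m)
  nc <- ncol(m)
  s <- apply(apply(m, 2L, cumsum), 1L, cumsum)
  s <- t(s) # s[r, c] = sum of m[1:r, 1:c]
  at <- function(r, c) {
    ok <- r >= 1L & c >= 1L
    out <- numeric(length(r))
    out[ok] <- s[cbind(r[ok], c[ok])]
    out
  }
  r <- rep(seq_len(nr), times = nc)
  c <- rep(seq_len(nc), each = nr)
  r1 <- pmax(r - half, 1L)
  r2 <- pmin(r + half, nr)
  c1 <- pmax(c - half, 1L)
  c2 <- pmin(c + half, nc)
  v <- at(r2, c2) - at(r1 - 1L, c2) - at(r2, c1 - 1L) + at(r1 - 1L, c1 - 1L)
  matrix(v, nr, nc)
}

#' Moving-window landscape diversity (Shannon entropy)
#'
#' For each cell, the Shannon entropy `H = -sum(p_k * ln p_k)` of land-use
#' class proportions within the centered `window` x `window` neighborhood
#' (natural logarithm). Windows are truncated at the map edge; nodata cells
#' are excluded from the proportions, and a fully-nodata window yields
#' nodata. `H` is 0 exactly when the window is monoclass and is bounded above
#' by `ln(number of classes)`.
#'
#' @param landuse Categorical `raster_grid` of class codes.
#' @param window Odd window size >= 3 (default 5, the conventional landscape
#'   diversity filter).
#' @return A continuous `raster_grid` of entropies.
#' @export
window_diversity <- function(landuse, window = 5L) {
  if (!is_raster_grid(landuse)) abort("`landuse` must be a raster_grid.")
  if (length(window) != 1L || window < 3L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 3.")
  }
  half <- (as.integer(window) - 1L) %/% 2L
  v <- landuse$values
  classes <- sort(unique(v[!is.na(v)]))
  n_valid <- box_sum(matrix(as.numeric(!is.na(v)), nrow(v)), half)
  h <- matrix(0, nrow(v), ncol(v))
  for (k in classes) {
    cnt <- box_sum(matrix(as.numeric(!is.na(v) & v == k), nrow(v)), half)
    p <- ifelse(n_valid > 0, cnt / n_valid, 0)
    term <- ifelse(p > 0, -p * log(p), 0)
    h <- h + term
  }
  h[n_valid == 0] <- NA_real_
  raster_grid(h, landuse$cell_size, landuse$origin, landuse$crs)
}

#' Cross-tabulation table with percentage accounting
#'
#' Builds the frequency/percentage layout used for land-use cross-tabs:
#' `percentage = 100 * frequency / sum(frequency)`, reported to two decimals.
#' The denominator is the table's own frequency total (per-season totals when
#' one table is built per season).
#'
#' @param class_name Character vector of class names.
#' @param frequency Non-negative integer counts.
#' @return A tibble of class `crosstab_table` with columns `class`,
#'   `frequency`, `percentage`.
#' @export
crosstab_table <- function(class_name, frequency) {
  if (length(class_name) != length(frequency)) {
    abort("`class_name` and `frequency` must have equal length.")
  }
  if (any(frequency < 0)) abort("Frequencies must be non-negative.")
  total <- sum(frequency)
  if (total <= 0) abort("Total frequency must be positive.")
  out <- tibble(
    class = as.character(class_name),
    frequency = as.integer(frequency),
    percentage = round(100 * frequency / total, 2)
  )
  class(out) <- unique(c("crosstab_table", class(out)))
  out
}

#' Cross-tabulate occurrence points by land-use class
#'
#' Counts points per land-use class (nearest-cell lookup) and reports
#' percentages of the table total. Classes with zero points are omitted;
#' points falling on nodata cells are counted in an explicit
#' `"unclassified"` row. When the grid carries a legend, class names come
#' from it; otherwise the numeric codes are used.
#'
#' @param points Data frame with `x`, `y` (projected meters).
#' @param landuse Categorical `raster_grid`.
#' @return A `crosstab_table` tibble, ordered by decreasing frequency.
#' @export
crosstab_landuse <- function(points, landuse) {
  if (!is_raster_grid(landuse)) abort("`landuse` must be a raster_grid.")
  if (!is.data.frame(points) || nrow(points) == 0L) {
    abort("`points` must be a non-empty data frame.")
  }
  rc <- point_to_cell(landuse, points$x, points$y)
  if (!any(rc$inside)) abort("No points fall inside the land-use extent.")
  codes <- rep(NA_real_, nrow(points))
  codes[rc$inside] <- landuse$values[cbind(rc$row[rc$inside], rc$col[rc$inside])]
  labels <- if (!is.null(landuse$legend)) {
    unname(landuse$legend[as.character(codes)])
  } else {
    as.character(codes)
  }
  labels[rc$inside & is.na(codes)] <- "unclassified"
  labels <- labels[rc$inside]
  tab <- sort(table(labels), decreasing = TRUE)
  crosstab_table(names(tab), as.integer(tab))
}
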