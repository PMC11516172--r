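#' Normalized between-season change surface
#'
#' For aligned risk maps `a` (earlier season) and `b` (later season), the
#' change index is `|b - a| / max(|b - a|)`, the maximum taken over cells
#' valid in both maps. The index lies in `[0, 1]`, attains 1 at the
#' cell(s) of largest between-season difference, is symmetric in its
#' arguments, and is invariant to scaling the difference field by any
#' positive constant. When the two maps are identical the index is defined
#' as 0 everywhere.
#'
#' @param a,b Aligned probability `raster_grid`s with values in `[0, 1]`
#'   (earlier and later season).
#' @param season_pair Optional tag such as `"spring-summer"`.
#' @return An object of class `seasonal_change_map`: list with `a`, `b`,
#'   `index` (a `raster_grid`), and `season_pair`.
#' @export
change_index <- function(a, b, season_pair = NA_character_) {
  if (!is_raster_grid(a) || !is_raster_grid(b)) {
    abort("`a` and `b` must be raster_grid objects.")
  }
  assert_aligned(a, b, "`b`")
  for (g in list(a, b)) {
    v <- g$values[!is.na(g$values)]
    if (length(v) > 0L && (min(v) < -1e-9 || max(v) > 1 + 1e-9)) {
      abort("Risk maps must hold probabilities in [0, 1].")
    }
  }
  d <- abs(b$values - a$values) # NA in either input propagates
  m <- suppressWarnings(max(d, na.rm = TRUE))
  idx <- if (!is.finite(m) || m == 0) {
    ifelse(is.na(d), NA_real_, 0)
  } else {
    d / m
  }
  index <- raster_grid(
    matrix(idx, nrow(a$values), ncol(a$values)),
    a$cell_size, a$origin, a$crs
  )
  structure(
    list(a = a, b = b, index = index, season_pair = as.character(season_pair)),
    class = "seasonal_change_map"
  )
}

#' @export
print.seasonal_change_map <- function(x, ...) {
  v <- x$index$values
  cat(sprintf(
    "<seasonal_change_map> %s: index in [%.3f, %.3f] over %d valid cells\n",
    ifelse(is.na(x$season_pair), "(untagged)", x$season_pair),
    suppressWarnings(min(v, na.rm = TRUE)), suppressWarnings(max(v, na.rm = TRUE)),
    sum(!is.na(v))
  ))
  invisible(x)
}
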