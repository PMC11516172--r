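#' GAP overlap of binary habitat and fire-risk maps
#'
#' Partitions the landscape into four classes — `at_risk_habitat`
#' (habitat AND fire risk), `fire_only`, `habitat_only`, and `neither` —
#' and accounts their areas in square kilometres
#' (`cells x (cell_size / 1000)^2`). Cells that are nodata in either input
#' are excluded from every class and reported separately, so the four areas
#' always sum to the valid-cell area exactly.
#'
#' @param habitat,fire Aligned binary `raster_grid`s (values 0/1, `NA`
#'   nodata); non-binary values are a validation error.
#' @param species,season Optional tags recorded on the summary.
#' @return An object of class `gap_overlap`: list with `class_map` (a
#'   categorical `raster_grid`, codes 1–4 with legend), `summary` (tibble
#'   `class`, `cells`, `area_km2` plus tags, class `overlap_summary`), and
#'   `nodata_cells`.
#' @export
gap_overlap <- function(habitat, fire, species = NA_character_, season = NA_character_) {
  if (!is_raster_grid(habitat) || !is_raster_grid(fire)) {
    abort("`habitat` and `fire` must be raster_grid objects.")
  }
  assert_aligned(habitat, fire, "`fire`")
  for (g in list(habitat = habitat, fire = fire)) {
    v <- g$values[!is.na(g$values)]
    if (length(v) > 0L && !all(v %in% c(0, 1))) {
      abort("GAP overlap needs binary (0/1) maps; binarize probability maps first.")
    }
  }
  h <- habitat$values
  f <- fire$values
  valid <- !is.na(h) & !is.na(f)
  code <- matrix(NA_real_, nrow(h), ncol(h))
  code[valid & h == 1 & f == 1] <- 1 # at-risk habitat (red)
  code[valid & h == 0 & f == 1] <- 2 # fire risk outside habitat (blue)
  code[valid & h == 1 & f == 0] <- 3 # habitat outside fire risk (green)
  code[valid & h == 0 & f == 0] <- 4 # neither
  legend <- c(
    "1" = "at_risk_habitat", "2" = "fire_only", "3" = "habitat_only", "4" = "neither"
  )
  class_map <- raster_grid(code, habitat$cell_size, habitat$origin, habitat$crs,
                           legend = legend)
  cell_km2 <- (habitat$cell_size / 1000)^2
  counts <- vapply(1:4, function(k) sum(code == k, na.rm = TRUE), numeric(1))
  summary <- tibble(
    class = unname(legend),
    cells = as.integer(counts),
    area_km2 = counts * cell_km2,
    species = as.character(species),
    season = as.character(season)
  )
  class(summary) <- unique(c("overlap_summary", class(summary)))
  structure(
    list(
      class_map = class_map,
      summary = summary,
      nodata_cells = sum(!valid)
    ),
    class = "gap_overlap"
  )
}

#' @export
print.gap_overlap <- function(x, ...) {
  cat("<gap_overlap>\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-16s %8.2f km^2 (%d cells)\n",
                x$summary$class[i], x$summary$area_km2[i], x$summary$cells[i]))
  }
  if (x$nodata_cells > 0L) cat(sprintf("  nodata cells excluded: %d\n", x$nodata_cells))
  invisible(x)
}

#' @export
tidy.gap_overlap <- function(x, ...) x$summary
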