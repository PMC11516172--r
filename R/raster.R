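#' Single-layer raster grid
#'
#' A `raster_grid` is a matrix of cell values in a projected (metric)
#' coordinate system, with `NA` marking nodata cells. Row 1 is the northern
#' (top) edge of the grid; the `origin` is the x/y coordinate of the grid's
#' upper-left corner. Categorical grids carry a `legend` mapping integer
#' class codes to class names.
#'
#' @param values Numeric matrix of cell values (`NA` = nodata). Row 1 is the
#'   top of the map.
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin Numeric length-2 vector `c(x, y)` of the upper-left corner.
#' @param crs Opaque CRS tag. Must describe a projected metric system;
#'   geographic (degree) systems are rejected, because all distance and area
#'   accounting in this package assumes metric cells.
#' @param legend Optional named character vector mapping class codes
#'   (as names, e.g. `"1"`) to class names, for categorical grids.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, nrow(values) * cell_size),
                        crs = "local-metric", legend = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  assert_scalar_number(cell_size, "cell_size")
  if (cell_size <= 0) abort("`cell_size` must be > 0.")
  if (!is.numeric(origin) || length(origin) != 2L || anyNA(origin)) {
    abort("`origin` must be c(x, y) of the upper-left corner.")
  }
  assert_projected_crs(crs)
  if (!is.null(legend)) {
    if (is.null(names(legend)) || anyNA(names(legend)) || any(names(legend) == "")) {
      abort("`legend` must be a named character vector (names = class codes).")
    }
    legend <- setNames(as.character(legend), names(legend))
  }
  structure(
    list(
      values = values,
      cell_size = as.numeric(cell_size),
      origin = as.numeric(origin),
      crs = as.character(crs),
      legend = legend
    ),
    class = "raster_grid"
  )
}

assert_projected_crs <- function(crs) {
  if (!is.character(crs) || length(crs) != 1L || is.na(crs) || !nzchar(crs)) {
    abort("`crs` must be a non-empty string; rasters without a CRS tag are rejected.")
  }
  if (grepl("4326|degree|longlat|wgs84[^/]*geographic|geographic", tolower(crs))) {
    abort(
      paste0(
        "CRS '", crs, "' looks geographic (degrees). This package works in ",
        "projected meters; reproject inputs before loading them."
      )
    )
  }
  invisible(crs)
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d x %d cells, %.6g m resolution\n", nrow(v), ncol(v), x$cell_size
  ))
  cat(sprintf(
    "  extent: x [%.6g, %.6g], y [%.6g, %.6g]  crs: %s\n",
    x$origin[1], x$origin[1] + ncol(v) * x$cell_size,
    x$origin[2] - nrow(v) * x$cell_size, x$origin[2], x$crs
  ))
  valid <- sum(!is.na(v))
  if (!is.null(x$legend)) {
    cat(sprintf("  categorical, %d classes; %d valid cells\n", length(x$legend), valid))
  } else {
    rng <- if (valid > 0) range(v, na.rm = TRUE) else c(NA, NA)
    cat(sprintf(
      "  values in [%.6g, %.6g]; %d valid of %d cells\n",
      rng[1], rng[2], valid, length(v)
    ))
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

grid_nodata_mask <- function(grid) is.na(grid$values)

#' Convert a raster grid to a tibble of cell records
#'
#' @param x A `raster_grid`.
#' @param drop_na Drop nodata cells (default `TRUE`).
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x`, `y` (cell centers) and
#'   `value` (plus `class` for categorical grids with a legend).
#' @export
as_tibble.raster_grid <- function(x, ..., drop_na = TRUE) {
  nr <- nrow(x$values)
  nc <- ncol(x$values)
  out <- tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    value = as.vector(x$values)
  )
  out$x <- x$origin[1] + (out$col - 0.5) * x$cell_size
  out$y <- x$origin[2] - (out$row - 0.5) * x$cell_size
  if (!is.null(x$legend)) {
    out$class <- unname(x$legend[as.character(out$value)])
  }
  out <- out[, c("row", "col", "x", "y", setdiff(names(out), c("row", "col", "x", "y")))]
  if (drop_na) out <- out[!is.na(out$value), , drop = FALSE]
  out
}

# Map projected coordinates to (row, col) under half-open cell intervals
# [edge, edge + cell_size): a point exactly on a shared vertical edge belongs
# to the cell on its right, on a shared horizontal edge to the cell below.
point_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  row <- floor((grid$origin[2] - y) / grid$cell_size) + 1L
  # the top edge itself (y == origin y) belongs to row 1, not row 0
  row[y == grid$origin[2]] <- 1L
  inside <- col >= 1L & col <= ncol(grid$values) & row >= 1L & row <= nrow(grid$values)
  tibble(row = as.integer(row), col = as.integer(col), inside = inside)
}

cell_center <- function(grid, row, col) {
  tibble(
    x = grid$origin[1] + (col - 0.5) * grid$cell_size,
    y = grid$origin[2] - (row - 0.5) * grid$cell_size
  )
}

#' Stack of aligned raster layers
#'
#' All layers must share shape, cell size, origin and CRS; layer names must
#' be unique and non-empty. Stacking misaligned grids is an error — this
#' package validates alignment and never resamples.
#'
#' @param layers Named list of `raster_grid` objects (or name/grid pairs
#'   passed as `...`).
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  if (!is.list(layers) || length(layers) == 0L) {
    abort("`layers` must be a non-empty named list of raster_grid objects.")
  }
  nms <- names(layers)
  if (is.null(nms) || anyNA(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    abort("Layer names must be unique and non-empty.")
  }
  for (nm in nms) {
    if (!is_raster_grid(layers[[nm]])) {
      abort(sprintf("Layer '%s' is not a raster_grid.", nm))
    }
  }
  ref <- layers[[1L]]
  for (nm in nms[-1L]) {
    assert_aligned(ref, layers[[nm]], sprintf("layer '%s'", nm))
  }
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  ref <- x$layers[[1L]]
  cat(sprintf(
    "<raster_stack> %d layers, %d x %d cells @ %.6g m\n  layers: %s\n",
    length(x$layers), nrow(ref$values), ncol(ref$values), ref$cell_size,
    paste(names(x$layers), collapse = ", ")
  ))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' @export
dim.raster_stack <- function(x) dim(x$layers[[1L]]$values)

# error if two grids do not share geometry; `what` names the offender
assert_aligned <- function(a, b, what = "grid") {
  ok <- identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9)) &&
    identical(a$crs, b$crs)
  if (!ok) {
    abort(sprintf(
      "%s is not aligned with the reference grid (shape/cell_size/origin/crs must match).",
      what
    ))
  }
  invisible(TRUE)
}

#' Convert a raster stack to a tibble, one row per cell
#'
#' @param x A `raster_stack`.
#' @param drop_na Drop rows where any layer is nodata (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `x`, `y` and one column per layer.
#' @export
as_tibble.raster_stack <- function(x, ..., drop_na = TRUE) {
  ref <- x$layers[[1L]]
  out <- as_tibble.raster_grid(ref, drop_na = FALSE)
  out$value <- NULL
  out$class <- NULL
  for (nm in names(x$layers)) {
    out[[nm]] <- as.vector(x$layers[[nm]]$values)
  }
  if (drop_na) {
    keep <- stats::complete.cases(out[names(x$layers)])
    out <- out[keep, , drop = FALSE]
  }
  out
}

# ---------------------------------------------------------------------------
# File formats: ESRI ASCII grid (.asc) + JSON sidecar (crs, legend).
# The sidecar is required on read: a raster without georeferencing metadata
# is rejected rather than guessed at.
# ---------------------------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

#' Write a raster grid to an ESRI ASCII grid file
#'
#' Writes the grid as plain-text ESRI ASCII grid (`.asc`) plus a JSON sidecar
#' (`<path>.json`) holding the CRS tag, the linear unit, and the class legend
#' for categorical grids. Continuous values are written with full double
#' precision so that a write/read round trip is exact to 1e-9 or better;
#' integer-valued grids round-trip bit-exactly.
#'
#' @param grid A `raster_grid`.
#' @param path Output path (conventionally ending in `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  if (!is_raster_grid(grid)) abort("`grid` must be a raster_grid.")
  v <- grid$values
  nr <- nrow(v)
  nc <- ncol(v)
  nodata <- -9999
  finite <- v[!is.na(v)]
  while (any(finite == nodata)) nodata <- nodata * 10 - 9 # avoid collisions
  integral <- length(finite) == 0L ||
    (all(is.finite(finite)) && all(finite == round(finite)) &&
       max(abs(finite)) < 2^52)
  fmt <- if (integral) "%.0f" else "%.17g"
  vv <- v
  vv[is.na(vv)] <- nodata
  lines <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", grid$origin[1]),
    sprintf("yllcorner %.17g", grid$origin[2] - nr * grid$cell_size),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %s", sprintf(fmt, nodata)),
    vapply(
      seq_len(nr),
      function(r) paste(sprintf(fmt, vv[r, ]), collapse = " "),
      character(1)
    )
  )
  writeLines(lines, path)
  meta <- list(crs = grid$crs, linear_unit = "meter")
  if (!is.null(grid$legend)) meta$legend <- as.list(grid$legend)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster grid from an ESRI ASCII grid file
#'
#' Expects the JSON sidecar written by [write_raster()] next to the `.asc`
#' file; a missing sidecar or missing CRS tag is a validation error (the
#' package refuses to guess georeferencing), and geographic-degree CRS tags
#' are rejected because all downstream analysis assumes metric cells.
#'
#' @param path Path to the `.asc` file.
#' @return A `raster_grid` with nodata cells masked as `NA`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read raster: file '%s' does not exist.", path))
  }
  lines <- readLines(path)
  if (length(lines) < 7L) abort(sprintf("'%s' is not an ASCII grid file.", path))
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    abort(sprintf("'%s' is missing ASCII grid header fields.", path))
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc) {
    abort(sprintf(
      "'%s': expected %d cell values, found %d.", path, nr * nc, length(body)
    ))
  }
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == hdr$nodata_value] <- NA_real_
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    abort(sprintf(
      "Raster '%s' has no georeferencing sidecar ('%s'); refusing to guess a CRS.",
      path, sp
    ))
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta$crs)) {
    abort(sprintf("Sidecar '%s' carries no `crs` tag.", sp))
  }
  legend <- NULL
  if (!is.null(meta$legend)) legend <- unlist(meta$legend)
  raster_grid(
    values = v,
    cell_size = hdr$cellsize,
    origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
    crs = meta$crs,
    legend = legend
  )
}

# ---------------------------------------------------------------------------
# Occurrence records
# ---------------------------------------------------------------------------

modeled_seasons <- c("spring", "summer", "autumn")

#' Build a validated occurrence table
#'
#' Occurrence records are plain tibbles with columns `x`, `y` (projected
#' meters), `season`, `label` and `source`. Winter is not a modeled season
#' (fires are rare and were excluded from the study design), so `season`
#' must be one of `"spring"`, `"summer"`, `"autumn"`.
#'
#' @param x,y Projected coordinates in meters.
#' @param season Season tag per record (recycled if length 1).
#' @param label `"presence"` or `"pseudo_absence"` (recycled if length 1).
#' @param source Free-text provenance tag (recycled).
#' @return A tibble with class `occurrence_set`.
#' @export
occurrence_set <- function(x, y, season, label = "presence", source = "unknown") {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  out <- tibble(
    x = as.numeric(x),
    y = as.numeric(y),
    season = rep_len(as.character(season), n),
    label = rep_len(as.character(label), n),
    source = rep_len(as.character(source), n)
  )
  validate_occurrences(out)
}

validate_occurrences <- function(points) {
  if (!is.data.frame(points)) abort("`points` must be a data frame.")
  need <- c("x", "y", "season", "label")
  missing <- setdiff(need, names(points))
  if (length(missing) > 0L) {
    abort(sprintf("`points` is missing columns: %s.", paste(missing, collapse = ", ")))
  }
  bad_season <- setdiff(unique(points$season), modeled_seasons)
  if (length(bad_season) > 0L) {
    abort(sprintf(
      "Unsupported season(s): %s. Modeled seasons are %s (winter is excluded).",
      paste(bad_season, collapse = ", "), paste(modeled_seasons, collapse = ", ")
    ))
  }
  bad_label <- setdiff(unique(points$label), c("presence", "pseudo_absence"))
  if (length(bad_label) > 0L) {
    abort(sprintf("Unsupported label(s): %s.", paste(bad_label, collapse = ", ")))
  }
  out <- as_tibble(points)
  class(out) <- unique(c("occurrence_set", class(out)))
  out
}

#' Read occurrence points from CSV
#'
#' Expects a header `x,y,season,label,source` (`label`/`source` optional,
#' defaulting to presence records of unknown source).
#'
#' @param path CSV path.
#' @return An `occurrence_set` tibble.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$label)) df$label <- "presence"
  if (is.null(df$source)) df$source <- "unknown"
  validate_occurrences(df)
}

#' Write occurrence points to CSV
#'
#' @param points Occurrence tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(points, path) {
  points <- validate_occurrences(points)
  utils::write.csv(
    points[, c("x", "y", "season", "label", "source")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' Sample raster layers at point locations
#'
#' Nearest-cell (containing-cell) sampling under the half-open cell
#' convention. Points outside the stack extent, and points whose cell is
#' nodata in any layer, are dropped from the feature table; the counts are
#' reported in the `dropped` attribute and via a message so runs are
#' auditable.
#'
#' @param stack A `raster_stack`.
#' @param points Data frame with `x` and `y` columns (projected meters).
#' @param quiet Suppress the drop-count message.
#' @return A tibble: the retained input columns plus one numeric column per
#'   layer, row order matching the retained input order. Attribute `dropped`
#'   is a tibble of drop reasons and counts.
#' @export
extract_at_points <- function(stack, points, quiet = FALSE) {
  if (!inherits(stack, "raster_stack")) abort("`stack` must be a raster_stack.")
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    abort("`points` must be a data frame with `x` and `y` columns.")
  }
  if (nrow(points) == 0L) {
    abort("`points` is empty; nothing to extract.")
  }
  ref <- stack$layers[[1L]]
  rc <- point_to_cell(ref, points$x, points$y)
  n_outside <- sum(!rc$inside)
  if (n_outside == nrow(points)) {
    abort("All points fall outside the stack extent; the feature table would be empty.")
  }
  idx_in <- which(rc$inside)
  lin <- cbind(rc$row[idx_in], rc$col[idx_in])
  feats <- lapply(stack$layers, function(g) g$values[lin])
  feat_mat <- do.call(cbind, feats)
  ok <- stats::complete.cases(feat_mat)
  n_nodata <- sum(!ok)
  keep <- idx_in[ok]
  out <- as_tibble(points[keep, , drop = FALSE])
  for (j in seq_along(stack$layers)) {
    out[[names(stack$layers)[j]]] <- as.vector(feat_mat[ok, j])
  }
  if (nrow(out) == 0L) {
    abort("Every in-extent point hit a nodata cell; the feature table is empty.")
  }
  dropped <- tibble(
    reason = c("outside_extent", "nodata_cell"),
    n = c(n_outside, n_nodata)
  )
  attr(out, "dropped") <- dropped
  if (!quiet && (n_outside + n_nodata) > 0L) {
    inform(sprintf(
      "extract_at_points: dropped %d point(s) outside the extent and %d on nodata cells.",
      n_outside, n_nodata
    ))
  }
  out
}
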