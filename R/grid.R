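#' Grid specification
#'
#' Describes a regular raster grid. Synthetic grids are planar and equal-area
#' by construction: map units are kilometres, so one cell covers
#' \code{cell_size^2} km2 and no latitude correction is needed. Grids whose
#' \code{crs_tag} contains \code{"longlat"} are treated as geographic
#' (degrees); their per-cell area is computed with a cosine-latitude
#' correction by [cell_area_grid()].
#'
#' The origin is the lower-left corner of the grid. Values are stored as
#' matrices with row 1 at the top (northernmost) row, the usual raster
#' convention.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param origin_x,origin_y Coordinates of the lower-left corner, map units.
#' @param cell_size Cell edge length in map units (> 0).
#' @param crs_tag Free-text tag; \code{"longlat"} marks geographic grids.
#' @return A \code{grid_spec} object.
#' @export
grid_spec <- function(n_rows, n_cols, origin_x = 0, origin_y = 0,
                      cell_size = 1, crs_tag = "planar-km") {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 origin_x = origin_x, origin_y = origin_y,
                 cell_size = cell_size, crs_tag = as.character(crs_tag)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell %g, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_tag))
  invisible(x)
}

grid_is_geographic <- function(spec) grepl("longlat", spec$crs_tag, fixed = TRUE)

n_cells <- function(spec) spec$n_rows * spec$n_cols

#' Cell-centre coordinates
#'
#' @param spec A [grid_spec()].
#' @return Data frame with columns \code{cell}, \code{row}, \code{col},
#'   \code{x}, \code{y}, one row per cell in row-major order (row 1 first).
#' @export
cell_centers <- function(spec) {
  row <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  col <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  data.frame(cell = seq_len(n_cells(spec)), row = row, col = col,
             x = spec$origin_x + (col - 0.5) * spec$cell_size,
             y = spec$origin_y + (spec$n_rows - row + 0.5) * spec$cell_size)
}

#' Locate points on a grid
#'
#' @param spec A [grid_spec()].
#' @param x,y Point coordinates (map units).
#' @return Data frame with \code{row}, \code{col}, \code{cell}; \code{NA} for
#'   points outside the grid extent.
#' @export
cell_from_xy <- function(spec, x, y) {
  stopifnot(length(x) == length(y))
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1
  row_from_bottom <- floor((y - spec$origin_y) / spec$cell_size) + 1
  row <- spec$n_rows - row_from_bottom + 1
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1) * spec$n_cols + col))
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_unless_coregistered <- function(a, b) {
  if (!same_grid(a, b)) stop("grids are not co-registered")
  invisible(TRUE)
}

#' Continuous suitability map
#'
#' Grid of habitat-suitability values in [0, 1] with an NA nodata mask.
#'
#' @param values Numeric matrix (\code{n_rows x n_cols}); values in [0, 1]
#'   or NA.
#' @param spec The [grid_spec()] the values live on.
#' @param provenance Free-form list (algorithm set, scenario key, ...).
#' @return A \code{suitability_map}.
#' @export
suitability_map <- function(values, spec, provenance = list()) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == spec$n_rows, ncol(values) == spec$n_cols)
  rng <- range(values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    stop("suitability values must lie in [0, 1]")
  structure(list(values = values, spec = spec, provenance = provenance),
            class = "suitability_map")
}

#' Binary presence/absence map
#'
#' @param values Matrix of 0/1 with NA nodata.
#' @param spec The [grid_spec()].
#' @param threshold Threshold used to produce the map (recorded, may be NA).
#' @param scenario Optional [scenario_key()] or label.
#' @return A \code{binary_map}.
#' @export
binary_map <- function(values, spec, threshold = NA_real_, scenario = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == spec$n_rows, ncol(values) == spec$n_cols)
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("binary map values must be 0, 1 or NA")
  structure(list(values = values, spec = spec, threshold = threshold,
                 scenario = scenario),
            class = "binary_map")
}

is_binary_map <- function(x) inherits(x, "binary_map")

#' Named stack of co-registered climate layers
#'
#' @param layers Named list of numeric matrices, one per bioclimatic
#'   variable, all on \code{spec}.
#' @param spec The shared [grid_spec()].
#' @param scenario Optional [scenario_key()].
#' @return A \code{climate_stack}.
#' @export
climate_stack <- function(layers, spec, scenario = NULL) {
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must carry unique non-empty names")
  for (l in layers) {
    l <- as.matrix(l)
    stopifnot(nrow(l) == spec$n_rows, ncol(l) == spec$n_cols)
  }
  structure(list(layers = lapply(layers, as.matrix), spec = spec,
                 scenario = scenario),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d layers (%s) on %d x %d grid\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

# ---- ESRI ASCII grid I/O ------------------------------------------------
# Plain-text single-band raster exchange format (header of six key/value
# lines followed by the value matrix). No installed package reads it, and it
# is the only standard text raster format, so the reader/writer live here.

#' Write a raster to an ESRI ASCII grid file
#'
#' @param values Matrix, or a [suitability_map()] / [binary_map()].
#' @param spec [grid_spec()]; ignored when \code{values} carries its own.
#' @param path Output path (conventionally \code{.asc}).
#' @param nodata Nodata sentinel written in place of NA.
#' @export
write_asc <- function(values, path, spec = NULL, nodata = -9999) {
  if (inherits(values, c("suitability_map", "binary_map"))) {
    spec <- values$spec
    values <- values$values
  }
  stopifnot(inherits(spec, "grid_spec"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x),
    sprintf("yllcorner %.10g", spec$origin_y),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 15),
                                           collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path File path.
#' @param crs_tag Tag recorded on the returned grid spec.
#' @return List with \code{values} (matrix, NA for nodata) and \code{spec}.
#' @export
read_asc <- function(path, crs_tag = "planar-km") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  vals <- scan(text = paste(body, collapse = "\n"), quiet = TRUE)
  spec <- grid_spec(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                    hdr$cellsize, crs_tag)
  m <- matrix(vals, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, spec = spec)
}
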