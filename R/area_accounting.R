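# Area bookkeeping between binary suitability maps: maintained / lost /
# gained areas under two explicit denominator conventions, stable climate
# refuges (cells suitable in every period), and protected-area overlap.

#' Per-cell area grid
#'
#' Planar grids (map units km) have uniform cell area \code{cell_size^2}
#' km2. Geographic grids (cell size in degrees) use
#' \code{(111.32 km x cellsize)^2 x cos(latitude)} at each cell-centre
#' latitude.
#'
#' @param spec A [grid_spec()].
#' @return Matrix of per-cell areas in km2.
#' @export
cell_area_grid <- function(spec) {
  if (!grid_is_geographic(spec))
    return(matrix(spec$cell_size^2, spec$n_rows, spec$n_cols))
  row <- seq_len(spec$n_rows)
  lat <- spec$origin_y + (spec$n_rows - row + 0.5) * spec$cell_size
  a <- (111.32 * spec$cell_size)^2 * cos(lat * pi / 180)
  matrix(a, spec$n_rows, spec$n_cols)
}

masked_area <- function(mask, area) sum(area[mask], na.rm = TRUE)

#' Maintained, lost and gained areas between two periods
#'
#' maintained = area(p1 AND p2), lost = area(p1 minus p2), gained =
#' area(p2 minus p1), all through the cell-area grid. Percentages are added
#' separately by [change_percentages()] under a declared convention.
#'
#' @param map_p1,map_p2 Co-registered [binary_map()]s for the two periods.
#' @return A \code{change_report} (areas filled, percentages NA).
#' @export
change_areas <- function(map_p1, map_p2) {
  stop_unless_coregistered(map_p1$spec, map_p2$spec)
  area <- cell_area_grid(map_p1$spec)
  a <- !is.na(map_p1$values) & map_p1$values == 1
  b <- !is.na(map_p2$values) & map_p2$values == 1
  change_report(area_p1 = masked_area(a, area),
                area_p2 = masked_area(b, area),
                maintained = masked_area(a & b, area),
                lost = masked_area(a & !b, area),
                gained = masked_area(!a & b, area))
}

#' Construct a change report from raw areas
#'
#' Useful when the areas come from an external table rather than from maps.
#'
#' @param area_p1,area_p2,maintained,lost,gained Areas in km2.
#' @return A \code{change_report} with percentage fields unset.
#' @export
change_report <- function(area_p1, area_p2, maintained, lost, gained) {
  structure(list(area_p1 = area_p1, area_p2 = area_p2,
                 maintained = maintained, lost = lost, gained = gained,
                 maintained_pct = NA_real_, lost_pct = NA_real_,
                 gained_pct = NA_real_, convention = NA_character_),
            class = "change_report")
}

#' Complete a change report with percentages
#'
#' Two denominator conventions are supported, matching the two ways such
#' tables are commonly printed: \code{"P1_ALL"} divides maintained, lost
#' and gained by the period-1 area; \code{"P1_MAINT_LOST_P2_GAIN"} divides
#' maintained and lost by the period-1 area but gained by the period-2 area
#' (a gain can only be expressed relative to the range it enlarges).
#'
#' @param report A \code{change_report} with areas filled.
#' @param convention \code{"P1_ALL"} or \code{"P1_MAINT_LOST_P2_GAIN"}.
#' @return The completed \code{change_report}.
#' @export
change_percentages <- function(report,
                               convention = c("P1_ALL",
                                              "P1_MAINT_LOST_P2_GAIN")) {
  convention <- match.arg(convention)
  if (report$area_p1 <= 0)
    stop("zero period-1 area: percentages undefined")
  gain_den <- if (convention == "P1_ALL") report$area_p1 else report$area_p2
  if (gain_den <= 0) stop("zero gain denominator: percentages undefined")
  report$maintained_pct <- 100 * report$maintained / report$area_p1
  report$lost_pct <- 100 * report$lost / report$area_p1
  report$gained_pct <- 100 * report$gained / gain_den
  report$convention <- convention
  report
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf(paste0("<change_report> p1 %.0f km2, p2 %.0f km2 | maintained ",
                     "%.0f (%.2f%%), lost %.0f (%.2f%%), gained %.0f (%.2f%%)",
                     " [%s]\n"),
              x$area_p1, x$area_p2, x$maintained, x$maintained_pct,
              x$lost, x$lost_pct, x$gained, x$gained_pct, x$convention))
  invisible(x)
}

#' Stable climate refuge
#'
#' Cells suitable in every compared period: the cellwise intersection of
#' all binary maps.
#'
#' @param maps List of >= 2 co-registered [binary_map()]s.
#' @return A [binary_map()] flagging refuge cells.
#' @export
stable_refuge <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 maps")
  spec <- maps[[1]]$spec
  acc <- matrix(1, spec$n_rows, spec$n_cols)
  for (m in maps) {
    stop_unless_coregistered(spec, m$spec)
    v <- m$values
    v[is.na(v)] <- 0  # unresolved cells cannot be a refuge
    acc <- acc * v
  }
  binary_map(acc, spec)
}

#' Rasterise polygons onto a grid
#'
#' A cell belongs to the mask iff its centre falls inside any polygon.
#'
#' @param polys Polygon or list of polygons.
#' @param spec A [grid_spec()].
#' @return A [binary_map()].
#' @export
rasterize_polygons <- function(polys, spec) {
  cc <- cell_centers(spec)
  inside <- points_in_polygon(cc$x, cc$y, polys)
  m <- matrix(0, spec$n_rows, spec$n_cols)
  m[cbind(cc$row, cc$col)] <- as.numeric(inside)
  binary_map(m, spec)
}

#' Protected-area coverage of the suitable range
#'
#' Rasterises the protected-area union onto the grid and reports
#' 100 x area(suitable AND protected) / area(suitable), overall and per
#' optional region polygon. Invalid polygons (degenerate area) are skipped
#' with a warning.
#'
#' @param suitable A [binary_map()] of the suitable range.
#' @param pa_polygons Protected-area polygon(s).
#' @param regions Optional named list of region polygons (e.g. countries).
#' @return Data frame: \code{region}, \code{suitable_km2},
#'   \code{protected_km2}, \code{percent_protected}.
#' @export
protection_overlap <- function(suitable, pa_polygons, regions = NULL) {
  if (is.matrix(pa_polygons) || is.data.frame(pa_polygons))
    pa_polygons <- list(pa_polygons)
  valid <- vapply(pa_polygons, function(p) {
    ok <- tryCatch(polygon_area(p) > 0, error = function(e) FALSE)
    if (!ok) warning("skipping invalid protected-area polygon")
    ok
  }, logical(1))
  pa_polygons <- pa_polygons[valid]
  spec <- suitable$spec
  area <- cell_area_grid(spec)
  s <- !is.na(suitable$values) & suitable$values == 1
  pa <- if (length(pa_polygons)) rasterize_polygons(pa_polygons, spec)$values == 1
        else matrix(FALSE, spec$n_rows, spec$n_cols)
  one_row <- function(label, mask) {
    s_km2 <- masked_area(s & mask, area)
    p_km2 <- masked_area(s & pa & mask, area)
    data.frame(region = label, suitable_km2 = s_km2, protected_km2 = p_km2,
               percent_protected = if (s_km2 > 0) 100 * p_km2 / s_km2
                                   else NA_real_)
  }
  out <- one_row("overall", matrix(TRUE, spec$n_rows, spec$n_cols))
  if (!is.null(regions)) {
    nm <- names(regions)
    if (is.null(nm)) nm <- paste0("region_", seq_along(regions))
    for (i in seq_along(regions))
      out <- rbind(out, one_row(nm[i],
                                rasterize_polygons(regions[[i]], spec)$values == 1))
  }
  rownames(out) <- NULL
  out
}
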