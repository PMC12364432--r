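# Occurrence cleaning and design of the modeling point sets: range filter,
# one-per-cell thinning, background sampling within the accessible area, and
# congener-based absence records.

occ_roles <- c("presence", "congener_absence", "background")

#' Occurrence record set
#'
#' @param records Data frame with columns \code{species}, \code{x}, \code{y},
#'   \code{role} (one of presence / congener_absence / background) and
#'   optionally \code{source}.
#' @return An \code{occurrence_set} (a validated data frame).
#' @export
occurrence_set <- function(records) {
  records <- as.data.frame(records)
  need <- c("species", "x", "y", "role")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"source" %in% names(records)) records$source <- ""
  if (nrow(records)) {
    if (!all(is.finite(records$x)) || !all(is.finite(records$y)))
      stop("coordinates must be finite")
    if (!all(records$role %in% occ_roles))
      stop("invalid role(s): ",
           paste(unique(setdiff(records$role, occ_roles)), collapse = ", "))
  }
  rownames(records) <- NULL
  structure(records[, c("species", "x", "y", "role", "source")],
            class = c("occurrence_set", "data.frame"))
}

#' Read / write occurrence CSV
#'
#' Columns \code{species,x,y,role,source} (\code{x}/\code{y} are lon/lat for
#' geographic data).
#' @param path File path.
#' @param occ An [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Background-sampling design
#'
#' @param radius Buffer radius around each presence, km (typically the mean
#'   hull-vertex-to-centroid distance, see [hull_background_radius()]).
#' @param multiplier Background points per presence (default 10).
#' @param fixed_count Optional absolute count overriding the multiplier
#'   (e.g. 10,000 for predictor screening).
#' @return A \code{background_spec}.
#' @export
background_spec <- function(radius, multiplier = 10, fixed_count = NULL) {
  stopifnot(radius > 0, multiplier >= 1)
  structure(list(radius = radius, multiplier = as.integer(multiplier),
                 fixed_count = if (is.null(fixed_count)) NULL
                               else as.integer(fixed_count)),
            class = "background_spec")
}

#' Retain records inside a (buffered) range polygon
#'
#' Records farther than \code{buffer_km} from the range polygon are dropped;
#' record order is preserved. Distances are Euclidean on planar grids and
#' haversine (Earth radius 6371 km) on geographic coordinates.
#'
#' @param occ An [occurrence_set()].
#' @param range_polygon Species range polygon.
#' @param buffer_km Dilation distance (>= 0), same units as coordinates for
#'   planar data (km), kilometres for geographic data.
#' @param geographic Coordinates are lon/lat degrees.
#' @return Filtered [occurrence_set()].
#' @export
range_filter <- function(occ, range_polygon, buffer_km = 100,
                         geographic = FALSE) {
  stopifnot(buffer_km >= 0)
  if (polygon_area(range_polygon) <= 0) stop("empty range polygon")
  if (nrow(occ) == 0) return(occ)
  if (geographic) {
    inside <- points_in_polygon(occ$x, occ$y, range_polygon)
    p <- polygon_ring(range_polygon)
    d <- vapply(seq_len(nrow(occ)), function(i) {
      if (inside[i]) 0 else min(haversine_km(occ$x[i], occ$y[i], p[, 1], p[, 2]))
    }, numeric(1))
  } else {
    d <- dist_points_polygon(occ$x, occ$y, range_polygon)
  }
  occurrence_set(occ[d <= buffer_km, , drop = FALSE])
}

#' Thin records to one per grid cell
#'
#' Exact duplicate coordinates (multi-database compilations) are collapsed
#' first; then the first-encountered record in each occupied cell is kept.
#' Records outside the grid are dropped with a warning.
#'
#' @param occ An [occurrence_set()].
#' @param spec A [grid_spec()].
#' @return Thinned [occurrence_set()].
#' @export
thin_one_per_cell <- function(occ, spec) {
  if (nrow(occ) == 0) return(occ)
  occ <- occ[!duplicated(occ[, c("x", "y")]), , drop = FALSE]
  loc <- cell_from_xy(spec, occ$x, occ$y)
  if (anyNA(loc$cell)) {
    warning(sum(is.na(loc$cell)), " record(s) outside the grid dropped")
    keep <- !is.na(loc$cell)
    occ <- occ[keep, , drop = FALSE]
    loc <- loc[keep, , drop = FALSE]
  }
  occurrence_set(occ[!duplicated(loc$cell), , drop = FALSE])
}

#' Background radius from the presence convex hull
#'
#' The accessible-area radius is the mean distance between the vertices of
#' the presence convex hull (the most peripheral points) and the hull
#' centroid.
#'
#' @param occ An [occurrence_set()] with >= 3 non-collinear presences.
#' @param geographic Coordinates are lon/lat degrees.
#' @return Radius in km (map units for planar data).
#' @export
hull_background_radius <- function(occ, geographic = FALSE) {
  pres <- occ[occ$role == "presence", , drop = FALSE]
  if (nrow(pres) < 3) stop("need at least 3 presences")
  h <- grDevices::chull(pres$x, pres$y)
  if (length(h) < 3) stop("degenerate (collinear) convex hull")
  hx <- pres$x[h]; hy <- pres$y[h]
  cen <- polygon_centroid(cbind(hx, hy))
  mean(point_distance(hx, hy, cen[1], cen[2], geographic))
}

#' Sample background points within the accessible area
#'
#' Draws uniform random grid cells within the union of radius-disks around
#' the presences, excluding cells that contain a presence. The count is
#' \code{multiplier x n_presences} unless \code{fixed_count} is set.
#'
#' @param occ An [occurrence_set()] containing presences.
#' @param spec A [background_spec()].
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param geographic Coordinates are lon/lat degrees.
#' @return An [occurrence_set()] with role \code{"background"}.
#' @export
sample_background <- function(occ, spec, grid, seed = 1, geographic = FALSE) {
  stopifnot(inherits(spec, "background_spec"))
  pres <- occ[occ$role == "presence", , drop = FALSE]
  if (nrow(pres) == 0) stop("no presences to buffer")
  n_bg <- if (!is.null(spec$fixed_count)) spec$fixed_count
          else spec$multiplier * nrow(pres)
  cc <- cell_centers(grid)
  within <- rep(FALSE, nrow(cc))
  for (i in seq_len(nrow(pres)))
    within <- within | point_distance(cc$x, cc$y, pres$x[i], pres$y[i],
                                      geographic) <= spec$radius
  pres_cells <- cell_from_xy(grid, pres$x, pres$y)$cell
  admissible <- which(within & !(cc$cell %in% pres_cells))
  if (length(admissible) < n_bg)
    stop("insufficient admissible cells (", length(admissible),
         ") for ", n_bg, " background points")
  idx <- with_seed(seed, sample(admissible, n_bg))
  occurrence_set(data.frame(species = "background", x = cc$x[idx],
                            y = cc$y[idx], role = "background",
                            source = "sampled"))
}

#' Build absence records from congener occurrences
#'
#' Congener points closer than \code{exclusion_km} to the target species'
#' range (including points inside it) are removed, to avoid overlap zones
#' and misidentified records; survivors are relabelled as absences.
#'
#' @param congener_occ An [occurrence_set()] of congener records.
#' @param target_range Target species range polygon.
#' @param exclusion_km Exclusion radius around the range (>= 0).
#' @param geographic Coordinates are lon/lat degrees.
#' @return An [occurrence_set()] with role \code{"congener_absence"}.
#' @export
congener_absences <- function(congener_occ, target_range, exclusion_km = 100,
                              geographic = FALSE) {
  stopifnot(exclusion_km >= 0)
  if (nrow(congener_occ) == 0) return(congener_occ)
  if (geographic) {
    inside <- points_in_polygon(congener_occ$x, congener_occ$y, target_range)
    p <- polygon_ring(target_range)
    d <- vapply(seq_len(nrow(congener_occ)), function(i) {
      if (inside[i]) 0
      else min(haversine_km(congener_occ$x[i], congener_occ$y[i], p[, 1], p[, 2]))
    }, numeric(1))
  } else {
    d <- dist_points_polygon(congener_occ$x, congener_occ$y, target_range)
  }
  out <- congener_occ[d > exclusion_km, , drop = FALSE]
  out$role <- rep("congener_absence", nrow(out))
  occurrence_set(out)
}
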