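# Planar vector geometry: polygons are numeric matrices with columns x, y
# (one ring, implicitly closed); a polygon set is a list of such rings.
# Point-in-polygon testing delegates to mgcv::in.out.

#' Build a rectangular polygon
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds (map units).
#' @return A polygon (two-column matrix of vertices, counter-clockwise).
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

polygon_ring <- function(poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  poly
}

#' Polygon area (shoelace formula)
#'
#' @param poly Polygon matrix.
#' @return Absolute area in squared map units.
#' @export
polygon_area <- function(poly) {
  p <- polygon_ring(poly)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(poly) {
  p <- polygon_ring(poly)
  x <- p[, 1]; y <- p[, 2]
  j <- c(2:nrow(p), 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))  # degenerate: vertex mean
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

#' Point-in-polygon test
#'
#' @param x,y Point coordinates.
#' @param poly A polygon or a list of polygons (union).
#' @return Logical vector; TRUE for points inside any ring.
#' @export
points_in_polygon <- function(x, y, poly) {
  if (is.matrix(poly) || is.data.frame(poly)) poly <- list(poly)
  pts <- cbind(x, y)
  inside <- rep(FALSE, length(x))
  for (p in poly) {
    p <- polygon_ring(p)
    inside <- inside | mgcv::in.out(rbind(p, p[1, , drop = FALSE]), pts)
  }
  inside
}

# Distance from points to a polygon boundary/interior: 0 inside, else the
# minimum distance to any edge segment.
dist_points_polygon <- function(x, y, poly) {
  p <- polygon_ring(poly)
  n <- nrow(p)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- p[c(2:n, 1), 1]; by <- p[c(2:n, 1), 2]
  d <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    vx <- bx[i] - ax[i]; vy <- by[i] - ay[i]
    len2 <- vx^2 + vy^2
    t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((x - ax[i]) * vx + (y - ay[i]) * vy) / len2))
    d <- pmin(d, sqrt((x - (ax[i] + t * vx))^2 + (y - (ay[i] + t * vy))^2))
  }
  d[points_in_polygon(x, y, poly)] <- 0
  d
}

#' Great-circle distance (haversine)
#'
#' Used when occurrence coordinates are geographic (degrees); planar inputs
#' use plain Euclidean distance. Earth radius fixed at 6371 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Pairwise point distance honouring the coordinate system.
point_distance <- function(x1, y1, x2, y2, geographic = FALSE) {
  if (geographic) haversine_km(x1, y1, x2, y2)
  else sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

# ---- GeoJSON polygon I/O ------------------------------------------------

#' Write a polygon set as GeoJSON
#'
#' @param polys A polygon or list of polygons.
#' @param path Output path.
#' @param properties Optional data frame of per-polygon properties.
#' @export
write_geojson <- function(polys, path, properties = NULL) {
  if (is.matrix(polys) || is.data.frame(polys)) polys <- list(polys)
  feats <- lapply(seq_along(polys), function(i) {
    p <- polygon_ring(polys[[i]])
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature",
         properties = if (is.null(properties)) setNames(list(), character(0))
                      else as.list(properties[i, , drop = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(k) as.numeric(ring[k, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Supports Polygon and MultiPolygon features; only outer rings are kept.
#'
#' @param path File path.
#' @return List of polygon matrices.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt)[1:2])))
    colnames(m) <- c("x", "y")
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  for (f in feats) {
    g <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(g$type, "Polygon")) {
      out[[length(out) + 1L]] <- ring_to_matrix(g$coordinates[[1]])
    } else if (identical(g$type, "MultiPolygon")) {
      for (pg in g$coordinates)
        out[[length(out) + 1L]] <- ring_to_matrix(pg[[1]])
    }
  }
  out
}
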