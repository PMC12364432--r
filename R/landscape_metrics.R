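# Landscape structure of the woody vegetation: 4-connected fragment
# extraction with raster-edge perimeters, the fragmentation index
# FI = total area / total perimeter (km; lower = more fragmented) and the
# mean centroid-distance connectivity index (km; higher = less connected).

#' Extract woody fragments from a binary land-cover raster
#'
#' Fragments are 4-connected (rook) components of woody cells. Area is cell
#' count times cell area; perimeter counts exposed cell edges (staircase
#' perimeter, so values are resolution-dependent); the centroid is the mean
#' of member cell centres. Fragments smaller than the minimum home range
#' are excluded.
#'
#' @param woody A [binary_map()] (1 = woody).
#' @param min_area_ha Minimum fragment area in hectares (default 11.875,
#'   the minimum home range of the target species).
#' @return A \code{fragment_set}: data frame with \code{id}, \code{area_km2},
#'   \code{perimeter_km}, \code{centroid_x}, \code{centroid_y},
#'   \code{n_cells}; the pre-filter totals are attached as attributes
#'   \code{total_area_km2} / \code{total_perimeter_km}.
#' @export
extract_fragments <- function(woody, min_area_ha = 11.875) {
  v <- woody$values
  if (all(is.na(v))) stop("all-nodata raster")
  spec <- woody$spec
  nr <- spec$n_rows; nc <- spec$n_cols
  wood <- !is.na(v) & v == 1
  cell_area <- spec$cell_size^2          # km2 (planar map units are km)
  idx <- which(wood)                     # column-major indices
  empty <- data.frame(id = integer(0), area_km2 = numeric(0),
                      perimeter_km = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), n_cells = integer(0))
  if (length(idx) == 0)
    return(structure(empty, total_area_km2 = 0, total_perimeter_km = 0,
                     class = c("fragment_set", "data.frame")))
  pos <- match(seq_len(nr * nc), idx)    # cell -> compact id
  # rook edges between woody cells (down and right neighbours)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  down <- which(r < nr)
  down <- down[wood[idx[down] + 1L]]
  right <- which(c < nc)
  right <- right[wood[idx[right] + nr]]
  edges <- rbind(cbind(down, pos[idx[down] + 1L]),
                 cbind(right, pos[idx[right] + nr]))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # exposed edges per cell: 4 minus number of woody rook neighbours
  up_ok    <- r > 1L  & wood[pmax(idx - 1L, 1L)]
  down_ok  <- r < nr  & wood[pmin(idx + 1L, nr * nc)]
  left_ok  <- c > 1L  & wood[pmax(idx - nr, 1L)]
  right_ok <- c < nc  & wood[pmin(idx + nr, nr * nc)]
  exposed <- 4L - (up_ok + down_ok + left_ok + right_ok)
  cx <- spec$origin_x + (c - 0.5) * spec$cell_size
  cy <- spec$origin_y + (nr - r + 0.5) * spec$cell_size
  frag <- data.frame(
    id = seq_len(max(comp)),
    area_km2 = as.numeric(tapply(rep(cell_area, length(idx)), comp, sum)),
    perimeter_km = as.numeric(tapply(exposed * spec$cell_size, comp, sum)),
    centroid_x = as.numeric(tapply(cx, comp, mean)),
    centroid_y = as.numeric(tapply(cy, comp, mean)),
    n_cells = as.integer(tapply(comp, comp, length)))
  total_area <- sum(frag$area_km2)
  total_perim <- sum(frag$perimeter_km)
  min_km2 <- min_area_ha / 100
  frag <- frag[frag$area_km2 >= min_km2, , drop = FALSE]
  frag$id <- seq_len(nrow(frag))
  rownames(frag) <- NULL
  structure(frag, total_area_km2 = total_area,
            total_perimeter_km = total_perim,
            class = c("fragment_set", "data.frame"))
}

#' Fragmentation index
#'
#' FI = total woody area / total woody perimeter (km2/km = km); decreasing
#' values indicate increasing fragmentation. Accepts either an extracted
#' [extract_fragments()] set or pre-summed totals.
#'
#' @param frags A \code{fragment_set} (ignored when totals are given).
#' @param total_area,total_perimeter Optional pre-summed totals (km2, km).
#' @return FI in km.
#' @export
fragmentation_index <- function(frags = NULL, total_area = NULL,
                                total_perimeter = NULL) {
  if (is.null(total_area) || is.null(total_perimeter)) {
    if (is.null(frags) || nrow(frags) < 1)
      stop("need at least one fragment or pre-summed totals")
    total_area <- sum(frags$area_km2)
    total_perimeter <- sum(frags$perimeter_km)
  }
  if (total_perimeter <= 0) stop("zero total perimeter")
  total_area / total_perimeter
}

#' Mean centroid-distance connectivity index
#'
#' For each fragment, the mean distance from its centroid to every other
#' fragment's centroid; these per-fragment means are averaged into one
#' value (identical to the mean over all ordered pairs). Increasing values
#' indicate decreasing connectivity.
#'
#' @param frags A \code{fragment_set} with >= 2 fragments.
#' @return Mean centroid distance in km.
#' @export
connectivity_index <- function(frags) {
  if (nrow(frags) < 2)
    stop("connectivity undefined for fewer than 2 fragments")
  d <- as.matrix(stats::dist(cbind(frags$centroid_x, frags$centroid_y)))
  mean(rowSums(d) / (nrow(frags) - 1))
}

#' Landscape metrics over a yearly land-cover series
#'
#' Per year: optionally clip to a mask (e.g. the dispersal-constrained
#' suitable area), extract fragments, filter by minimum area, and report
#' totals, FI, mean connectivity and fragment count.
#'
#' @param series Named list (year -> [binary_map()] of woody cover).
#' @param clip Optional co-registered [binary_map()]; cells outside it are
#'   treated as non-woody.
#' @param min_area_ha Minimum fragment area in hectares.
#' @return Data frame with one row per year: \code{year},
#'   \code{area_km2}, \code{perimeter_km}, \code{fi},
#'   \code{mean_connectivity_km}, \code{n_fragments}, \code{empty} flag.
#' @export
landscape_series <- function(series, clip = NULL, min_area_ha = 11.875) {
  if (length(series) == 0) stop("empty land-cover series")
  yrs <- names(series)
  if (is.null(yrs)) stop("series must be named by year")
  do.call(rbind, lapply(yrs, function(y) {
    woody <- series[[y]]
    if (!is.null(clip)) {
      stop_unless_coregistered(woody$spec, clip$spec)
      v <- woody$values
      v[!is.na(v)] <- v[!is.na(v)] *
        ifelse(is.na(clip$values[!is.na(v)]), 0, clip$values[!is.na(v)])
      woody <- binary_map(v, woody$spec)
    }
    frag <- extract_fragments(woody, min_area_ha)
    if (nrow(frag) == 0) {
      data.frame(year = as.integer(y), area_km2 = 0, perimeter_km = 0,
                 fi = NA_real_, mean_connectivity_km = NA_real_,
                 n_fragments = 0L, empty = TRUE)
    } else {
      data.frame(year = as.integer(y),
                 area_km2 = sum(frag$area_km2),
                 perimeter_km = sum(frag$perimeter_km),
                 fi = fragmentation_index(frag),
                 mean_connectivity_km = if (nrow(frag) >= 2)
                   connectivity_index(frag) else NA_real_,
                 n_fragments = nrow(frag), empty = FALSE)
    }
  }))
}
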