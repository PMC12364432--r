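# Dispersal-constrained projection: the maximum dispersal distance (MDD)
# follows the home-range allometry of Bowman and colleagues,
# MDD_one_generation = 40 * sqrt(home range in m2), accumulated linearly
# over the generations spanned by a projection interval; projected suitable
# areas are then clipped to what lies within the accumulated MDD of the
# previously occupied range.

#' Dispersal parameters
#'
#' @param home_range_ha Home-range area in hectares (default 11.875, the
#'   mean group home range of the target howler).
#' @param generation_years Generation time in years (default 10).
#' @param interval_years Projection interval in years (default 20).
#' @return A \code{dispersal_params}.
#' @export
dispersal_params <- function(home_range_ha = 11.875, generation_years = 10,
                             interval_years = 20) {
  stopifnot(home_range_ha > 0, generation_years > 0, interval_years > 0)
  structure(list(home_range_ha = home_range_ha,
                 generation_years = generation_years,
                 interval_years = interval_years),
            class = "dispersal_params")
}

#' Maximum dispersal distance in one generation
#'
#' \code{40 * sqrt(home_range_ha * 10000)} metres: the home range is
#' converted to square metres and the allometric constant 40 applied to its
#' square root (so quadrupling the home range doubles the distance).
#'
#' @param home_range_ha Home-range area in hectares (> 0).
#' @return Distance in metres.
#' @export
mdd_one_generation <- function(home_range_ha) {
  stopifnot(home_range_ha > 0)
  40 * sqrt(home_range_ha * 10000)
}

#' Maximum dispersal distance over a projection interval
#'
#' The one-generation distance times the whole number of generations in the
#' interval; intervals that are not whole multiples of the generation time
#' are rejected.
#'
#' @param params A [dispersal_params()].
#' @return Distance in metres.
#' @export
mdd_interval <- function(params) {
  stopifnot(inherits(params, "dispersal_params"))
  gens <- params$interval_years / params$generation_years
  if (abs(gens - round(gens)) > 1e-9 || gens < 1)
    stop("interval_years (", params$interval_years,
         ") must be a positive whole multiple of generation_years (",
         params$generation_years, "); choose an interval of e.g. ",
         params$generation_years, ", ", 2 * params$generation_years, ", ...")
  mdd_one_generation(params$home_range_ha) * round(gens)
}

# Exact 1-D squared-distance transform (Felzenszwalb & Huttenlocher).
edt_1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Distance to the nearest occupied cell
#'
#' Exact Euclidean distance transform between cell centres: each cell gets
#' the distance (map units) to the centre of the nearest cell that is 1 in
#' \code{occupied}. Cells that are 1 get 0; if no cell is occupied all
#' distances are Inf.
#'
#' @param occupied A [binary_map()].
#' @return Numeric matrix of distances in map units.
#' @export
distance_to_occupied <- function(occupied) {
  v <- occupied$values
  if (!any(!is.na(v) & v == 1))
    return(matrix(Inf, nrow(v), ncol(v)))
  # finite sentinel larger than any squared in-grid distance keeps the
  # parabola intersections well-defined where no source exists yet
  large <- nrow(v)^2 + ncol(v)^2 + 1
  f <- matrix(large, nrow(v), ncol(v))
  f[!is.na(v) & v == 1] <- 0
  for (i in seq_len(nrow(f))) f[i, ] <- edt_1d(f[i, ])
  for (j in seq_len(ncol(f))) f[, j] <- edt_1d(f[, j])
  sqrt(f) * occupied$spec$cell_size
}

#' Clip future suitability to the dispersal-reachable area
#'
#' A cell stays suitable only if it is suitable at time t1 and its centre
#' lies within \code{mdd} of the centre of some cell occupied at t0.
#' Planar map units are kilometres, so \code{mdd} (metres) is converted.
#'
#' @param occupied_t0 [binary_map()] occupied at the start of the interval.
#' @param suitable_t1 [binary_map()] suitable at the end of the interval.
#' @param mdd Maximum dispersal distance in metres (>= 0).
#' @return A [binary_map()] (subset of \code{suitable_t1}).
#' @export
reachable_clip <- function(occupied_t0, suitable_t1, mdd) {
  stop_unless_coregistered(occupied_t0$spec, suitable_t1$spec)
  stopifnot(mdd >= 0)
  d <- distance_to_occupied(occupied_t0)
  reach <- d <= mdd / 1000
  out <- suitable_t1$values
  out[!is.na(out)] <- out[!is.na(out)] * reach[!is.na(out)]
  binary_map(out, suitable_t1$spec, threshold = suitable_t1$threshold,
             scenario = suitable_t1$scenario)
}

#' Chain dispersal clipping across successive periods
#'
#' occupied(k) = reachable_clip(occupied(k-1), suitable(k), MDD per
#' interval), starting from the present occupied map, so the range can only
#' spread by one interval's MDD per step.
#'
#' @param present [binary_map()] occupied at the start.
#' @param future_suitables Ordered list of future [binary_map()]s.
#' @param params A [dispersal_params()] (one interval per step).
#' @return Ordered list of occupied [binary_map()]s, one per future period.
#' @export
iterate_dispersal <- function(present, future_suitables, params) {
  if (length(future_suitables) == 0) stop("no future maps supplied")
  mdd <- mdd_interval(params)
  out <- vector("list", length(future_suitables))
  occupied <- present
  for (k in seq_along(future_suitables)) {
    occupied <- reachable_clip(occupied, future_suitables[[k]], mdd)
    out[[k]] <- occupied
  }
  names(out) <- names(future_suitables)
  out
}
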