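# Synthetic-data generators: every input the workflow consumes (climate
# stacks, occurrences, congener records, land-cover series, protected areas)
# can be produced with known ground truth, so each downstream stage is
# testable without any download.

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a root seed and a stage label, so each
# pipeline stage draws from its own reproducible substream.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

# Separable truncated-Gaussian smoothing (sd = scale, radius = 3 * scale),
# renormalised at the edges so the kernel mass is 1 everywhere.
smooth_gaussian <- function(m, scale) {
  if (scale <= 0) return(m)
  r <- max(1L, ceiling(3 * scale))
  k <- dnorm(seq(-r, r), sd = scale)
  conv_cols <- function(mat) {
    n <- nrow(mat)
    pad <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) out <- out + k[j] * pad[seq_len(n) + (j - 1L), , drop = FALSE]
    out
  }
  ones <- matrix(1, nrow(m), ncol(m))
  num <- t(conv_cols(t(conv_cols(m))))
  den <- t(conv_cols(t(conv_cols(ones))))
  num / den
}

#' Generate a synthetic climate stack
#'
#' Each layer is spatially autocorrelated seeded noise (truncated-Gaussian
#' smoothing of white noise) plus a linear spatial gradient in a random
#' direction, standardised to mean 0 and sd 1. Identical seeds give
#' bitwise-identical stacks.
#'
#' @param spec A [grid_spec()].
#' @param variable_names Unique layer names (e.g. \code{"bio2"}).
#' @param spatial_scale Autocorrelation range in cells (>= 1); larger values
#'   give smoother fields.
#' @param seed Integer seed.
#' @return A [climate_stack()].
#' @export
gen_climate_stack <- function(spec, variable_names, spatial_scale = 5, seed = 1) {
  if (length(variable_names) == 0) stop("variable_names must be nonempty")
  if (anyDuplicated(variable_names)) stop("duplicate variable names")
  if (spatial_scale < 1) stop("spatial_scale must be >= 1")
  cc <- cell_centers(spec)
  layers <- with_seed(seed, {
    lapply(seq_along(variable_names), function(i) {
      noise <- matrix(rnorm(n_cells(spec)), spec$n_rows, spec$n_cols)
      smoothed <- smooth_gaussian(noise, spatial_scale)
      theta <- runif(1, 0, 2 * pi)
      grad_strength <- runif(1, 0.2, 0.8)
      grad <- matrix(NA_real_, spec$n_rows, spec$n_cols)
      grad[cbind(cc$row, cc$col)] <- cos(theta) * cc$x + sin(theta) * cc$y
      field <- smoothed +
        grad_strength * sd(smoothed) / max(sd(grad), 1e-12) * grad
      (field - mean(field)) / sd(field)
    })
  })
  names(layers) <- variable_names
  climate_stack(layers, spec)
}

#' Shift layers of a stack to emulate a future scenario
#'
#' Future climate is modelled as an additive change on named layers (e.g. a
#' uniform warming); all other layers and the grid are untouched.
#'
#' @param stack A [climate_stack()].
#' @param deltas Named numeric vector/list, names a subset of the stack's.
#' @return A new [climate_stack()] on the same grid.
#' @export
gen_future_stack <- function(stack, deltas) {
  deltas <- unlist(deltas)
  unknown <- setdiff(names(deltas), names(stack$layers))
  if (length(unknown)) stop("unknown variable name(s): ",
                            paste(unknown, collapse = ", "))
  layers <- stack$layers
  for (v in names(deltas)) layers[[v]] <- layers[[v]] + deltas[[v]]
  climate_stack(layers, stack$spec, stack$scenario)
}

#' Ground-truth niche definition
#'
#' A logistic niche: suitability = plogis(intercept + sum(coef * value) +
#' sum(quad * value^2)). Used both to sample presences and to score recovery
#' of known parameters.
#'
#' @param intercept Real intercept.
#' @param coefficients Named vector of linear terms.
#' @param quadratic Optional named vector of quadratic terms.
#' @return A \code{niche_truth}.
#' @export
niche_truth <- function(intercept, coefficients, quadratic = NULL) {
  structure(list(intercept = intercept, coefficients = unlist(coefficients),
                 quadratic = if (is.null(quadratic)) NULL else unlist(quadratic)),
            class = "niche_truth")
}

#' Ground-truth suitability surface of a synthetic niche
#'
#' The logistic of the niche's linear (plus optional quadratic) predictor,
#' evaluated on every grid cell — the exact suitability the generator
#' samples from, available for parameter-recovery checks.
#'
#' @param stack A [climate_stack()].
#' @param truth A [niche_truth()].
#' @return Matrix of probabilities on the stack's grid.
#' @export
truth_probability <- function(stack, truth) {
  miss <- setdiff(c(names(truth$coefficients), names(truth$quadratic)),
                  names(stack$layers))
  if (length(miss)) stop("truth references unknown layer(s): ",
                         paste(miss, collapse = ", "))
  lp <- matrix(truth$intercept, stack$spec$n_rows, stack$spec$n_cols)
  for (v in names(truth$coefficients))
    lp <- lp + truth$coefficients[[v]] * stack$layers[[v]]
  for (v in names(truth$quadratic))
    lp <- lp + truth$quadratic[[v]] * stack$layers[[v]]^2
  stats::plogis(lp)
}

#' Sample presence records from a known logistic niche
#'
#' Cell centres are proposed uniformly and accepted with probability equal
#' to the niche's logistic suitability (rejection sampling) until
#' \code{n_target} presences are collected.
#'
#' @param stack A [climate_stack()].
#' @param truth A [niche_truth()].
#' @param n_target Number of presences (>= 1).
#' @param seed Integer seed.
#' @param max_proposals Proposal budget before giving up (guards against a
#'   niche with near-zero mean suitability).
#' @return An [occurrence_set()] with role \code{"presence"}.
#' @export
sample_occurrences <- function(stack, truth, n_target, seed = 1,
                               max_proposals = 2000 * n_target) {
  if (n_target < 1) stop("n_target must be >= 1")
  p <- truth_probability(stack, truth)
  cc <- cell_centers(stack$spec)
  pv <- p[cbind(cc$row, cc$col)]
  idx <- with_seed(seed, {
    acc <- integer(0)
    used <- 0L
    while (length(acc) < n_target && used < max_proposals) {
      batch <- min(max(4L * n_target, 100L), max_proposals - used)
      cand <- sample.int(nrow(cc), batch, replace = TRUE)
      keep <- stats::runif(batch) < pv[cand]
      acc <- c(acc, cand[keep])
      used <- used + batch
    }
    if (length(acc) < n_target)
      stop("proposal budget exhausted: mean suitability too low (",
           signif(mean(pv), 3), ")")
    acc[seq_len(n_target)]
  })
  occurrence_set(data.frame(species = "target", x = cc$x[idx], y = cc$y[idx],
                            role = "presence", source = "synthetic"))
}

#' Sample congener (parapatric relative) occurrences outside a region
#'
#' Congeners of the target species are parapatric, so their records fall
#' outside the target's range; they later serve as absence records.
#'
#' @param stack A [climate_stack()].
#' @param target_region Polygon strictly inside the grid bounds.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return An [occurrence_set()] with role \code{"congener_absence"}.
#' @export
gen_congener_occurrences <- function(stack, target_region, n, seed = 1) {
  stopifnot(n >= 1)
  cc <- cell_centers(stack$spec)
  admissible <- which(!points_in_polygon(cc$x, cc$y, target_region))
  if (length(admissible) == 0)
    stop("target_region covers the whole grid; no admissible cells")
  idx <- with_seed(seed,
    sample(admissible, n, replace = n > length(admissible)))
  occurrence_set(data.frame(species = "congener", x = cc$x[idx], y = cc$y[idx],
                            role = "congener_absence", source = "synthetic"))
}

#' Fragmentation schedule for the land-cover generator
#'
#' @param years Strictly increasing integer years.
#' @param woody_fraction Target woody cover per year, each in (0, 1].
#' @param patch_count Target number of 4-connected woody patches per year.
#' @return A \code{fragmentation_schedule}.
#' @export
fragmentation_schedule <- function(years, woody_fraction, patch_count) {
  stopifnot(length(years) == length(woody_fraction),
            length(years) == length(patch_count))
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  if (any(woody_fraction <= 0 | woody_fraction > 1))
    stop("woody_fraction must lie in (0, 1]")
  if (any(patch_count < 1)) stop("patch_count must be >= 1")
  structure(list(years = as.integer(years), woody_fraction = woody_fraction,
                 patch_count = as.integer(patch_count)),
            class = "fragmentation_schedule")
}

# Grow one woody raster with an exact cell budget and a fixed patch count.
# Different patches are kept out of rook adjacency while growing, so the
# 4-connected component count equals the number of seeds.
gen_landcover_year <- function(spec, fraction, patches, seed) {
  ncell <- n_cells(spec)
  n_woody <- max(1L, round(fraction * ncell))
  if (patches > n_woody) stop("infeasible: patch_count exceeds woody cells")
  nr <- spec$n_rows; nc <- spec$n_cols
  with_seed(seed, {
    lab <- matrix(0L, nr, nc)
    # seed cells, pairwise Chebyshev distance >= 2 so patches start disjoint
    order_cells <- sample.int(ncell)
    chosen <- integer(0)
    for (cell in order_cells) {
      r <- (cell - 1L) %/% nc + 1L; c <- (cell - 1L) %% nc + 1L
      nbr <- lab[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)]
      if (all(nbr == 0L)) {
        chosen <- c(chosen, cell)
        lab[r, c] <- length(chosen)
        if (length(chosen) == patches) break
      }
    }
    if (length(chosen) < patches)
      stop("infeasible: could not place ", patches, " separated patch seeds")
    neighbors4 <- function(r, c) {
      rr <- c(r - 1L, r + 1L, r, r); cc2 <- c(c, c, c - 1L, c + 1L)
      ok <- rr >= 1L & rr <= nr & cc2 >= 1L & cc2 <= nc
      cbind(rr[ok], cc2[ok])
    }
    frontier <- vector("list", patches)
    for (i in seq_len(patches)) {
      cell <- chosen[i]
      frontier[[i]] <- neighbors4((cell - 1L) %/% nc + 1L, (cell - 1L) %% nc + 1L)
    }
    placed <- patches
    active <- seq_len(patches)
    while (placed < n_woody && length(active)) {
      i <- if (length(active) == 1L) active else sample(active, 1L)
      grown <- FALSE
      while (nrow(frontier[[i]]) > 0L) {
        j <- sample.int(nrow(frontier[[i]]), 1L)
        rc <- frontier[[i]][j, ]
        frontier[[i]] <- frontier[[i]][-j, , drop = FALSE]
        if (lab[rc[1], rc[2]] != 0L) next
        nb <- neighbors4(rc[1], rc[2])
        labs <- lab[nb]
        if (any(labs != 0L & labs != i)) next  # would touch another patch
        lab[rc[1], rc[2]] <- i
        frontier[[i]] <- rbind(frontier[[i]], nb[labs == 0L, , drop = FALSE])
        placed <- placed + 1L
        grown <- TRUE
        break
      }
      if (!grown) active <- setdiff(active, i)
    }
    if (placed < n_woody && (n_woody - placed) / n_woody > 0.1)
      stop("infeasible: woody fraction unreachable with ", patches,
           " separated patches")
    binary_map((lab > 0L) * 1, spec)
  })
}

#' Generate a yearly woody/non-woody land-cover series
#'
#' Emulates a multi-decadal land-cover product on a fragmentation schedule:
#' per year the woody fraction is within 10\% (relative) of its target and
#' the 4-connected patch count within 20\% of its target (both are met
#' exactly in practice; patches are grown without touching).
#'
#' @param spec A [grid_spec()].
#' @param schedule A [fragmentation_schedule()].
#' @param seed Integer seed.
#' @return Named list (year -> [binary_map()]), 1 = woody.
#' @export
gen_landcover_series <- function(spec, schedule, seed = 1) {
  stopifnot(inherits(schedule, "fragmentation_schedule"))
  out <- lapply(seq_along(schedule$years), function(i) {
    gen_landcover_year(spec, schedule$woody_fraction[i], schedule$patch_count[i],
                       child_seed(seed, paste0("landcover", schedule$years[i])))
  })
  names(out) <- as.character(schedule$years)
  out
}

#' Generate disjoint rectangular protected-area polygons
#'
#' @param spec A [grid_spec()].
#' @param n_polygons Number of rectangles.
#' @param total_fraction Fraction of grid area to cover, in (0, 1).
#' @param seed Integer seed.
#' @return List of polygon matrices, pairwise disjoint, with union area
#'   within 10\% (relative) of \code{total_fraction} of the grid.
#' @export
gen_protected_areas <- function(spec, n_polygons, total_fraction, seed = 1) {
  if (total_fraction <= 0 || total_fraction >= 1)
    stop("total_fraction must lie in (0, 1)")
  stopifnot(n_polygons >= 1)
  w_grid <- spec$n_cols * spec$cell_size
  h_grid <- spec$n_rows * spec$cell_size
  area_tot <- total_fraction * w_grid * h_grid
  with_seed(seed, {
    shares <- rep(area_tot / n_polygons, n_polygons)
    polys <- list()
    overlaps <- function(a, b)
      a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4]
    for (i in seq_len(n_polygons)) {
      placed <- FALSE
      for (try in seq_len(500)) {
        aspect <- exp(stats::runif(1, -0.7, 0.7))
        w <- min(sqrt(shares[i] * aspect), w_grid)
        h <- shares[i] / w
        if (h > h_grid) { h <- h_grid; w <- shares[i] / h }
        x0 <- spec$origin_x + stats::runif(1, 0, w_grid - w)
        y0 <- spec$origin_y + stats::runif(1, 0, h_grid - h)
        box <- c(x0, x0 + w, y0, y0 + h)
        if (!any(vapply(polys, function(p)
          overlaps(c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2])), box),
          logical(1)))) {
          polys[[i]] <- rect_polygon(box[1], box[2], box[3], box[4])
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible packing: could not place polygon ", i)
    }
    polys
  })
}
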