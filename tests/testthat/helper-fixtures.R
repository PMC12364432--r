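# Shared fixture builders and independent oracles used across the suite.
# Oracles here are deliberately naive (enumeration, brute force) so they
# stay independent of the implementation paths they check.

tiny_spec <- function(nr = 10, nc = 10, cell = 1) {
  grid_spec(nr, nc, cell_size = cell)
}

# Build a climate stack directly from matrices (bypasses the generator).
stack_from <- function(..., cell = 1) {
  layers <- list(...)
  spec <- grid_spec(nrow(layers[[1]]), ncol(layers[[1]]), cell_size = cell)
  climate_stack(layers, spec)
}

# Parse a compact raster sketch: rows of characters, "1" woody/suitable,
# "0" empty, "." nodata.
map_sketch <- function(rows, cell = 1) {
  m <- do.call(rbind, lapply(strsplit(rows, ""), function(ch)
    ifelse(ch == ".", NA_real_, as.numeric(ch))))
  binary_map(m, grid_spec(nrow(m), ncol(m), cell_size = cell))
}

occ_from_xy <- function(x, y, role = "presence") {
  occurrence_set(data.frame(species = "sp", x = x, y = y, role = role,
                            source = "test"))
}

# Ray-casting point-in-polygon oracle, independent of mgcv.
pip_oracle <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py) &&
        px < (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
             (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

# Gift-wrapping convex hull oracle (returns vertex indices, any order).
jarvis_hull <- function(x, y) {
  n <- length(x)
  start <- which.min(x)
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p) next
      cross <- (x[q] - x[p]) * (y[r] - y[p]) - (y[q] - y[p]) * (x[r] - x[p])
      d_q <- (x[q] - x[p])^2 + (y[q] - y[p])^2
      d_r <- (x[r] - x[p])^2 + (y[r] - y[p])^2
      if (cross < 0 || (cross == 0 && d_r > d_q)) q <- r
    }
    p <- q
    if (p == start) break
  }
  hull
}

# Brute-force AUC by enumerating all (pos, neg) pairs.
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Brute-force nearest-occupied distance per cell.
edt_oracle <- function(binmap) {
  cc <- cell_centers(binmap$spec)
  occ <- which(t(binmap$values) == 1)  # cell order is row-major
  d <- matrix(Inf, binmap$spec$n_rows, binmap$spec$n_cols)
  for (k in seq_len(nrow(cc))) {
    if (length(occ))
      d[cc$row[k], cc$col[k]] <-
        min(sqrt((cc$x[k] - cc$x[occ])^2 + (cc$y[k] - cc$y[occ])^2))
  }
  d
}

random_binary_map <- function(spec, p = 0.5) {
  binary_map(matrix(rbinom(spec$n_rows * spec$n_cols, 1, p),
                    spec$n_rows, spec$n_cols), spec)
}

# Moran-style lag-1 neighbour correlation of a matrix (right neighbours).
neighbor_cor <- function(m) {
  stats::cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
}
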