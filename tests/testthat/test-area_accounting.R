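test_that("cell areas are uniform on planar grids and cosine-scaled on geographic", {
  planar <- cell_area_grid(grid_spec(5, 5, cell_size = 1))
  expect_true(all(planar == 1))
  # 0.5-degree cells from the equator up
  geo <- grid_spec(120, 10, origin_y = 0, cell_size = 0.5,
                   crs_tag = "longlat (synthetic)")
  a <- cell_area_grid(geo)
  expect_equal(a[120, 1], (111.32 * 0.5)^2 * cos(0.25 * pi / 180))
  # near-equator cells are about twice the area of near-60-degree cells
  expect_equal(a[120, 1] / a[1, 1],
               cos(0.25 * pi / 180) / cos(59.75 * pi / 180))
  expect_equal(a[120, 1] / a[1, 1], 2, tolerance = 0.02)
})

test_that("change areas satisfy the conservation identities", {
  spec <- grid_spec(20, 20, cell_size = 2)
  set.seed(1)
  p1 <- random_binary_map(spec, 0.4)
  p2 <- random_binary_map(spec, 0.5)
  r <- change_areas(p1, p2)
  expect_equal(r$maintained + r$lost, r$area_p1)
  expect_equal(r$maintained + r$gained, r$area_p2)
  same <- change_areas(p1, p1)
  expect_equal(same$lost, 0); expect_equal(same$gained, 0)
  expect_equal(same$maintained, same$area_p1)
  none <- binary_map(1 - p1$values, spec)
  disj <- change_areas(p1, none)
  expect_equal(disj$maintained, 0)
  expect_equal(disj$lost, disj$area_p1)
  expect_equal(disj$gained, disj$area_p2)
  expect_error(change_areas(p1, random_binary_map(grid_spec(5, 5), 0.5)),
               "co-registered")
})

test_that("change areas match an exhaustive cell audit on a random 50x50 pair", {
  spec <- grid_spec(50, 50, cell_size = 1.5)
  set.seed(2)
  p1 <- random_binary_map(spec, 0.35)
  p2 <- random_binary_map(spec, 0.55)
  r <- change_areas(p1, p2)
  cell <- 1.5^2
  m <- l <- g <- 0
  for (i in 1:50) for (j in 1:50) {
    a <- p1$values[i, j] == 1; b <- p2$values[i, j] == 1
    if (a && b) m <- m + cell
    if (a && !b) l <- l + cell
    if (!a && b) g <- g + cell
  }
  expect_equal(r$maintained, m)
  expect_equal(r$lost, l)
  expect_equal(r$gained, g)
})

test_that("percentage conventions divide by the declared denominators", {
  r <- change_report(area_p1 = 1000, area_p2 = 800, maintained = 700,
                     lost = 300, gained = 100)
  top <- change_percentages(r, "P1_ALL")
  expect_equal(top$maintained_pct, 70)
  expect_equal(top$lost_pct, 30)
  expect_equal(top$gained_pct, 10)      # against the period-1 area
  mid <- change_percentages(r, "P1_MAINT_LOST_P2_GAIN")
  expect_equal(mid$maintained_pct, 70)
  expect_equal(mid$gained_pct, 12.5)    # against the period-2 area
  ident <- change_percentages(
    change_report(500, 500, 500, 0, 0), "P1_ALL")
  expect_equal(c(ident$maintained_pct, ident$lost_pct, ident$gained_pct),
               c(100, 0, 0))
  expect_error(change_percentages(change_report(0, 10, 0, 0, 10), "P1_ALL"),
               "zero")
})

test_that("stable refuges are the shrinking intersection of period maps", {
  spec <- grid_spec(15, 15)
  set.seed(3)
  maps <- lapply(1:4, function(i) random_binary_map(spec, 0.6))
  ref <- stable_refuge(maps)
  for (m in maps) expect_true(all(ref$values <= m$values))
  expect_equal(stable_refuge(list(maps[[1]], maps[[1]]))$values,
               maps[[1]]$values)
  zero <- binary_map(matrix(0, 15, 15), spec)
  expect_equal(sum(stable_refuge(c(maps, list(zero)))$values), 0)
  shrinking <- stable_refuge(maps)
  expect_true(all(shrinking$values <= stable_refuge(maps[1:3])$values))
  expect_lte(area_of(ref), min(vapply(maps, area_of, numeric(1))))
  expect_error(stable_refuge(maps[1]), "at least 2")
})

test_that("protected-area overlap reports exact percentages", {
  spec <- grid_spec(10, 10, cell_size = 1)
  suit <- binary_map(matrix(1, 10, 10), spec)
  left_half <- rect_polygon(0, 5, 0, 10)
  r <- protection_overlap(suit, left_half)
  expect_equal(r$percent_protected, 50)
  expect_equal(r$protected_km2, 50)
  nowhere <- rect_polygon(20, 30, 20, 30)
  expect_equal(protection_overlap(suit, nowhere)$percent_protected, 0)
})

test_that("protection overlap matches a point-in-polygon audit and survives subdivision", {
  spec <- grid_spec(50, 50, cell_size = 1)
  set.seed(4)
  suit <- random_binary_map(spec, 0.5)
  pa <- cbind(x = c(5.3, 44.7, 40.2, 19.9, 8.1),
              y = c(5.1, 9.8, 44.6, 40.3, 29.7))
  r <- protection_overlap(suit, pa)
  cc <- cell_centers(spec)
  inpa <- vapply(seq_len(nrow(cc)), function(k)
    pip_oracle(cc$x[k], cc$y[k], pa), logical(1))
  s <- suit$values[cbind(cc$row, cc$col)] == 1
  expect_equal(r$protected_km2, sum(inpa & s))
  expect_equal(r$percent_protected, 100 * sum(inpa & s) / sum(s))
  # subdividing a PA polygon along a line changes nothing
  whole <- list(rect_polygon(5, 45, 5, 45))
  split <- list(rect_polygon(5, 25, 5, 45), rect_polygon(25, 45, 5, 45))
  expect_equal(protection_overlap(suit, split)$percent_protected,
               protection_overlap(suit, whole)$percent_protected)
  expect_warning(
    protection_overlap(suit, list(pa, cbind(c(0, 0, 0), c(1, 1, 1)))),
    "invalid")
})

test_that("per-region reporting restricts both numerator and denominator", {
  spec <- grid_spec(10, 10)
  suit <- binary_map(matrix(1, 10, 10), spec)
  pa <- rect_polygon(0, 5, 0, 5)
  regions <- list(south = rect_polygon(0, 10, 0, 5),
                  north = rect_polygon(0, 10, 5, 10))
  r <- protection_overlap(suit, pa, regions)
  expect_equal(r$percent_protected[r$region == "south"], 50)
  expect_equal(r$percent_protected[r$region == "north"], 0)
})
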