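test_that("climate generator is deterministic, standardised and autocorrelated", {
  spec <- grid_spec(60, 60, cell_size = 1)
  a <- gen_climate_stack(spec, c("bio1", "bio2"), spatial_scale = 5, seed = 7)
  b <- gen_climate_stack(spec, c("bio1", "bio2"), spatial_scale = 5, seed = 7)
  expect_identical(a, b)
  c <- gen_climate_stack(spec, c("bio1", "bio2"), spatial_scale = 5, seed = 8)
  expect_false(identical(a$layers$bio1, c$layers$bio1))
  for (l in a$layers) {
    expect_lt(abs(mean(l)), 0.05)
    expect_equal(sd(l), 1, tolerance = 1e-10)
  }
  rough <- gen_climate_stack(spec, "v", spatial_scale = 1, seed = 3)
  smooth <- gen_climate_stack(spec, "v", spatial_scale = 10, seed = 3)
  expect_lt(neighbor_cor(rough$layers$v), neighbor_cor(smooth$layers$v))
  expect_error(gen_climate_stack(spec, c("x", "x")), "duplicate")
  expect_error(gen_climate_stack(spec, character(0)), "nonempty")
})

test_that("future shifts are additive, exact and name-checked", {
  st <- stack_from(a = matrix(rnorm(100), 10), b = matrix(rnorm(100), 10))
  expect_identical(gen_future_stack(st, c(a = 0, b = 0))$layers, st$layers)
  shifted <- gen_future_stack(st, c(a = 2))
  expect_equal(mean(shifted$layers$a) - mean(st$layers$a), 2)
  expect_identical(shifted$layers$b, st$layers$b)
  twice <- gen_future_stack(gen_future_stack(st, c(a = 1)), c(a = 1))
  expect_equal(twice$layers$a, gen_future_stack(st, c(a = 2))$layers$a)
  expect_error(gen_future_stack(st, c(zz = 1)), "unknown variable")
})

test_that("a flat niche yields near-uniform presences; a strong coefficient enriches", {
  spec <- grid_spec(40, 40, cell_size = 1)
  st <- gen_climate_stack(spec, "v", spatial_scale = 4, seed = 1)
  flat <- sample_occurrences(st, niche_truth(10, c(v = 0)), 400, seed = 2)
  expect_equal(nrow(flat), 400)
  qx <- flat$x > 20; qy <- flat$y > 20
  counts <- table(factor(qx, c(FALSE, TRUE)), factor(qy, c(FALSE, TRUE)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
  enriched <- vapply(1:10, function(s) {
    occ <- sample_occurrences(st, niche_truth(-1, c(v = 3)), 100, seed = s)
    vals <- extract_predictors(st, occ)$v
    mean(vals) - mean(st$layers$v)
  }, numeric(1))
  expect_true(all(enriched > 0))
  expect_error(sample_occurrences(st, niche_truth(0, c(v = 0)), 0), "n_target")
  expect_error(
    sample_occurrences(st, niche_truth(-40, c(v = 0)), 50, max_proposals = 5000),
    "budget")
})

test_that("presence selectivity weakens as the niche intercept rises", {
  spec <- grid_spec(30, 30, cell_size = 1)
  st <- gen_climate_stack(spec, "v", spatial_scale = 3, seed = 5)
  # grid-level prevalence is monotone in the intercept...
  prev <- vapply(c(-2, 0, 2), function(b0)
    mean(truth_probability(st, niche_truth(b0, c(v = 2)))), numeric(1))
  expect_true(all(diff(prev) > 0))
  # ...and sampled presences become less environmentally selective
  enrich <- sapply(c(-2, 0, 2), function(b0) {
    vapply(1:5, function(s) {
      occ <- sample_occurrences(st, niche_truth(b0, c(v = 2)), 80, seed = s)
      mean(extract_predictors(st, occ)$v)
    }, numeric(1))
  })
  expect_true(all(diff(colMeans(enrich)) < 0))
})

test_that("congener points fall outside the target region, exactly n of them", {
  spec <- grid_spec(20, 20, cell_size = 1)
  st <- gen_climate_stack(spec, "v", seed = 1)
  region <- rect_polygon(4, 16, 4, 16)
  occ <- gen_congener_occurrences(st, region, 50, seed = 9)
  expect_equal(nrow(occ), 50)
  expect_false(any(points_in_polygon(occ$x, occ$y, region)))
  expect_true(all(occ$role == "congener_absence"))
  cc <- cell_centers(spec)
  admissible <- function(r) sum(!points_in_polygon(cc$x, cc$y, r))
  sizes <- vapply(list(rect_polygon(2, 18, 2, 18), rect_polygon(5, 15, 5, 15),
                       rect_polygon(8, 12, 8, 12)), admissible, numeric(1))
  expect_true(all(diff(sizes) > 0))
  expect_error(
    gen_congener_occurrences(st, rect_polygon(-5, 25, -5, 25), 10),
    "whole grid")
})

test_that("land-cover generator honours fraction and patch-count targets", {
  spec <- grid_spec(50, 50, cell_size = 1)
  sched <- fragmentation_schedule(c(2000, 2007), c(0.35, 0.25), c(8, 14))
  s1 <- gen_landcover_series(spec, sched, seed = 3)
  s2 <- gen_landcover_series(spec, sched, seed = 3)
  expect_identical(s1, s2)
  for (i in 1:2) {
    woody <- sum(s1[[i]]$values)
    expect_lt(abs(woody / 2500 - sched$woody_fraction[i]) /
                sched$woody_fraction[i], 0.1)
    frags <- extract_fragments(s1[[i]], min_area_ha = 0)
    expect_lt(abs(nrow(frags) - sched$patch_count[i]) / sched$patch_count[i],
              0.2 + 1e-9)
  }
  full <- gen_landcover_series(
    spec, fragmentation_schedule(1999, 1, 1), seed = 1)[[1]]
  expect_true(all(full$values == 1))
  expect_error(
    gen_landcover_series(grid_spec(5, 5),
                         fragmentation_schedule(2000, 0.1, 20), seed = 1),
    "infeasible")
})

test_that("land-cover rasters survive an ASCII round-trip into fragment extraction", {
  spec <- grid_spec(30, 30, cell_size = 1)
  lc <- gen_landcover_series(spec, fragmentation_schedule(2020, 0.3, 6),
                             seed = 11)[[1]]
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(lc, path)
  back <- read_asc(path)
  frags_direct <- extract_fragments(lc, min_area_ha = 0)
  frags_rt <- extract_fragments(binary_map(back$values, back$spec),
                                min_area_ha = 0)
  expect_equal(frags_rt$area_km2, frags_direct$area_km2)
  expect_equal(frags_rt$perimeter_km, frags_direct$perimeter_km)
})

test_that("protected-area rectangles are disjoint and cover the target fraction", {
  spec <- grid_spec(40, 40, cell_size = 1)
  pas <- gen_protected_areas(spec, 6, 0.2, seed = 4)
  expect_length(pas, 6)
  total <- sum(vapply(pas, polygon_area, numeric(1)))
  expect_lt(abs(total / 1600 - 0.2) / 0.2, 0.1)
  for (i in 1:5) for (j in (i + 1):6) {
    a <- pas[[i]]; b <- pas[[j]]
    expect_false(max(a[, 1]) > min(b[, 1]) && max(b[, 1]) > min(a[, 1]) &&
                   max(a[, 2]) > min(b[, 2]) && max(b[, 2]) > min(a[, 2]))
  }
  one <- gen_protected_areas(spec, 1, 0.5, seed = 2)
  expect_equal(polygon_area(one[[1]]), 800, tolerance = 1e-6)
  expect_error(gen_protected_areas(spec, 1, 1.2, seed = 1), "total_fraction")
})
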