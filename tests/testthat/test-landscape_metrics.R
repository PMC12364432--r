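test_that("fragment extraction counts areas and staircase perimeters exactly", {
  # 100-m cells: a 2x2 woody block is 4 ha with a 0.8-km perimeter and falls
  # below the 11.875-ha home-range cutoff; a 4x4 block (16 ha) survives
  small <- map_sketch(c("0000", "0110", "0110", "0000"), cell = 0.1)
  all_frags <- extract_fragments(small, min_area_ha = 0)
  expect_equal(all_frags$area_km2, 0.04)        # 4 ha
  expect_equal(all_frags$perimeter_km, 0.8)
  expect_equal(nrow(extract_fragments(small)), 0)  # dropped at 11.875 ha
  big <- map_sketch(c("000000", "011110", "011110", "011110", "011110",
                      "000000"), cell = 0.1)
  frags <- extract_fragments(big)
  expect_equal(frags$area_km2, 0.16)            # 16 ha retained
  expect_equal(frags$perimeter_km, 1.6)         # 16 exposed edges x 0.1 km
  expect_equal(frags$centroid_x, 0.3)  # cols 2-5 of 100-m cells
})

test_that("diagonal contact separates fragments under 4-connectivity", {
  diag2 <- map_sketch(c("1100", "1100", "0011", "0011"))
  frags <- extract_fragments(diag2, min_area_ha = 0)
  expect_equal(nrow(frags), 2)
  expect_equal(sort(frags$n_cells), c(4, 4))
})

test_that("pre-filter totals conserve the woody cell count", {
  set.seed(1)
  spec <- grid_spec(30, 30, cell_size = 0.5)
  woody <- random_binary_map(spec, 0.3)
  frags <- extract_fragments(woody, min_area_ha = 0)
  expect_equal(attr(frags, "total_area_km2"),
               sum(woody$values) * 0.25)
  expect_equal(sum(frags$area_km2), attr(frags, "total_area_km2"))
  expect_error(extract_fragments(
    binary_map(matrix(NA_real_, 3, 3), grid_spec(3, 3))), "nodata")
})

test_that("fragmentation index is area over perimeter, with closed forms", {
  sq <- map_sketch(c("00000", "01110", "01110", "01110", "00000"), cell = 1)
  frags <- extract_fragments(sq, min_area_ha = 0)
  expect_equal(fragmentation_index(frags), 3 / 4)  # square of side 3
  expect_equal(fragmentation_index(total_area = 100, total_perimeter = 40),
               2.5)
  expect_error(fragmentation_index(total_area = 1, total_perimeter = 0),
               "perimeter")
})

test_that("splitting a fragment with conserved area strictly lowers FI", {
  joined <- map_sketch("11111111")
  split <- map_sketch(c("111101111"))
  fi_joined <- fragmentation_index(extract_fragments(joined, 0))
  frags_split <- extract_fragments(split, 0)
  expect_equal(sum(frags_split$area_km2),
               sum(extract_fragments(joined, 0)$area_km2))
  expect_lt(fragmentation_index(frags_split), fi_joined)
})

test_that("connectivity index equals the all-pairs mean and its symmetries", {
  two <- data.frame(centroid_x = c(0, 10), centroid_y = c(0, 0))
  expect_equal(connectivity_index(two), 10)
  d <- 7
  tri <- data.frame(centroid_x = d * cos(2 * pi * (0:2) / 3),
                    centroid_y = d * sin(2 * pi * (0:2) / 3))
  side <- sqrt(sum((tri[1, ] - tri[2, ])^2))
  expect_equal(connectivity_index(tri), side)
  set.seed(2)
  cloud <- data.frame(centroid_x = runif(20, 0, 100),
                      centroid_y = runif(20, 0, 100))
  brute <- mean(vapply(1:20, function(i)
    mean(sqrt((cloud$centroid_x[i] - cloud$centroid_x[-i])^2 +
                (cloud$centroid_y[i] - cloud$centroid_y[-i])^2)),
    numeric(1)))
  expect_equal(connectivity_index(cloud), brute)
  theta <- 0.7
  rotated <- data.frame(
    centroid_x = cos(theta) * cloud$centroid_x - sin(theta) * cloud$centroid_y + 55,
    centroid_y = sin(theta) * cloud$centroid_x + cos(theta) * cloud$centroid_y - 12)
  expect_equal(connectivity_index(rotated), connectivity_index(cloud))
  expect_error(connectivity_index(two[1, , drop = FALSE]), "fewer than 2")
})

test_that("landscape series reports constant input as constant output", {
  spec <- grid_spec(25, 25, cell_size = 1)
  lc <- gen_landcover_series(spec, fragmentation_schedule(2000, 0.35, 6),
                             seed = 4)[[1]]
  series <- list("2000" = lc, "2007" = lc, "2014" = lc)
  rep <- landscape_series(series, min_area_ha = 0)
  expect_equal(nrow(rep), 3)
  expect_equal(length(unique(rep$fi)), 1)
  expect_equal(length(unique(rep$mean_connectivity_km)), 1)
})

test_that("clipping a series to an empty mask yields flagged empty rows", {
  spec <- grid_spec(10, 10)
  lc <- gen_landcover_series(spec, fragmentation_schedule(2000, 0.4, 3),
                             seed = 5)
  empty <- binary_map(matrix(0, 10, 10), spec)
  rep <- landscape_series(lc, clip = empty, min_area_ha = 0)
  expect_true(all(rep$empty))
  expect_true(all(is.na(rep$fi)))
  expect_equal(rep$area_km2, 0)
})

test_that("a scheduled fragmentation increase drives FI down over years", {
  spec <- grid_spec(45, 45, cell_size = 1)
  sched <- fragmentation_schedule(
    years = seq(1985, 2020, by = 7),
    woody_fraction = seq(0.45, 0.28, length.out = 6),
    patch_count = round(seq(6, 22, length.out = 6)))
  ok <- vapply(1:10, function(s) {
    rep <- landscape_series(gen_landcover_series(spec, sched, seed = s),
                            min_area_ha = 0)
    all(diff(rep$fi) <= 1e-12)
  }, logical(1))
  expect_gte(sum(ok), 8)
})
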