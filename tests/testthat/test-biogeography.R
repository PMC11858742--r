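test_that("occupancy counts cells, unique contributions, and dataset algebra", {
  occ <- validate_occurrences(dplyr::bind_rows(
    make_occ(2, plon = c(10.2, 10.9), plat = c(45.7, 45.1)), # same 1-degree cell
    make_occ(1, plon = 30, plat = -5, occurrence_id = "a2"),
    make_occ(2, in_dark = FALSE, in_published = TRUE,
             occurrence_id = c("b1", "b2"), plon = c(10.5, 60), plat = c(45.5, 0))
  ))
  out <- occupancy(partition_datasets(occ))
  g <- dplyr::filter(out, bin == "(global)")
  expect_equal(g$cells_dark, 2)
  expect_equal(g$cells_published, 2)
  expect_equal(g$cells_total, 3)
  expect_equal(g$unique_dark, 1)
  expect_equal(g$unique_published, 1)
  expect_equal(g$shared, 1)
  # unique(A) + unique(B) + shared covers occupied(D)
  expect_equal(g$unique_dark + g$unique_published + g$shared, g$cells_total)
})

test_that("occupancy is order invariant and monotone under grid refinement", {
  set.seed(7)
  n <- 120
  occ <- validate_occurrences(make_occ(n, plon = runif(n, -30, 30),
                                       plat = runif(n, -20, 40)))
  part1 <- partition_datasets(occ)
  part2 <- partition_datasets(occ[sample(n), ])
  o1 <- occupancy(part1, resolution = 2)
  o2 <- occupancy(part2, resolution = 2)
  expect_equal(o1$cells_total, o2$cells_total)
  fine <- occupancy(part1, resolution = 1)
  expect_gte(fine$cells_total, o1$cells_total)
})

test_that("hull areas match an independent geodesic oracle and degrade gracefully", {
  skip_if_not_installed("geosphere")
  # 1x1 degree square at the equator, within 0.5% of the spherical oracle
  sq <- cbind(lon = c(0, 1, 1, 0), lat = c(0, 0, 1, 1))
  h <- hull_range(sq[, "lon"], sq[, "lat"])
  oracle <- geosphere::areaPolygon(sq, a = 6371008.8, f = 0) / 1e6
  expect_equal(h$area_km2, oracle, tolerance = 0.005)

  # a larger irregular hull agrees too
  set.seed(3)
  p <- cbind(runif(60, -40, 10), runif(60, -35, 25))
  h2 <- hull_range(p[, 1], p[, 2])
  v <- as.matrix(h2$vertices)
  oracle2 <- geosphere::areaPolygon(v, a = 6371008.8, f = 0) / 1e6
  expect_equal(h2$area_km2, oracle2, tolerance = 0.005)

  expect_equal(hull_range(c(0, 10), c(0, 5))$area_km2, 0) # two points
  expect_equal(hull_range(c(0, 5, 10), c(0, 0, 0))$area_km2, 0) # collinear
  expect_error(hull_range(numeric(0), numeric(0)), class = "pd_input_error")
})

test_that("hulls handle the antimeridian by longitude recentring", {
  h <- hull_range(c(179, -179, 179.5, -179.5), c(0, 0, 1, 1))
  expect_lt(h$area_km2, 50000) # a ~2x1 degree patch, not a wrap-around band
  expect_equal(h$frame, "spherical")

  expect_warning(
    wide <- hull_range(c(-170, -90, 0, 90, 170), c(0, 10, -10, 5, 0)),
    "hemisphere"
  )
  expect_equal(wide$frame, "planar")
})

test_that("subset hulls never exceed the full hull (randomized property)", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(5:40, 1)
    lon <- runif(n, -60, 60)
    lat <- runif(n, -50, 50)
    full <- hull_range(lon, lat)$area_km2
    keep <- sample(n, sample(3:n, 1))
    sub <- hull_range(lon[keep], lat[keep])$area_km2
    expect_lte(sub, full + 1e-6)
  }
})

test_that("dense cap sampling recovers the true cap area", {
  set.seed(5)
  R <- 6371.0088
  r_km <- 900
  pts <- palaeodark:::sample_cap(600, 15, -10, r_km / R)
  est <- hull_range(pts[, 1], pts[, 2])$area_km2
  truth <- 2 * pi * R^2 * (1 - cos(r_km / R))
  expect_equal(est, truth, tolerance = 0.08)
  expect_lte(est, truth) # the hull of interior points cannot exceed the cap
})

test_that("range overlap and added percentages satisfy their identities", {
  sim <- simulate_scenario(small_scenario(), seed = 13)
  occ <- assign_bins(deduplicate_occurrences(sim$occurrences),
                     palaeozoic_bins("sub_period"))
  part <- partition_datasets(occ)
  geo <- range_overlap_added(part, "genus")
  expect_gt(nrow(geo), 0)
  wide <- tidyr::pivot_wider(
    dplyr::select(geo, taxon, bin, subset, overlap_pct, added_pct),
    names_from = subset, values_from = c(overlap_pct, added_pct)
  )
  # overlap%(B) + added%(A) = 100 exactly, and symmetrically
  expect_equal(wide$overlap_pct_published + wide$added_pct_dark,
               rep(100, nrow(wide)), tolerance = 1e-9)
  expect_equal(wide$overlap_pct_dark + wide$added_pct_published,
               rep(100, nrow(wide)), tolerance = 1e-9)
  expect_true(all(geo$overlap_pct >= 0 & geo$overlap_pct <= 100 + 1e-9))
  expect_true(all(geo$area_km2 <= geo$area_total_km2 + 1e-6))
})

test_that("latitudinal metrics match hand-computed intervals", {
  # dark occupies [-10, 20], published [0, 10]: total [-10, 20]
  occ <- validate_occurrences(dplyr::bind_rows(
    make_occ(2, plat = c(-10, 20), genus = "Ga", max_ma = 330, min_ma = 320),
    make_occ(2, in_dark = FALSE, in_published = TRUE, genus = "Ga",
             occurrence_id = c("b1", "b2"), plat = c(0, 10),
             max_ma = 330, min_ma = 320)
  ))
  occ <- assign_bins(occ, carboniferous_bins())
  lat <- lat_range_metrics(partition_datasets(occ), "genus")
  dark <- dplyr::filter(lat, subset == "dark")
  expect_equal(dark$width, 30)
  expect_equal(dark$midpoint, 5)
  pub <- dplyr::filter(lat, subset == "published")
  expect_equal(pub$width, 10)
  expect_equal(pub$overlap_pct, 100 * 10 / 30)
  expect_equal(pub$midpoint_shift, 0) # published midpoint 5 = total midpoint 5
  # removing dark leaves [0, 10]: dark adds 20 of 30 degrees
  expect_equal(dark$added_pct_of_total, 100 * 20 / 30)
  expect_equal(dark$added_pct_of_subset, 100 * 20 / 10)
})
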