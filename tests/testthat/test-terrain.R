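test_that("grid construction counts cells and rejects non-divisible plots", {
  expect_equal(nrow(build_quadrat_grid(200, 110, 10)$cells), 220L)
  expect_equal(nrow(build_quadrat_grid(10, 10, 10)$cells), 1L)
  expect_equal(nrow(build_quadrat_grid(30, 20, 10)$cells), 6L)
  expect_error(build_quadrat_grid(205, 110, 10), "remainder")
  expect_error(build_quadrat_grid(0, 110, 10), "positive")
})

test_that("half-open cell membership matches an exhaustive lattice oracle", {
  g <- build_quadrat_grid(30, 20, 10)
  pts <- expand.grid(x = seq(0, 30, by = 0.5), y = seq(0, 20, by = 0.5))
  got <- assign_quadrat(g, pts$x, pts$y)
  # oracle: brute-force membership against each cell's half-open box,
  # folding the top/right plot boundary into the last cells
  oracle <- vapply(seq_len(nrow(pts)), function(i) {
    x <- min(pts$x[i], 30 - 1e-9); y <- min(pts$y[i], 20 - 1e-9)
    hit <- which(g$cells$x0 <= x & x < g$cells$x1 &
                 g$cells$y0 <= y & y < g$cells$y1)
    stopifnot(length(hit) == 1L)
    g$cells$cell[hit]
  }, 0L)
  expect_identical(got, oracle)
  expect_error(assign_quadrat(g, -1, 5), "outside")
})

test_that("elevation and convexity follow their defining arithmetic", {
  expect_equal(quadrat_elevation(c(0, 0, 0, 0)), 0)
  expect_equal(quadrat_elevation(c(10, 20, 30, 40)), 25)
  expect_error(quadrat_elevation(c(1, 2, NA, 4)), "finite")

  expect_equal(quadrat_convexity(5, c(0, 0, 0, 0)), 5)
  expect_error(quadrat_convexity(NA_real_, c(1, 1, 1, 1)), "missing")

  # planar surface: center equals the vertex mean, convexity 0
  z <- plane_z(c(0, 10, 10, 0), c(0, 0, 10, 10), 1293, 25, 200, 5, 5)
  zc <- plane_z(5, 5, 1293, 25, 200, 5, 5)
  expect_equal(quadrat_convexity(zc, z), 0, tolerance = 1e-9)
  # raised mound: center 2 m above the plane
  expect_equal(quadrat_convexity(zc + 2, z), 2, tolerance = 1e-9)
})

test_that("slope of the four vertex triples matches the plane-normal oracle", {
  flat <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), c(0, 0, 0, 0))
  expect_equal(quadrat_slope(flat), 0)

  # z = y: a 45-degree plane, all four triples coplanar
  tilt <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(quadrat_slope(tilt), 45)

  # one raised corner: per-triple dips 0, 45, 54.7356, 45 degrees
  v <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), c(0, 0, 0, 10))
  dips <- c(0, 45, acos(1 / sqrt(3)) * 180 / pi, 45)
  expect_equal(quadrat_slope(v), mean(dips), tolerance = 1e-10)

  degen <- cbind(c(0, 5, 10, 0), c(0, 0, 0, 10), c(0, 1, 2, 3))
  expect_error(quadrat_slope(degen), "collinear")
})

test_that("aspect is the circular mean of downslope bearings", {
  # plane dipping due south: every triple aspect 180
  south <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10),
                 plane_z(c(0, 10, 10, 0), c(0, 0, 10, 10), 100, 30, 180, 5, 5))
  expect_equal(quadrat_aspect(south), 180, tolerance = 1e-9)

  # circular mean straddling north: 350 and 10 average to 0
  expect_equal(circular_mean_deg(c(350, 10)), 0, tolerance = 1e-9)
  expect_equal(circular_mean_deg(c(NA, 90, NA)), 90)

  # all-flat quadrat: undefined sentinel, not an error
  flat <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), c(5, 5, 5, 5))
  expect_true(is.na(quadrat_aspect(flat)))
})

test_that("planar-field identities hold for every quadrat of a generated grid", {
  grid <- build_quadrat_grid(100, 60, 10)
  cfg <- stand_config(plot_width = 100, plot_height = 60, n_stems = 10,
                      seed = 6, elevation_noise_sd = 0,
                      elevation_trend = c(base = 1293, slope_deg = 25,
                                          dip_azimuth_deg = 200))
  ef <- generate_elevation_field(cfg, grid)
  tt <- terrain_table(grid, ef, substrate = NULL)
  expect_equal(tt$convexity, rep(0, nrow(tt)), tolerance = 1e-9)
  expect_equal(tt$slope, rep(25, nrow(tt)), tolerance = 1e-6)
  expect_equal(tt$aspect, rep(200, nrow(tt)), tolerance = 1e-6)
  expect_true(all(tt$site_type == "soil"))
})

test_that("rock fractions and the >= 50% rule behave at the boundary", {
  sm <- substrate_map(list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))),
                      20, 10)
  g <- build_quadrat_grid(20, 10, 10)
  expect_equal(rock_fraction(g$cells[1, ], sm), 1.0)
  expect_equal(rock_fraction(g$cells[2, ], sm), 0.0)

  # half-cell rectangle: fraction 0.5, classified rock under the >= rule
  half <- substrate_map(list(rbind(c(0, 0), c(5, 0), c(5, 10), c(0, 10))),
                        10, 10)
  g1 <- build_quadrat_grid(10, 10, 10)
  expect_equal(rock_fraction(g1$cells[1, ], half), 0.5)

  tt <- data.frame(cell = 1:3, rock_fraction = c(0.49, 0.50, 0.51))
  cls <- classify_site_type(tt, g)
  expect_equal(as.character(cls$site_type), c("soil", "rock", "rock"))
  tot <- site_type_totals(cls)
  expect_equal(tot$n_rock_quadrats + tot$n_soil_quadrats, 3L)
})

test_that("clipping conserves rock area across cells and matches the raster oracle", {
  sc <- demo_scenario()
  tt <- sc$terrain
  cell_area <- sc$grid$cell_size^2
  # sum over cells of clipped rock area equals the substrate's rock area
  expect_equal(sum(tt$rock_fraction) * cell_area, sc$substrate$rock_area,
               tolerance = 1e-6)
  # every quadrat is exactly one of rock/soil and counts match areas
  tot <- site_type_totals(tt)
  expect_equal(tot$n_rock_quadrats + tot$n_soil_quadrats, nrow(tt))
  expect_equal(tot$rock_quadrat_area, tot$n_rock_quadrats * cell_area)

  # per-cell raster cross-check on a sample of quadrats
  set.seed(1)
  for (k in sample(nrow(tt), 12)) {
    cell <- sc$grid$cells[k, ]
    rast <- raster_cover_fraction(sc$substrate$polygons,
                                  c(cell$x0, cell$x1), c(cell$y0, cell$y1),
                                  step = 0.1)
    expect_lt(abs(rast - tt$rock_fraction[k]), 0.01)
  }
})
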