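test_that("point pattern preconditions and determinism hold", {
  expect_error(stand_config(n_stems = 1), "n_stems")
  expect_error(stand_config(plot_width = -5), "positive")
  # infeasible hard-core packing is rejected up front, naming the geometry
  expect_error(stand_config(n_stems = 5000, pattern = "hardcore",
                            pattern_params = list(r = 5)),
               "infeasible hard-core")

  cfg <- stand_config(n_stems = 2000, seed = 42)
  p1 <- generate_point_pattern(cfg)
  p2 <- generate_point_pattern(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 2000L)
  expect_true(all(p1[, 1] >= 0 & p1[, 1] <= 200))
  expect_true(all(p1[, 2] >= 0 & p1[, 2] <= 110))
})

test_that("hard-core pattern keeps every pair at least r apart (brute force)", {
  cfg <- stand_config(n_stems = 500, pattern = "hardcore",
                      pattern_params = list(r = 5), seed = 9)
  pts <- generate_point_pattern(cfg)
  expect_equal(nrow(pts), 500L)
  d <- stats::dist(pts)
  expect_gte(min(d), 5)
})

test_that("truncated Weibull diameters match the analytic moment", {
  cfg <- stand_config(n_stems = 100000, seed = 5,
                      dbh_weibull = c(shape = 2, scale = 10))
  pts <- generate_point_pattern(cfg)
  stems <- assign_species_and_sizes(pts, cfg)
  # mean of Weibull(2, 10) truncated at 1 cm, by numeric integration
  shape <- 2; scale <- 10
  num <- stats::integrate(function(x) x * dweibull(x, shape, scale),
                          1, Inf, rel.tol = 1e-10)$value
  truth <- num / (1 - pweibull(1, shape, scale))
  expect_lt(abs(mean(stems$dbh_cm) - truth) / truth, 0.02)
  expect_true(all(stems$dbh_cm >= 1))
  expect_true(all(stems$th_m > 1.3))
})

test_that("species marks recover the configured abundances", {
  p <- c(a = 0.55, b = 0.25, c = 0.15, d = 0.05)
  cfg <- stand_config(n_stems = 100000, seed = 2, species_abundances = p)
  pts <- generate_point_pattern(cfg)
  stems <- assign_species_and_sizes(pts, cfg, exact_counts = FALSE)
  phat <- table(stems$species)[names(p)] / nrow(stems)
  expect_lt(max(abs(as.numeric(phat) - p)), 0.02)

  # single species: downstream mingling is forced to zero
  cfg1 <- stand_config(n_stems = 50, seed = 3,
                       species_abundances = c(only = 1))
  s1 <- assign_species_and_sizes(generate_point_pattern(cfg1), cfg1)
  expect_true(all(s1$species == "only"))
  rec <- sssp_table(s1)
  expect_true(all(rec$M == 0))
})

test_that("census preset reproduces its abundance table at the census total", {
  cen <- census_species()
  expect_equal(sum(cen$count), 4596L)
  expect_equal(nrow(cen), 62L)
  cfg <- stand_config(n_stems = 4596, seed = 8)
  stems <- assign_species_and_sizes(generate_point_pattern(cfg), cfg,
                                    exact_counts = TRUE)
  counts <- table(stems$species)
  expect_equal(as.integer(counts[["PS"]]), 1369L)
  expect_equal(as.integer(counts[["LOV"]]), 832L)
  expect_equal(length(counts), 62L)
})

test_that("substrate generation hits its target fraction and is deterministic", {
  cfg <- stand_config(n_stems = 100, seed = 21, rock_target_fraction = 0.283)
  sm <- generate_substrate(cfg)
  achieved <- sm$rock_area / (200 * 110)
  expect_gte(achieved, 0.253)
  expect_lte(achieved, 0.313)
  # independent raster measurement of the same polygons
  rast <- raster_cover_fraction(sm$polygons, c(0, 200), c(0, 110), step = 0.25)
  expect_lt(abs(rast - achieved), 0.01)

  # byte-identical GeoJSON under the same seed
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  write_substrate(sm, f1)
  write_substrate(generate_substrate(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  # zero target: empty substrate, all-soil classification downstream
  cfg0 <- stand_config(n_stems = 100, seed = 21, rock_target_fraction = 0)
  sm0 <- generate_substrate(cfg0)
  expect_length(sm0$polygons, 0)
  expect_equal(sm0$soil_area, 22000)
})

test_that("noiseless elevation fields are exactly planar", {
  grid <- build_quadrat_grid(60, 40, 10)
  cfg <- stand_config(plot_width = 60, plot_height = 40, n_stems = 10,
                      seed = 4, elevation_noise_sd = 0,
                      elevation_trend = c(base = 1293, slope_deg = 25,
                                          dip_azimuth_deg = 200))
  ef <- generate_elevation_field(cfg, grid)
  truth <- plane_z(ef$x, ef$y, 1293, 25, 200, 30, 20)
  expect_equal(ef$z, truth, tolerance = 1e-12)

  # flat configuration: all elevations equal the base
  cfg0 <- stand_config(plot_width = 60, plot_height = 40, n_stems = 10,
                       seed = 4, elevation_noise_sd = 0,
                       elevation_trend = c(1293, 0, 200))
  expect_true(all(generate_elevation_field(cfg0, grid)$z == 1293))
})

test_that("scenario invariants: in-plot, distinct, exact count, reproducible", {
  sc <- demo_scenario()
  stems <- sc$stems
  expect_equal(nrow(stems), 1200L)
  expect_true(all(stems$x >= 0 & stems$x <= 200 &
                  stems$y >= 0 & stems$y <= 110))
  expect_false(anyDuplicated(stems[, c("x", "y")]) > 0)
  expect_gte(min(stats::dist(cbind(head(stems$x, 300), head(stems$y, 300)))),
             0.01)
  sc2 <- simulate_stand(sc$config)
  expect_identical(sc$stems, sc2$stems)
  expect_identical(sc$elevations, sc2$elevations)
})

test_that("mean W orders hard-core < Poisson < cluster patterns", {
  mean_w <- function(pattern, params) {
    mean(sapply(1:6, function(s) {
      cfg <- stand_config(n_stems = 2000, pattern = pattern,
                          pattern_params = params, seed = 100 + s,
                          species_abundances = c(one = 1),
                          rock_target_fraction = 0, elevation_noise_sd = 0)
      stems <- assign_species_and_sizes(generate_point_pattern(cfg), cfg)
      rec <- sssp_table(stems, buffer_m = 5)
      mean(rec$W[!rec$edge_flag])
    }))
  }
  w_hard <- mean_w("hardcore", list(r = 2))
  w_pois <- mean_w("poisson", list())
  w_clus <- mean_w("thomas_cluster",
                   list(parent_intensity = 60 / 22000, cluster_sd = 3))
  expect_lt(w_hard, w_pois)
  expect_lt(w_pois, w_clus)
})
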