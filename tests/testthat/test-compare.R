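test_that("basal area follows the closed form and the census threshold", {
  expect_equal(basal_area(20), pi * 0.01, tolerance = 1e-12)
  expect_equal(basal_area(200 / sqrt(pi)), 1.0, tolerance = 1e-12)
  expect_equal(basal_area(24.83), pi * (24.83 / 200)^2, tolerance = 1e-15)
  expect_equal(round(basal_area(24.83), 7), 0.0484221)
  expect_error(basal_area(0.5), "census threshold")
  # monotone in DBH
  d <- seq(1, 100, by = 0.5)
  expect_true(all(diff(basal_area(d)) > 0))
})

test_that("quadrat size metrics average stems and flag empty cells", {
  stems <- lattice_stems(4, 4, spacing = 10, margin = 5)  # one per cell
  g <- build_quadrat_grid(40, 40, 10)
  ef <- local({
    cfg <- stand_config(plot_width = 40, plot_height = 40, n_stems = 10,
                        seed = 1, elevation_noise_sd = 0,
                        elevation_trend = c(100, 0, 0))
    generate_elevation_field(cfg, g)
  })
  tt <- terrain_table(g, ef, substrate = NULL)
  sm <- quadrat_size_metrics(stems, g, tt)
  expect_true(all(sm$quadrat$n == 1))
  expect_true(all(sm$quadrat$mean_dbh == 10))
  expect_equal(sm$quadrat$mean_ba, rep(basal_area(10), 16))
  # zero variance across quadrats when all stems are identical
  expect_equal(stats::var(sm$quadrat$mean_dbh), 0)

  # Jensen direction: mean per-tree BA >= BA of the mean DBH
  stems2 <- random_stems(300, seed = 5)
  cc <- assign_quadrat(g <- build_quadrat_grid(100, 100, 10),
                       stems2$x, stems2$y)
  for (cl in split(seq_len(300), cc)) {
    expect_gte(mean(basal_area(stems2$dbh_cm[cl])) + 1e-12,
               basal_area(mean(stems2$dbh_cm[cl])))
  }
})

test_that("rock-biased size reduction is recovered as a rock/soil difference", {
  hits <- 0L
  for (s in 1:20) {
    sc <- list()
    cfg <- stand_config(n_stems = 600, seed = 500 + s)
    stems <- assign_species_and_sizes(generate_point_pattern(cfg), cfg)
    substrate <- generate_substrate(cfg)
    grid <- build_quadrat_grid(200, 110, 10)
    ef <- generate_elevation_field(cfg, grid)
    tt <- terrain_table(grid, ef, substrate)
    on_rock <- tt$site_type[match(assign_quadrat(grid, stems$x, stems$y),
                                  tt$cell)] == "rock"
    # generator-style rock penalty: shrink DBH by 30% on rock (floor 1 cm)
    stems$dbh_cm[on_rock] <- pmax(1, stems$dbh_cm[on_rock] * 0.7)
    sm <- quadrat_size_metrics(stems, grid, tt)
    st <- sm$site_type
    if (st$mean_dbh[st$site_type == "rock"] <
        st$mean_dbh[st$site_type == "soil"]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("Kruskal-Wallis matches the rank-formula oracle and banding rules", {
  tr <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # closed-form ranks: R1 = 6, R2 = 15, H = 12/(6*7)*(12 + 75) - 21
  H <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(tr$statistic, H, tolerance = 1e-10)
  expect_equal(tr$p_value, stats::pchisq(H, 1, lower.tail = FALSE))
  expect_equal(tr$band, "significant")

  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  # fully identical samples: the tie correction degenerates; report H=0, p=1
  tied <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "empty")

  # monte-carlo permutation cross-check on a small two-group dataset
  x <- c(2.1, 3.4, 1.2, 5.6, 4.4); y <- c(6.2, 7.1, 5.9, 8.0, 2.2)
  obs <- kruskal_wallis(list(x, y))
  pool <- c(x, y)
  set.seed(71)
  perm <- replicate(4000, {
    lab <- sample(rep(1:2, each = 5))
    kruskal_wallis(split(pool, lab))$statistic
  })
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  expect_lt(abs(obs$p_value - p_perm), 0.08)
})

test_that("significance bands put boundary p values in the less significant band", {
  expect_equal(significance_band(0.2), "ns")
  expect_equal(significance_band(0.05), "ns")
  expect_equal(significance_band(0.049), "significant")
  expect_equal(significance_band(0.01), "significant")
  expect_equal(significance_band(0.009), "highly_significant")
  expect_error(significance_band(1.2), "0, 1")
})

test_that("KW is invariant under monotone transforms (rank-based)", {
  set.seed(19)
  a <- rnorm(15); b <- rnorm(15, 0.8)
  t1 <- kruskal_wallis(list(a, b))
  t2 <- kruskal_wallis(list(exp(a), exp(b)))
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p_value, t2$p_value)
})

test_that("KS statistic equals the exhaustive ECDF supremum", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(10, 11))$statistic, 1)
  # quantized structure-parameter inputs
  x <- c(0, 0.25, 0.5); y <- c(0.5, 0.75, 1)
  got <- ks_two_sample(x, y)$statistic
  grid <- sort(unique(c(x, y)))
  oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_equal(got, oracle)
  expect_equal(got, 2 / 3, tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(0), 1), "empty")
})

test_that("linear trends match the normal-equations oracle", {
  x <- 1:10
  tr <- suppressWarnings(linear_trend(x, 2 * x + 1))  # lm flags exact fits
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_equal(tr$intercept, 1, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1)

  trc <- linear_trend(x, rep(3, 10))
  expect_equal(trc$slope, 0, tolerance = 1e-12)
  expect_equal(trc$r_squared, 0)

  expect_error(linear_trend(rep(1, 5), 1:5), "zero variance")
  expect_error(linear_trend(1:2, 1:2), "at least 3")

  set.seed(29)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    xs <- rnorm(n); ys <- rnorm(n)
    tr <- linear_trend(xs, ys)
    X <- cbind(1, xs)
    beta <- solve(t(X) %*% X, t(X) %*% ys)
    expect_equal(tr$intercept, beta[1], tolerance = 1e-9)
    expect_equal(tr$slope, beta[2], tolerance = 1e-9)
  }

  # per-group fits
  g <- rep(c("rock", "soil"), each = 10)
  xg <- c(1:10, 1:10); yg <- c(3 * (1:10), -2 * (1:10) + 5)
  trg <- suppressWarnings(linear_trend(xg, yg, group = g))  # exact fits
  expect_equal(trg$slope[trg$group == "rock"], 3, tolerance = 1e-12)
  expect_equal(trg$slope[trg$group == "soil"], -2, tolerance = 1e-12)
})

test_that("ordination export aligns rows and conserves abundances", {
  sc <- demo_scenario()
  rec <- sssp_table(sc$stems, sc$grid, sc$terrain)
  suppressMessages(
    ords <- ordination_export(sc$stems, sc$grid, sc$terrain, records = rec))
  expect_equal(nrow(ords$response), nrow(ords$explanatory))
  expect_equal(nrow(ords$response), nrow(ords$abundance))
  expect_identical(ords$response$cell, ords$explanatory$cell)
  expect_identical(names(ords$explanatory),
                   c("cell", "rock_area", "soil_area", "elevation",
                     "convexity", "aspect", "slope"))
  # abundance row sums equal the quadrat N of the diversity table
  div <- diversity_table(sc$stems, sc$grid, sc$terrain)$quadrat
  rs <- rowSums(ords$abundance[, -1, drop = FALSE])
  expect_equal(unname(rs), div$N[match(ords$abundance$cell, div$cell)])
  expect_false(anyNA(ords$response))
})
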