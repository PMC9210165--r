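# Configuration of the synthetic stand generator. The default preset
# emulates the census of a 2.2 ha (200 x 110 m) old-growth oak forest plot
# on karst terrain: 4,596 live stems of 62 species with a strongly skewed
# abundance distribution, ~28% exposed rock, mean elevation ~1,293 m and a
# mean slope of ~25 degrees.

#' Census species-abundance preset
#'
#' Species list of the old-growth karst oak forest the generator emulates:
#' 40 enumerated taxa plus 22 rare species. The rare species are pooled in
#' the source census (28 individuals across 22 taxa); here they are expanded
#' as 6 species of 2 stems and 16 singletons so that richness and total
#' abundance are both preserved. Rare life forms were not recorded and are
#' assigned "tree".
#'
#' @return A data.frame with columns `species` (label), `count` (stems) and
#'   `lifeform` (`"tree"` or `"shrub"`); counts sum to 4596 over 62 species.
#' @export
#' @examples
#' sum(census_species()$count)  # 4596
census_species <- function() {
  listed <- data.frame(
    species = c("PS", "LOV", "QF", "QV", "RC", "CMV", "KD", "TG", "CS", "VM",
                "BA", "MR", "AK", "LV", "PL", "AA", "LF", "LP", "CA", "MF",
                "BK", "PT", "LN", "PY", "CN", "KS", "GP", "CM", "FI", "LO",
                "CR", "CC", "CG", "EJ", "IF", "CP", "AD", "IM", "H", "SR"),
    count = c(1369L, 832L, 698L, 638L, 203L, 140L, 139L, 126L, 66L, 53L,
              42L, 30L, 23L, 21L, 18L, 17L, 15L, 14L, 13L, 11L,
              10L, 6L, 6L, 5L, 5L, 5L, 5L, 5L, 5L, 4L,
              4L, 3L, 3L, 3L, 3L, 3L, 3L, 9L, 7L, 6L),
    lifeform = c("tree", "shrub", "tree", "tree", "shrub", "shrub", "tree",
                 "tree", "tree", "tree", "tree", "shrub", "shrub", "shrub",
                 "tree", "tree", "tree", "tree", "tree", "shrub", "shrub",
                 "shrub", "shrub", "tree", "shrub", "tree", "shrub", "shrub",
                 "tree", "shrub", "shrub", "tree", "tree", "tree", "tree",
                 "tree", "tree", "shrub", "tree", "tree"),
    stringsAsFactors = FALSE
  )
  rare <- data.frame(
    species = sprintf("RARE%02d", 1:22),
    count = c(rep(2L, 6L), rep(1L, 16L)),
    lifeform = "tree",
    stringsAsFactors = FALSE
  )
  rbind(listed, rare)
}

#' Build a synthetic stand configuration
#'
#' All arguments have defaults describing the emulated karst oak plot; any
#' subset can be overridden. Relative abundances may be given directly or
#' via `species_abundances = "census"` ([census_species()]).
#'
#' @param plot_width,plot_height Plot extent, m.
#' @param n_stems Number of live stems to generate.
#' @param pattern Point process: `"poisson"` (complete spatial randomness),
#'   `"thomas_cluster"` (Poisson cluster process conditioned on `n_stems`)
#'   or `"hardcore"` (sequential inhibition with a minimum spacing).
#' @param pattern_params Named list. For `thomas_cluster`:
#'   `parent_intensity` (parents per m2) and `cluster_sd` (offspring
#'   dispersal, m). For `hardcore`: `r` (minimum pairwise distance, m).
#' @param species_abundances `"census"`, or a named numeric vector of
#'   relative abundances summing to 1.
#' @param lifeform_of_species Named character vector mapping species to
#'   `"tree"`/`"shrub"`; defaults come with the census preset, otherwise
#'   `"tree"`.
#' @param dbh_weibull `c(shape, scale)` of the Weibull DBH distribution
#'   (cm), left-truncated at the 1 cm census threshold.
#' @param height_allometry `c(a, b)` of the height model
#'   `TH = 1.3 + a * DBH^b` (m, DBH in cm).
#' @param height_noise_sdlog Lognormal multiplicative noise (sdlog) on the
#'   allometric height increment; 0 disables it.
#' @param rock_target_fraction Target proportion of the plot under rock,
#'   in [0, 0.95).
#' @param rock_blob_params Named list: `n_seeds` (number of outcrop blobs)
#'   and `mean_radius` (m).
#' @param elevation_trend `c(base, slope_deg, dip_azimuth_deg)`: plane
#'   elevation at the plot center (m), dip angle (degrees) and downslope
#'   bearing (degrees clockwise from north).
#' @param elevation_noise_sd Standard deviation (m) of the smooth
#'   correlated noise added to the planar trend; 0 gives an exact plane.
#' @param elevation_noise_range Correlation length (m) of that noise.
#' @param min_separation Minimum distance between stems, m; coincident
#'   stems are rejected because neighbour azimuths are undefined at zero
#'   distance.
#' @param seed Integer seed; drives independent sub-streams for points,
#'   marks, substrate and elevation.
#' @return An object of class `stand_config`.
#' @export
#' @examples
#' cfg <- stand_config(n_stems = 500, seed = 1)
#' cfg$plot_width
stand_config <- function(plot_width = 200, plot_height = 110,
                         n_stems = 4596L,
                         pattern = c("poisson", "thomas_cluster", "hardcore"),
                         pattern_params = list(),
                         species_abundances = "census",
                         lifeform_of_species = NULL,
                         dbh_weibull = c(shape = 1.1, scale = 5),
                         height_allometry = c(a = 1.9, b = 0.55),
                         height_noise_sdlog = 0.15,
                         rock_target_fraction = 0.283,
                         rock_blob_params = list(n_seeds = 26L, mean_radius = 9),
                         elevation_trend = c(base = 1293, slope_deg = 25,
                                             dip_azimuth_deg = 200),
                         elevation_noise_sd = 1.5,
                         elevation_noise_range = 40,
                         min_separation = 0.01,
                         seed = 1L) {
  pattern <- match.arg(pattern)
  if (!is.numeric(plot_width) || !is.numeric(plot_height) ||
      plot_width <= 0 || plot_height <= 0)
    stop2("plot dimensions must be positive")
  n_stems <- as.integer(n_stems)
  if (is.na(n_stems) || n_stems < 5L)
    stop2("n_stems must be an integer >= 5")

  if (identical(species_abundances, "census")) {
    cen <- census_species()
    p <- cen$count / sum(cen$count)
    names(p) <- cen$species
    if (is.null(lifeform_of_species)) {
      lifeform_of_species <- cen$lifeform
      names(lifeform_of_species) <- cen$species
    }
    species_abundances <- p
  }
  p <- species_abundances
  if (length(p) == 0L) stop2("species abundance vector is empty")
  if (is.null(names(p))) names(p) <- sprintf("sp%02d", seq_along(p))
  if (any(p < 0)) stop2("species abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop2("species abundances must sum to 1 (tolerance 1e-9), got ", sum(p))
  if (is.null(lifeform_of_species)) {
    lifeform_of_species <- rep("tree", length(p))
    names(lifeform_of_species) <- names(p)
  }
  if (!all(names(p) %in% names(lifeform_of_species)))
    stop2("lifeform_of_species must cover every species in the abundance vector")
  if (!all(lifeform_of_species %in% c("tree", "shrub")))
    stop2("life forms must be 'tree' or 'shrub'")

  if (length(dbh_weibull) != 2L || any(dbh_weibull <= 0))
    stop2("dbh_weibull must be positive c(shape, scale)")
  # the truncated-at-1-cm distribution must retain mass
  if (stats::pweibull(1, dbh_weibull[[1L]], dbh_weibull[[2L]]) > 0.99)
    stop2("dbh_weibull scale too small: almost no mass above the 1 cm threshold")
  if (!is.numeric(rock_target_fraction) || rock_target_fraction < 0 ||
      rock_target_fraction > 0.95)
    stop2("rock_target_fraction must lie in [0, 0.95]")
  if (elevation_noise_sd < 0) stop2("elevation_noise_sd must be >= 0")
  if (min_separation <= 0) stop2("min_separation must be > 0")

  defaults <- switch(pattern,
    poisson = list(),
    thomas_cluster = list(parent_intensity = 40 / (plot_width * plot_height),
                          cluster_sd = 5),
    hardcore = list(r = 1)
  )
  pattern_params <- utils::modifyList(defaults, pattern_params)
  if (pattern == "hardcore") {
    r <- pattern_params$r
    if (!is.numeric(r) || r <= 0) stop2("hardcore radius r must be > 0")
    # quick feasibility screen: disks of radius r/2 must fit loosely
    if (n_stems * pi * (r / 2)^2 > 0.547 * plot_width * plot_height)
      stop2(sprintf(
        "infeasible hard-core packing: n = %d disks of radius r/2 = %.3g m exceed the jamming density of a %g x %g m window",
        n_stems, r / 2, plot_width, plot_height))
  }

  structure(list(
    plot_width = plot_width, plot_height = plot_height, n_stems = n_stems,
    pattern = pattern, pattern_params = pattern_params,
    species_abundances = p, lifeform_of_species = lifeform_of_species,
    dbh_weibull = c(shape = dbh_weibull[[1L]], scale = dbh_weibull[[2L]]),
    height_allometry = c(a = height_allometry[[1L]], b = height_allometry[[2L]]),
    height_noise_sdlog = height_noise_sdlog,
    rock_target_fraction = rock_target_fraction,
    rock_blob_params = rock_blob_params,
    elevation_trend = c(base = elevation_trend[[1L]],
                        slope_deg = elevation_trend[[2L]],
                        dip_azimuth_deg = elevation_trend[[3L]]),
    elevation_noise_sd = elevation_noise_sd,
    elevation_noise_range = elevation_noise_range,
    min_separation = min_separation,
    seed = as.integer(seed)
  ), class = "stand_config")
}

#' @export
print.stand_config <- function(x, ...) {
  cat(sprintf("Synthetic stand configuration\n"))
  cat(sprintf("  plot: %g x %g m, %d stems, pattern '%s'\n",
              x$plot_width, x$plot_height, x$n_stems, x$pattern))
  cat(sprintf("  species pool: %d; rock target %.3f; seed %d\n",
              length(x$species_abundances), x$rock_target_fraction, x$seed))
  invisible(x)
}
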