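# Synthetic stand generator. The undeposited field census is emulated by
# construction: a marked point pattern (species, DBH, height, life form) in
# a rectangular plot, a rock-outcrop substrate map hitting a target cover
# fraction, and a planar-trend elevation field with smooth correlated
# noise. One global seed drives independent sub-streams (points, marks,
# substrate, elevation) so each component can be regenerated alone.

#' Generate a stem point pattern
#'
#' Draws exactly `n_stems` stem locations in the plot window under one of
#' three point processes: homogeneous Poisson (complete spatial
#' randomness), a Thomas cluster process conditioned on the total count
#' (parents uniform, offspring isotropic Gaussian reflected into the
#' window), or a hard-core process (sequential inhibition with minimum
#' pairwise distance `r`). All three enforce the configured minimum
#' separation between stems.
#'
#' @param config A [stand_config()].
#' @return A two-column matrix of (x, y) coordinates, `n_stems` rows.
#' @export
#' @examples
#' pts <- generate_point_pattern(stand_config(n_stems = 100, seed = 7))
#' nrow(pts)
generate_point_pattern <- function(config) {
  stopifnot(inherits(config, "stand_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_subseeds(config$seed)[1L])
  W <- config$plot_width; H <- config$plot_height
  n <- config$n_stems

  pts <- switch(config$pattern,
    poisson = cbind(stats::runif(n, 0, W), stats::runif(n, 0, H)),
    thomas_cluster = rthomas_n(n, W, H, config$pattern_params),
    hardcore = rhardcore_n(n, W, H, config$pattern_params$r,
                           config$min_separation)
  )
  if (config$pattern != "hardcore")
    pts <- enforce_min_separation(pts, W, H, config$min_separation)
  colnames(pts) <- c("x", "y")
  pts
}

# Thomas cluster process conditioned on exact n: Poisson number of uniform
# parents, each offspring assigned a uniformly chosen parent plus an
# isotropic Gaussian displacement, reflected back into the window.
rthomas_n <- function(n, W, H, params) {
  kappa <- params$parent_intensity
  sdv <- params$cluster_sd
  if (!is.numeric(kappa) || kappa <= 0) stop2("parent_intensity must be > 0")
  if (!is.numeric(sdv) || sdv <= 0) stop2("cluster_sd must be > 0")
  np <- max(1L, stats::rpois(1L, kappa * W * H))
  px <- stats::runif(np, 0, W); py <- stats::runif(np, 0, H)
  pid <- sample.int(np, n, replace = TRUE)
  x <- reflect_into(px[pid] + stats::rnorm(n, 0, sdv), W)
  y <- reflect_into(py[pid] + stats::rnorm(n, 0, sdv), H)
  cbind(x, y)
}

reflect_into <- function(v, hi) {
  p <- 2 * hi
  v <- v %% p
  ifelse(v > hi, p - v, v)
}

# Sequential inhibition (dart throwing) with minimum pairwise distance r.
rhardcore_n <- function(n, W, H, r, min_sep) {
  if (!is.numeric(r) || r <= 0) stop2("hardcore radius r must be > 0")
  r <- max(r, min_sep)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop2(sprintf(
        "could not place %d hard-core stems with r = %g m in a %g x %g m window (placed %d after %d attempts)",
        n, r, W, H, placed, attempts - 1L))
    cx <- stats::runif(1L, 0, W); cy <- stats::runif(1L, 0, H)
    if (placed > 0L) {
      i <- seq_len(placed)
      if (min((xs[i] - cx)^2 + (ys[i] - cy)^2) < r^2) next
    }
    placed <- placed + 1L
    xs[placed] <- cx; ys[placed] <- cy
  }
  cbind(xs, ys)
}

# Replace points that violate the minimum separation (sorted sweep along
# x); neighbour azimuths are undefined at zero distance, so coincident
# stems are rejected and redrawn uniformly.
enforce_min_separation <- function(pts, W, H, d, max_rounds = 100L) {
  for (round in seq_len(max_rounds)) {
    bad <- close_pair_indices(pts[, 1L], pts[, 2L], d)
    if (length(bad) == 0L) return(pts)
    pts[bad, 1L] <- stats::runif(length(bad), 0, W)
    pts[bad, 2L] <- stats::runif(length(bad), 0, H)
  }
  stop2("could not enforce the minimum stem separation of ", d, " m")
}

# Indices of the later member of every pair closer than d.
close_pair_indices <- function(x, y, d) {
  n <- length(x)
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  bad <- logical(n)
  j0 <- 1L
  for (i in 2L:n) {
    while (xo[i] - xo[j0] >= d) j0 <- j0 + 1L
    if (j0 < i) {
      j <- j0:(i - 1L)
      if (any((xo[j] - xo[i])^2 + (yo[j] - yo[i])^2 < d^2)) bad[i] <- TRUE
    }
  }
  ord[bad]
}

#' Attach species, sizes and life forms to a point pattern
#'
#' Species come from the configured relative abundances, either iid or as
#' exact largest-remainder multinomial counts (the default, so the census
#' preset reproduces its abundance table exactly at the census total).
#' DBH is Weibull, left-truncated at the 1 cm census threshold; height
#' follows `TH = 1.3 + a * DBH^b` with optional mean-one lognormal noise
#' on the increment, so heights always exceed breast height.
#'
#' @param points Two-column (x, y) matrix from [generate_point_pattern()].
#' @param config A [stand_config()].
#' @param exact_counts Use exact multinomial species counts (largest
#'   remainder) instead of iid sampling.
#' @return A `stem_map` data.frame: `id, x, y, species, dbh_cm, th_m,
#'   lifeform`.
#' @export
assign_species_and_sizes <- function(points, config, exact_counts = TRUE) {
  stopifnot(inherits(config, "stand_config"))
  n <- nrow(points)
  p <- config$species_abundances
  if (length(p) == 0L) stop2("species abundance vector is empty")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_subseeds(config$seed)[2L])

  if (exact_counts) {
    counts <- largest_remainder_counts(p, n)
    species <- sample(rep(names(p), counts))
  } else {
    species <- sample(names(p), n, replace = TRUE, prob = p)
  }

  shape <- config$dbh_weibull[["shape"]]; scale <- config$dbh_weibull[["scale"]]
  # inverse-CDF draw from the Weibull conditioned on DBH >= 1 cm
  f1 <- stats::pweibull(1, shape, scale)
  u <- stats::runif(n, f1, 1)
  dbh <- stats::qweibull(u, shape, scale)

  a <- config$height_allometry[["a"]]; b <- config$height_allometry[["b"]]
  incr <- a * dbh^b
  sdl <- config$height_noise_sdlog
  if (sdl > 0)
    incr <- incr * stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  th <- 1.3 + incr

  stems <- data.frame(
    id = seq_len(n),
    x = points[, 1L], y = points[, 2L],
    species = species,
    dbh_cm = dbh, th_m = th,
    lifeform = unname(config$lifeform_of_species[species]),
    stringsAsFactors = FALSE
  )
  as_stem_map(stems, config$plot_width, config$plot_height)
}

# Exact multinomial counts by the largest-remainder method; when n * p is
# integral (the census preset at its own total) the counts are exact.
largest_remainder_counts <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a rock-outcrop substrate map
#'
#' Rock cover is modelled as a set of mutually disjoint star-shaped blob
#' polygons (smooth low-order harmonic perturbations of circles around
#' random seeds), clipped to the plot rectangle. Blob radii are scaled
#' iteratively (monotone bisection on a common scale factor, topping up
#' with extra blobs when needed) until the achieved rock fraction is
#' within 0.005 of the target — well inside the 0.03 band the generator
#' guarantees.
#'
#' @param config A [stand_config()].
#' @return A `substrate_map` (see [substrate_map()]); empty when the
#'   target fraction is 0.
#' @export
generate_substrate <- function(config) {
  stopifnot(inherits(config, "stand_config"))
  target <- config$rock_target_fraction
  if (target > 0.95) stop2("rock_target_fraction must be < 0.95")
  W <- config$plot_width; H <- config$plot_height
  if (target == 0)
    return(substrate_map(list(), plot_width = W, plot_height = H))

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_subseeds(config$seed)[3L])
  n_seeds <- config$rock_blob_params$n_seeds %||% 26L
  mean_radius <- config$rock_blob_params$mean_radius %||% 9

  blobs <- list()   # each: list(cx, cy, base_r, max_r, shape fn params)
  achieved <- function(s) {
    a <- 0
    for (b in blobs) {
      poly <- blob_polygon(b, s)
      a <- a + polygon_rect_intersection_area(poly, c(0, W), c(0, H))
    }
    a / (W * H)
  }
  add_blobs <- function(k) {
    for (i in seq_len(k)) {
      for (try in 1:400) {
        r <- stats::rlnorm(1L, meanlog = log(mean_radius) - 0.35^2 / 2,
                           sdlog = 0.35)
        r <- min(r, 2.2 * mean_radius)
        amp <- stats::runif(2L, 0.05, 0.22)
        phase <- stats::runif(2L, 0, 2 * pi)
        max_r <- r * (1 + sum(amp))
        cx <- stats::runif(1L, 0, W); cy <- stats::runif(1L, 0, H)
        ok <- TRUE
        for (b in blobs) {
          if (sqrt((b$cx - cx)^2 + (b$cy - cy)^2) <
              1.02 * (max_r + b$max_r)) { ok <- FALSE; break }
        }
        if (ok) {
          blobs[[length(blobs) + 1L]] <<- list(
            cx = cx, cy = cy, base_r = r, max_r = max_r,
            amp = amp, phase = phase)
          break
        }
      }
    }
  }

  add_blobs(n_seeds)
  for (round in 1:30) {
    if (length(blobs) == 0L)
      stop2("failed to place any substrate blobs in the plot")
    # disjointness holds for any common scale s <= s_max
    s_max <- Inf
    nb <- length(blobs)
    if (nb > 1L) {
      for (i in 1:(nb - 1L)) for (j in (i + 1L):nb) {
        dd <- sqrt((blobs[[i]]$cx - blobs[[j]]$cx)^2 +
                   (blobs[[i]]$cy - blobs[[j]]$cy)^2)
        s_max <- min(s_max, dd / (blobs[[i]]$max_r + blobs[[j]]$max_r))
      }
    }
    s_max <- min(s_max, 3)
    if (achieved(s_max) >= target) {
      lo <- 1e-3; hi <- s_max
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (achieved(mid) < target) lo <- mid else hi <- mid
      }
      s <- (lo + hi) / 2
      polys <- lapply(blobs, function(b)
        clip_polygon_rect(blob_polygon(b, s), c(0, W), c(0, H)))
      polys <- polys[vapply(polys, nrow, 0L) >= 3L]
      sm <- substrate_map(polys, plot_width = W, plot_height = H)
      if (abs(sm$rock_area / (W * H) - target) > 0.03)
        stop2("substrate generation missed the target rock fraction")
      return(sm)
    }
    add_blobs(3L)  # top up and retry
  }
  stop2(sprintf(
    "could not reach rock fraction %.3f with blobs of mean radius %g m in a %g x %g m plot",
    target, mean_radius, W, H))
}

# Star-shaped blob: radius(theta) = s * r * (1 + a1 cos(2 theta + f1)
#                                              + a2 cos(3 theta + f2))
blob_polygon <- function(b, s, k = 28L) {
  theta <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  rad <- s * b$base_r * (1 + b$amp[1L] * cos(2 * theta + b$phase[1L]) +
                             b$amp[2L] * cos(3 * theta + b$phase[2L]))
  cbind(b$cx + rad * cos(theta), b$cy + rad * sin(theta))
}

#' Generate an elevation field over a quadrat grid
#'
#' Elevation at every quadrat vertex and center is a planar trend — the
#' configured base elevation at the plot center, dipping at the configured
#' slope along the dip azimuth — plus smooth correlated Gaussian noise
#' (random harmonic superposition with the configured correlation length).
#' With zero noise the field is exactly planar, so downstream convexity is
#' 0 and slope/aspect equal the configured dip everywhere.
#'
#' @param config A [stand_config()].
#' @param grid A [build_quadrat_grid()] result.
#' @return An `elevation_field` data.frame: `kind` ("vertex"/"center"),
#'   `i`, `j` (lattice row/column), `x`, `y`, `z`.
#' @export
generate_elevation_field <- function(config, grid) {
  stopifnot(inherits(config, "stand_config"), inherits(grid, "quadrat_grid"))
  if (config$elevation_noise_sd < 0) stop2("elevation_noise_sd must be >= 0")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(derive_subseeds(config$seed)[4L])

  s <- grid$cell_size
  vx <- rep(seq(0, grid$plot_width, by = s), times = grid$nrow + 1L)
  vy <- rep(seq(0, grid$plot_height, by = s), each = grid$ncol + 1L)
  vi <- rep(seq_len(grid$nrow + 1L), each = grid$ncol + 1L)
  vj <- rep(seq_len(grid$ncol + 1L), times = grid$nrow + 1L)

  cells <- grid$cells
  x <- c(vx, cells$cx); y <- c(vy, cells$cy)
  kind <- c(rep("vertex", length(vx)), rep("center", nrow(cells)))
  i <- c(vi, cells$row); j <- c(vj, cells$col)

  tr <- config$elevation_trend
  t <- tan(tr[["slope_deg"]] * pi / 180)
  az <- tr[["dip_azimuth_deg"]] * pi / 180
  # elevation decreases along the downslope (dip) direction; base is the
  # plane value at the plot center
  dx <- x - grid$plot_width / 2; dy <- y - grid$plot_height / 2
  z <- tr[["base"]] - t * (dx * sin(az) + dy * cos(az))

  sd <- config$elevation_noise_sd
  if (sd > 0) {
    K <- 48L
    ell <- config$elevation_noise_range
    wx <- stats::rnorm(K, 0, 1 / ell); wy <- stats::rnorm(K, 0, 1 / ell)
    phi <- stats::runif(K, 0, 2 * pi)
    noise <- numeric(length(x))
    for (k in seq_len(K))
      noise <- noise + cos(wx[k] * x + wy[k] * y + phi[k])
    z <- z + sd * sqrt(2 / K) * noise
  }

  structure(data.frame(kind = kind, i = i, j = j, x = x, y = y, z = z,
                       stringsAsFactors = FALSE),
            class = c("elevation_field", "data.frame"))
}

#' Simulate a complete synthetic scenario
#'
#' Runs the three generators under one seed and returns the stem map,
#' substrate map, elevation field and the quadrat grid they share,
#' together with the configuration for provenance.
#'
#' @param config A [stand_config()].
#' @param cell_size Quadrat size, m.
#' @return A list of class `stand_scenario` with elements `stems`,
#'   `substrate`, `elevations`, `grid`, `config`.
#' @export
#' @examples
#' sc <- simulate_stand(stand_config(n_stems = 200, seed = 3))
#' nrow(sc$stems)
simulate_stand <- function(config, cell_size = 10) {
  stopifnot(inherits(config, "stand_config"))
  grid <- build_quadrat_grid(config$plot_width, config$plot_height, cell_size)
  pts <- generate_point_pattern(config)
  stems <- assign_species_and_sizes(pts, config)
  substrate <- generate_substrate(config)
  elevations <- generate_elevation_field(config, grid)
  structure(list(stems = stems, substrate = substrate,
                 elevations = elevations, grid = grid, config = config),
            class = "stand_scenario")
}

#' @export
print.stand_scenario <- function(x, ...) {
  cat(sprintf("Synthetic stand scenario: %d stems, %d species, %d quadrats\n",
              nrow(x$stems), length(unique(x$stems$species)),
              nrow(x$grid$cells)))
  cat(sprintf("  rock fraction %.3f; pattern '%s'; seed %d\n",
              x$substrate$rock_area /
                (x$config$plot_width * x$config$plot_height),
              x$config$pattern, x$config$seed))
  invisible(x)
}
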