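# Fixture builders and independent oracles shared across test files.

# Brute-force O(n^2) k-nearest-neighbour oracle: full distance matrix,
# ties broken by (distance, id) like the implementation claims.
brute_knn <- function(stems, k = 4L) {
  n <- nrow(stems)
  d <- as.matrix(stats::dist(cbind(stems$x, stems$y)))
  diag(d) <- Inf
  nn_id <- matrix(0L, n, k)
  nn_dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], stems$id)[seq_len(k)]
    nn_id[i, ] <- stems$id[ord]
    nn_dist[i, ] <- d[i, ord]
  }
  list(nn_id = nn_id, nn_dist = nn_dist)
}

# Uniform random marked stems in a window, as a plain validated stem map.
random_stems <- function(n, width = 100, height = 100, seed = 1,
                         species = c("A", "B", "C"),
                         prob = NULL) {
  set.seed(seed)
  df <- data.frame(
    id = seq_len(n),
    x = runif(n, 0, width), y = runif(n, 0, height),
    species = sample(species, n, replace = TRUE, prob = prob),
    dbh_cm = 1 + rexp(n, 1 / 8),
    th_m = 2 + runif(n, 0, 10),
    lifeform = "tree",
    stringsAsFactors = FALSE
  )
  as_stem_map(df, width, height)
}

# Square lattice of stems with a margin to the plot boundary.
lattice_stems <- function(nx = 10, ny = 10, spacing = 5, margin = 10,
                          species = "A") {
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  df <- data.frame(
    id = seq_len(nrow(g)),
    x = margin + (g$ix - 1) * spacing,
    y = margin + (g$iy - 1) * spacing,
    species = species,
    dbh_cm = 10, th_m = 8, lifeform = "tree",
    stringsAsFactors = FALSE
  )
  as_stem_map(df, margin * 2 + (nx - 1) * spacing,
              margin * 2 + (ny - 1) * spacing)
}

# Neighbour coordinates at given compass bearings around a reference.
neighbours_at_azimuths <- function(az_deg, ref = c(0, 0), dist = 1) {
  rad <- az_deg * pi / 180
  cbind(ref[1] + dist * sin(rad), ref[2] + dist * cos(rad))
}

# Planar elevation field evaluator (oracle for the generator and the
# terrain identities): base at the plot center, dipping along azimuth.
plane_z <- function(x, y, base, slope_deg, dip_az_deg, cx, cy) {
  t <- tan(slope_deg * pi / 180)
  az <- dip_az_deg * pi / 180
  base - t * ((x - cx) * sin(az) + (y - cy) * cos(az))
}

# A small cached end-to-end scenario shared by expensive tests.
.demo_env <- new.env(parent = emptyenv())
demo_scenario <- function() {
  if (is.null(.demo_env$sc)) {
    cfg <- stand_config(n_stems = 1200, seed = 42)
    .demo_env$sc <- simulate_stand(cfg)
    .demo_env$sc$terrain <- terrain_table(.demo_env$sc$grid,
                                          .demo_env$sc$elevations,
                                          .demo_env$sc$substrate)
  }
  .demo_env$sc
}
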