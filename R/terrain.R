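# Quadrat grid and per-quadrat topographic attributes. Conventions:
# plot-local Cartesian metres, x east, y north, origin at the lower-left
# corner; azimuths clockwise from true north; half-open cell membership
# [lo, hi) with the top/right plot boundary folded into the last cell, so
# every in-plot point belongs to exactly one quadrat.

#' Build the quadrat grid
#'
#' Tiles the plot rectangle with square cells, row-major (row 1 at the
#' bottom). Plot dimensions must be integer multiples of the cell size.
#'
#' @param plot_width,plot_height Plot extent, m.
#' @param cell_size Cell side, m (default 10).
#' @return A `quadrat_grid`: plot extent, cell size, `nrow`, `ncol` and a
#'   `cells` data.frame (`cell`, `row`, `col`, `x0`, `x1`, `y0`, `y1`,
#'   `cx`, `cy`).
#' @export
#' @examples
#' g <- build_quadrat_grid(200, 110, 10)
#' nrow(g$cells)  # 220
build_quadrat_grid <- function(plot_width, plot_height, cell_size = 10) {
  if (plot_width <= 0 || plot_height <= 0 || cell_size <= 0)
    stop2("plot dimensions and cell size must be positive")
  for (d in c(plot_width, plot_height)) {
    rem <- d %% cell_size
    if (min(rem, cell_size - rem) > 1e-9)
      stop2(sprintf(
        "plot dimension %g m is not a multiple of the %g m cell size (remainder %g m)",
        d, cell_size, rem))
  }
  ncol <- as.integer(round(plot_width / cell_size))
  nrow <- as.integer(round(plot_height / cell_size))
  col <- rep(seq_len(ncol), times = nrow)
  row <- rep(seq_len(nrow), each = ncol)
  x0 <- (col - 1L) * cell_size; y0 <- (row - 1L) * cell_size
  cells <- data.frame(
    cell = seq_len(ncol * nrow), row = row, col = col,
    x0 = x0, x1 = x0 + cell_size, y0 = y0, y1 = y0 + cell_size,
    cx = x0 + cell_size / 2, cy = y0 + cell_size / 2
  )
  structure(list(plot_width = plot_width, plot_height = plot_height,
                 cell_size = cell_size, nrow = nrow, ncol = ncol,
                 cells = cells),
            class = "quadrat_grid")
}

#' @export
print.quadrat_grid <- function(x, ...) {
  cat(sprintf("Quadrat grid: %d x %d cells of %g m (%d quadrats, %g x %g m plot)\n",
              x$ncol, x$nrow, x$cell_size, nrow(x$cells),
              x$plot_width, x$plot_height))
  invisible(x)
}

#' Assign points to quadrats
#'
#' Half-open membership: cell (r, c) owns `[x0, x1) x [y0, y1)`; points on
#' the top/right plot boundary belong to the last cell.
#'
#' @param grid A `quadrat_grid`.
#' @param x,y Point coordinates, m.
#' @return Integer vector of cell ids (row-major).
#' @export
assign_quadrat <- function(grid, x, y) {
  out <- x < 0 | x > grid$plot_width | y < 0 | y > grid$plot_height
  if (any(out))
    stop2("point(s) outside the plot rectangle at position(s) ",
          paste(utils::head(which(out), 5L), collapse = ", "))
  col <- pmin(floor(x / grid$cell_size) + 1L, grid$ncol)
  row <- pmin(floor(y / grid$cell_size) + 1L, grid$nrow)
  as.integer((row - 1L) * grid$ncol + col)
}

#' Quadrat elevation from its four vertices
#'
#' The quadrat elevation is the arithmetic mean of the four vertex
#' elevations.
#'
#' @param vertex_z Four finite vertex elevations, m.
#' @return Mean elevation, m.
#' @export
quadrat_elevation <- function(vertex_z) {
  if (length(vertex_z) != 4L || !all(is.finite(vertex_z)))
    stop2("quadrat elevation needs 4 finite vertex elevations")
  mean(vertex_z)
}

#' Quadrat convexity
#'
#' Center elevation minus the mean vertex elevation: positive when the
#' center is raised above its surroundings, negative when sunken, zero for
#' a locally planar (or bilinearly interpolated) surface.
#'
#' @param center_z Center elevation, m.
#' @param vertex_z Four vertex elevations, m.
#' @return Convexity, m.
#' @export
quadrat_convexity <- function(center_z, vertex_z) {
  if (length(center_z) != 1L || !is.finite(center_z))
    stop2("center elevation is missing; enable bilinear interpolation or supply it")
  center_z - quadrat_elevation(vertex_z)
}

# Plane normal through three (x, y, z) points; errors when the xy
# projections are collinear (no unique plane orientation over the cell).
triple_normal <- function(p1, p2, p3) {
  u <- p2 - p1; v <- p3 - p1
  n <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  if (abs(u[1L] * v[2L] - u[2L] * v[1L]) < 1e-12)
    stop2("degenerate vertex triple: collinear in the xy plane")
  n
}

vertex_triples <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (!all(dim(vertices) == c(4L, 3L)))
    stop2("vertices must be a 4 x 3 (x, y, z) matrix")
  lapply(1:4, function(skip) vertices[-skip, , drop = FALSE])
}

#' Quadrat slope from the four vertex triples
#'
#' Each of the four planes through three of the quadrat's vertices has a
#' dip angle `acos(|n_z| / |n|)` (n the plane normal); the quadrat slope
#' is the arithmetic mean of the four dip angles.
#'
#' @param vertices 4 x 3 matrix of (x, y, z) vertex coordinates, m.
#' @return Slope in degrees, in [0, 90].
#' @export
quadrat_slope <- function(vertices) {
  dips <- vapply(vertex_triples(vertices), function(tr) {
    n <- triple_normal(tr[1L, ], tr[2L, ], tr[3L, ])
    acos(abs(n[3L]) / sqrt(sum(n^2))) * 180 / pi
  }, 0)
  mean(dips)
}

#' Quadrat aspect from the four vertex triples
#'
#' Aspect of each triple's plane is the compass bearing of its
#' steepest-descent (downslope) direction, the GIS convention. The four
#' triple aspects are combined by the circular mean — an arithmetic mean
#' is wrong across the 0/360 wrap. Flat triples (dip < 1e-9 degrees) have
#' no defined aspect and are excluded; a fully flat quadrat returns `NA`.
#'
#' @param vertices 4 x 3 matrix of (x, y, z) vertex coordinates, m.
#' @return Aspect in degrees clockwise from north in [0, 360), or `NA`.
#' @export
quadrat_aspect <- function(vertices) {
  aspects <- vapply(vertex_triples(vertices), function(tr) {
    n <- triple_normal(tr[1L, ], tr[2L, ], tr[3L, ])
    dip <- acos(abs(n[3L]) / sqrt(sum(n^2))) * 180 / pi
    if (dip < 1e-9) return(NA_real_)
    # plane z = ax + by + c with a = -nx/nz, b = -ny/nz; steepest descent
    # points along -(a, b)
    a <- -n[1L] / n[3L]; b <- -n[2L] / n[3L]
    azimuth_deg(-a, -b)
  }, 0)
  circular_mean_deg(aspects)
}

#' Rock fraction of one quadrat
#'
#' Exact area of intersection between the cell rectangle and the rock
#' polygons (Sutherland-Hodgman clipping), divided by the cell area. Rock
#' polygons are assumed disjoint; the result is clamped to [0, 1].
#'
#' @param cell One row of `grid$cells` (or any list with `x0,x1,y0,y1`).
#' @param substrate A [substrate_map()].
#' @return Rock proportion in [0, 1].
#' @export
rock_fraction <- function(cell, substrate) {
  stopifnot(inherits(substrate, "substrate_map"))
  xlim <- c(cell$x0, cell$x1); ylim <- c(cell$y0, cell$y1)
  a <- 0
  for (p in substrate$polygons)
    a <- a + polygon_rect_intersection_area(p, xlim, ylim)
  min(1, a / ((xlim[2L] - xlim[1L]) * (ylim[2L] - ylim[1L])))
}

#' Per-quadrat terrain table
#'
#' Computes elevation, convexity, slope, aspect and rock fraction for every
#' quadrat from an elevation field and a substrate map, then classifies
#' each quadrat as rock or soil.
#'
#' @param grid A `quadrat_grid`.
#' @param elevations An `elevation_field` (vertex and center records).
#' @param substrate A `substrate_map`, or `NULL` for an all-soil plot.
#' @param rock_threshold Rock-cover proportion at or above which a quadrat
#'   is classified rock (default 0.5).
#' @param interpolate_centers If `TRUE`, missing center elevations are
#'   filled by bilinear interpolation of the four vertices — which forces
#'   convexity to 0 for those quadrats; the fallback is flagged in the
#'   `center_interpolated` column.
#' @return A `terrain_table` data.frame, one row per quadrat: `cell`,
#'   `row`, `col`, `elevation`, `convexity`, `slope`, `aspect`,
#'   `rock_fraction`, `site_type`, `center_interpolated`; site totals in
#'   `attr(, "totals")`.
#' @export
terrain_table <- function(grid, elevations, substrate = NULL,
                          rock_threshold = 0.5,
                          interpolate_centers = FALSE) {
  stopifnot(inherits(grid, "quadrat_grid"))
  verts <- elevations[elevations$kind == "vertex", , drop = FALSE]
  cents <- elevations[elevations$kind == "center", , drop = FALSE]
  vz <- matrix(NA_real_, nrow = grid$nrow + 1L, ncol = grid$ncol + 1L)
  vz[cbind(verts$i, verts$j)] <- verts$z
  if (anyNA(vz)) stop2("elevation field is missing vertex records")
  cz <- matrix(NA_real_, nrow = grid$nrow, ncol = grid$ncol)
  if (nrow(cents) > 0L) cz[cbind(cents$i, cents$j)] <- cents$z

  cells <- grid$cells
  n <- nrow(cells)
  elevation <- convexity <- slope <- aspect <- frac <- numeric(n)
  interp <- logical(n)
  for (k in seq_len(n)) {
    r <- cells$row[k]; c <- cells$col[k]
    z4 <- c(vz[r, c], vz[r, c + 1L], vz[r + 1L, c + 1L], vz[r + 1L, c])
    vmat <- cbind(
      x = c(cells$x0[k], cells$x1[k], cells$x1[k], cells$x0[k]),
      y = c(cells$y0[k], cells$y0[k], cells$y1[k], cells$y1[k]),
      z = z4)
    elevation[k] <- quadrat_elevation(z4)
    zc <- cz[r, c]
    if (is.na(zc)) {
      if (!interpolate_centers)
        stop2("center elevation missing for quadrat ", cells$cell[k],
              "; supply it or set interpolate_centers = TRUE")
      zc <- mean(z4)  # bilinear interpolation at the cell center
      interp[k] <- TRUE
    }
    convexity[k] <- quadrat_convexity(zc, z4)
    slope[k] <- quadrat_slope(vmat)
    aspect[k] <- quadrat_aspect(vmat)
    frac[k] <- if (is.null(substrate)) 0 else rock_fraction(cells[k, ], substrate)
  }
  out <- data.frame(cell = cells$cell, row = cells$row, col = cells$col,
                    elevation = elevation, convexity = convexity,
                    slope = slope, aspect = aspect,
                    rock_fraction = frac,
                    center_interpolated = interp,
                    stringsAsFactors = FALSE)
  classify_site_type(out, grid, rock_threshold = rock_threshold)
}

#' Classify quadrats as rock or soil
#'
#' A quadrat is rock when its rock-cover fraction is at or above the
#' threshold (default 0.5, i.e. the ">= 50% rock" rule), otherwise soil.
#'
#' @param terrain Data.frame with a `rock_fraction` column (one row per
#'   quadrat).
#' @param grid The `quadrat_grid` the rows describe.
#' @param rock_threshold Classification threshold (default 0.5).
#' @return The input with a `site_type` factor column; totals (quadrat
#'   counts and areas per site type, m2) in `attr(, "totals")`.
#' @export
classify_site_type <- function(terrain, grid, rock_threshold = 0.5) {
  site <- ifelse(terrain$rock_fraction >= rock_threshold, "rock", "soil")
  terrain$site_type <- factor(site, levels = c("rock", "soil"))
  cell_area <- grid$cell_size^2
  totals <- list(
    n_rock_quadrats = sum(site == "rock"),
    n_soil_quadrats = sum(site == "soil"),
    rock_quadrat_area = sum(site == "rock") * cell_area,
    soil_quadrat_area = sum(site == "soil") * cell_area,
    rock_threshold = rock_threshold
  )
  structure(terrain, totals = totals,
            class = c("terrain_table", class(terrain)))
}

#' Site-type totals of a terrain table
#'
#' @param terrain A `terrain_table`.
#' @return List: quadrat counts and quadrat areas (m2) per site type.
#' @export
site_type_totals <- function(terrain) {
  attr(terrain, "totals")
}
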