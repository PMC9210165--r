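# Planar polygon primitives used by the substrate map and quadrat
# classification. Polygons are two-column (x, y) matrices in plot-local
# metres, vertices in order, closing edge implicit. All quadrat/plot
# clipping windows are axis-aligned rectangles, for which
# Sutherland-Hodgman clipping is exact; area comes from the shoelace
# formula. Degenerate connector edges that S-H can introduce for
# multi-piece intersections carry zero area and do not bias results.

#' Signed and absolute polygon area
#'
#' Shoelace formula; vertices in either orientation, closing edge implicit.
#'
#' @param poly Two-column matrix of (x, y) vertices.
#' @return Absolute area in squared input units.
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L) stop2("a polygon must be a two-column (x, y) matrix")
  storage.mode(poly) <- "double"
  if (anyNA(poly)) stop2("polygon contains missing coordinates")
  # drop an explicit closing vertex
  n <- nrow(poly)
  if (n >= 2L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of the
#' rectangle. Exact for simple polygons against a convex window.
#'
#' @param poly Two-column (x, y) vertex matrix.
#' @param xlim,ylim Rectangle extents, length-2 numeric.
#' @return Clipped vertex matrix (possibly 0 rows when disjoint).
#' @export
clip_polygon_rect <- function(poly, xlim, ylim) {
  poly <- as_polygon(poly)
  clips <- list(
    function(p) p[, 1L] >= xlim[1L], function(p) p[, 1L] <= xlim[2L],
    function(p) p[, 2L] >= ylim[1L], function(p) p[, 2L] <= ylim[2L]
  )
  lines <- list(
    c(1L, xlim[1L]), c(1L, xlim[2L]), c(2L, ylim[1L]), c(2L, ylim[2L])
  )
  out <- poly
  for (k in seq_along(clips)) {
    if (nrow(out) == 0L) break
    inside <- clips[[k]](out)
    axis <- lines[[k]][1L]; level <- lines[[k]][2L]
    n <- nrow(out)
    nxt <- c(seq_len(n)[-1L], 1L)
    keep <- vector("list", n)
    for (i in seq_len(n)) {
      j <- nxt[i]
      a <- out[i, ]; b <- out[j, ]
      pts <- NULL
      if (inside[i]) pts <- rbind(pts, a)
      if (inside[i] != inside[j]) {
        # intersection of segment a-b with the clip line
        t <- (level - a[axis]) / (b[axis] - a[axis])
        pts <- rbind(pts, a + t * (b - a))
      }
      keep[[i]] <- pts
    }
    out <- do.call(rbind, keep)
    if (is.null(out)) out <- matrix(numeric(0), ncol = 2L)
  }
  unname(out)
}

#' Area of intersection between a polygon and a rectangle
#'
#' @inheritParams clip_polygon_rect
#' @return Intersection area.
#' @export
polygon_rect_intersection_area <- function(poly, xlim, ylim) {
  # bounding-box prefilter: disjoint boxes cannot intersect
  poly <- as_polygon(poly)
  if (nrow(poly) < 3L) return(0)
  if (max(poly[, 1L]) <= xlim[1L] || min(poly[, 1L]) >= xlim[2L] ||
      max(poly[, 2L]) <= ylim[1L] || min(poly[, 2L]) >= ylim[2L]) return(0)
  polygon_area(clip_polygon_rect(poly, xlim, ylim))
}

#' Test points against a polygon (even-odd rule)
#'
#' Vectorized ray-casting membership test, used by the rasterization
#' cross-checks of the exact clipped areas.
#'
#' @param x,y Point coordinates.
#' @param poly Two-column vertex matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Check a polygon is simple (non-self-intersecting)
#'
#' Brute-force pairwise proper-intersection test over edges; adequate for
#' the small outcrop polygons handled here.
#'
#' @param poly Two-column vertex matrix.
#' @return `TRUE` when simple.
#' @export
polygon_is_simple <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  a <- poly
  b <- poly[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip edges sharing a vertex
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_properly_intersect(a[i, ], b[i, ], a[j, ], b[j, ]))
        return(FALSE)
    }
  }
  TRUE
}

segments_properly_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

cross2 <- function(u, v) u[1L] * v[2L] - u[2L] * v[1L]

# Raster estimate of the rock fraction of a rectangle under a set of
# polygons, at a given sampling step (cell-center sampling). Serves as the
# independent oracle for the exact clipping path.
raster_cover_fraction <- function(polys, xlim, ylim, step = 0.1) {
  xs <- seq(xlim[1L] + step / 2, xlim[2L] - step / 2, by = step)
  ys <- seq(ylim[1L] + step / 2, ylim[2L] - step / 2, by = step)
  g <- expand.grid(x = xs, y = ys)
  hit <- rep(FALSE, nrow(g))
  for (p in polys) {
    p <- as_polygon(p)
    if (nrow(p) < 3L) next
    sub <- !hit &
      g$x >= min(p[, 1L]) & g$x <= max(p[, 1L]) &
      g$y >= min(p[, 2L]) & g$y <= max(p[, 2L])
    if (!any(sub)) next
    hit[sub] <- points_in_polygon(g$x[sub], g$y[sub], p)
  }
  mean(hit)
}
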