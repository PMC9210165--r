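#' Construct and validate a stem map
#'
#' A stem map is one record per standing live tree: plot-local coordinates
#' (m), species label, DBH (cm, census threshold 1 cm), total height (m)
#' and life form. Validation enforces unique ids, unique coordinates,
#' in-plot positions and the DBH threshold.
#'
#' @param stems data.frame with columns `id, x, y, species, dbh_cm, th_m,
#'   lifeform`.
#' @param plot_width,plot_height Plot extent, m.
#' @return A `stem_map` data.frame with the plot extent as attributes.
#' @export
as_stem_map <- function(stems, plot_width, plot_height) {
  required <- c("id", "x", "y", "species", "dbh_cm", "th_m", "lifeform")
  miss <- setdiff(required, names(stems))
  if (length(miss) > 0L)
    stop2("stem map is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(stems$id)) {
    dup <- unique(stems$id[duplicated(stems$id)])
    stop2("duplicate stem id(s): ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (anyDuplicated(stems[, c("x", "y")]))
    stop2("stem map contains coincident coordinates")
  out <- stems$x < 0 | stems$x > plot_width |
    stems$y < 0 | stems$y > plot_height
  if (any(out))
    stop2("stem(s) outside the plot rectangle: ids ",
          paste(utils::head(stems$id[out], 5L), collapse = ", "))
  if (any(stems$dbh_cm < 1)) {
    rows <- which(stems$dbh_cm < 1)
    stop2("DBH below the 1 cm census threshold in row(s) ",
          paste(utils::head(rows, 5L), collapse = ", "))
  }
  if (!all(stems$lifeform %in% c("tree", "shrub")))
    stop2("lifeform must be 'tree' or 'shrub'")
  structure(as.data.frame(stems, stringsAsFactors = FALSE),
            plot_width = plot_width, plot_height = plot_height,
            class = c("stem_map", "data.frame"))
}

#' @export
print.stem_map <- function(x, ...) {
  cat(sprintf("Stem map: %d stems, %d species, plot %g x %g m\n",
              nrow(x), length(unique(x$species)),
              attr(x, "plot_width"), attr(x, "plot_height")))
  cat(sprintf("  DBH %.1f-%.1f cm; %d trees, %d shrubs\n",
              min(x$dbh_cm), max(x$dbh_cm),
              sum(x$lifeform == "tree"), sum(x$lifeform == "shrub")))
  invisible(x)
}

#' Construct a substrate map from rock polygons
#'
#' Polygons are validated (simple, i.e. non-self-intersecting), clipped to
#' the plot rectangle, and assumed mutually disjoint (digitized outcrop
#' patches do not overlap), so the total rock area is the sum of the
#' clipped polygon areas; soil is the complement.
#'
#' @param polygons List of two-column (x, y) vertex matrices, plot-local m.
#' @param plot_width,plot_height Plot extent, m.
#' @return A list of class `substrate_map`: `polygons`, `plot_width`,
#'   `plot_height`, `rock_area`, `soil_area` (m2).
#' @export
substrate_map <- function(polygons, plot_width, plot_height) {
  polygons <- lapply(polygons, as_polygon)
  for (k in seq_along(polygons)) {
    if (!polygon_is_simple(polygons[[k]]))
      stop2("substrate polygon ", k, " is invalid (self-intersecting)")
  }
  polygons <- lapply(polygons, clip_polygon_rect,
                     xlim = c(0, plot_width), ylim = c(0, plot_height))
  polygons <- polygons[vapply(polygons, nrow, 0L) >= 3L]
  rock <- sum(vapply(polygons, polygon_area, 0))
  structure(list(polygons = polygons,
                 plot_width = plot_width, plot_height = plot_height,
                 rock_area = rock,
                 soil_area = plot_width * plot_height - rock),
            class = "substrate_map")
}

#' @export
print.substrate_map <- function(x, ...) {
  cat(sprintf("Substrate map: %d rock polygons; rock %.0f m2, soil %.0f m2 (%.1f%% rock)\n",
              length(x$polygons), x$rock_area, x$soil_area,
              100 * x$rock_area / (x$rock_area + x$soil_area)))
  invisible(x)
}
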