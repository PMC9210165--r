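# Species diversity indices at plot, site-type and quadrat scales.
# Natural logarithms are used throughout, so Pielou evenness is exactly
# H' / ln S.

#' Species abundance counts by group
#'
#' Tallies stems into species-abundance vectors at one of three scales:
#' the whole plot, rock vs soil site types (a stem inherits the site type
#' of its containing quadrat), or individual quadrats.
#'
#' @param stems A `stem_map`.
#' @param grouping `"plot"`, `"site_type"` or `"quadrat"`.
#' @param grid A `quadrat_grid`; required unless `grouping = "plot"`.
#' @param terrain A classified `terrain_table`; required for
#'   `grouping = "site_type"`.
#' @return A list of `community_counts` objects, each with `group`,
#'   `counts` (named integer vector), `N` (total stems) and `S`
#'   (richness).
#' @export
community_counts <- function(stems, grouping = c("plot", "site_type", "quadrat"),
                             grid = NULL, terrain = NULL) {
  grouping <- match.arg(grouping)
  group_of <- switch(grouping,
    plot = rep("plot", nrow(stems)),
    quadrat = {
      if (is.null(grid)) stop2("quadrat grouping requires a quadrat grid")
      as.character(assign_quadrat(grid, stems$x, stems$y))
    },
    site_type = {
      if (is.null(grid) || is.null(terrain))
        stop2("site_type grouping requires a grid and a classified terrain table")
      cell <- assign_quadrat(grid, stems$x, stems$y)
      as.character(terrain$site_type[match(cell, terrain$cell)])
    })
  lapply(split(stems$species, group_of), function(sp) {
    counts <- table(sp)
    structure(list(group = NULL, counts = stats::setNames(as.integer(counts),
                                                          names(counts)),
                   N = length(sp), S = sum(counts > 0L)),
              class = "community_counts")
  }) -> groups
  for (g in names(groups)) groups[[g]]$group <- g
  groups
}

as_counts <- function(counts) {
  if (inherits(counts, "community_counts")) counts <- counts$counts
  counts <- counts[counts > 0]
  if (any(counts < 0)) stop2("abundances must be non-negative")
  counts
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum(p_i * ln p_i)` over species relative abundances
#' `p_i = n_i / N`, natural logarithms. Zero-abundance species are
#' ignored.
#'
#' @param counts A `community_counts` object or a numeric abundance
#'   vector.
#' @return H' in nats, in `[0, ln S]`.
#' @export
#' @examples
#' shannon_index(c(25, 25, 25, 25))  # log(4)
shannon_index <- function(counts) {
  counts <- as_counts(counts)
  N <- sum(counts)
  if (N == 0) stop2("cannot compute H' of an empty community")
  p <- counts / N
  -sum(p * log(p))
}

#' Pielou evenness index
#'
#' `E_H = H' / ln S` with natural logarithms throughout, so equal
#' abundances give exactly 1. Undefined for single-species communities
#' (`ln S = 0`); these return `NA` and are excluded from summaries.
#'
#' @inheritParams shannon_index
#' @return E_H in (0, 1], or `NA` when S < 2.
#' @export
pielou_evenness <- function(counts) {
  counts <- as_counts(counts)
  S <- length(counts)
  if (S < 2L) return(NA_real_)
  shannon_index(counts) / log(S)
}

#' Stem density per hectare
#'
#' `count * 10000 / area_m2`. The integer report follows the convention of
#' truncation toward zero; the raw value is retained alongside it.
#'
#' @param count Number of stems.
#' @param area_m2 Reference area, m2.
#' @return List with `per_ha` (raw) and `per_ha_int` (truncated).
#' @export
#' @examples
#' density_per_hectare(1427, 6224)$per_ha_int  # 2292
density_per_hectare <- function(count, area_m2) {
  if (!is.numeric(area_m2) || area_m2 <= 0) stop2("area must be positive")
  d <- count * 10000 / area_m2
  list(per_ha = d, per_ha_int = trunc(d))
}

#' Diversity table at quadrat and site-type scales
#'
#' Per-quadrat richness, abundance, H' and E_H, plus site-type aggregates
#' under the two area conventions in use for karst plots: the actual
#' digitized substrate area, and the area implied by quadrat counts (rock
#' quadrats x cell area). Densities are reported under both.
#'
#' @param stems A `stem_map`.
#' @param grid A `quadrat_grid`.
#' @param terrain A classified `terrain_table`.
#' @param substrate A `substrate_map` supplying the actual substrate
#'   areas; when `NULL` only the quadrat convention is reported.
#' @return List with `quadrat` (per-quadrat data.frame: `cell`,
#'   `site_type`, `N`, `R`, `shannon`, `evenness`) and `site_type`
#'   (aggregate data.frame with both density conventions).
#' @export
diversity_table <- function(stems, grid, terrain, substrate = NULL) {
  cell <- assign_quadrat(grid, stems$x, stems$y)
  per_q <- lapply(split(stems$species, cell), function(sp) {
    counts <- table(sp)
    c(N = length(sp), R = sum(counts > 0L),
      shannon = shannon_index(as.integer(counts)),
      evenness = pielou_evenness(as.integer(counts)))
  })
  qids <- as.integer(names(per_q))
  qdf <- data.frame(cell = terrain$cell,
                    site_type = terrain$site_type,
                    N = 0L, R = 0L, shannon = NA_real_, evenness = NA_real_)
  m <- match(qids, qdf$cell)
  qdf$N[m] <- vapply(per_q, `[[`, 0, "N")
  qdf$R[m] <- vapply(per_q, `[[`, 0, "R")
  qdf$shannon[m] <- vapply(per_q, `[[`, 0, "shannon")
  qdf$evenness[m] <- vapply(per_q, `[[`, 0, "evenness")

  totals <- site_type_totals(terrain)
  site <- terrain$site_type[match(cell, terrain$cell)]
  sdf <- do.call(rbind, lapply(levels(site), function(st) {
    sp <- stems$species[site == st]
    counts <- table(sp)
    area_q <- if (st == "rock") totals$rock_quadrat_area else totals$soil_quadrat_area
    area_s <- if (is.null(substrate)) NA_real_
              else if (st == "rock") substrate$rock_area else substrate$soil_area
    dq <- if (area_q > 0) density_per_hectare(length(sp), area_q) else
      list(per_ha = NA_real_, per_ha_int = NA_real_)
    ds <- if (!is.na(area_s) && area_s > 0) density_per_hectare(length(sp), area_s) else
      list(per_ha = NA_real_, per_ha_int = NA_real_)
    data.frame(site_type = st, N = length(sp), R = sum(counts > 0L),
               shannon = if (length(sp)) shannon_index(as.integer(counts)) else NA_real_,
               evenness = if (length(sp)) pielou_evenness(as.integer(counts)) else NA_real_,
               quadrat_area_m2 = area_q, substrate_area_m2 = area_s,
               density_quadrat_ha = dq$per_ha_int,
               density_substrate_ha = ds$per_ha_int,
               stringsAsFactors = FALSE)
  }))
  list(quadrat = qdf, site_type = sdf)
}
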