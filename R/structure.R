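# Nearest-neighbour stand spatial structure parameters (SSSPs). Each
# reference tree and its four nearest neighbours yield three indices,
# each quantized to {0, 0.25, 0.5, 0.75, 1}:
#   W (uniform angle index)  - relative spatial positioning: the fraction
#       of the four circular gaps between consecutive neighbour bearings
#       smaller than the standard angle alpha0; ~0.5 under randomness.
#   U (dominance)            - size differentiation: the fraction of
#       neighbours strictly larger than the reference, so U = 1 means the
#       reference is fully suppressed.
#   M (mingling)             - species mixture: the fraction of
#       neighbours of a different species.
# Neighbour search is stand-wide (it crosses quadrat boundaries); edge
# handling flags stems within a boundary buffer.

#' k nearest neighbours of every stem
#'
#' Exact Euclidean k-nearest-neighbour search; distance ties are broken
#' by stem id ((distance, id) lexicographic order), so results are fully
#' deterministic.
#'
#' @param stems A `stem_map` (or data.frame with `id`, `x`, `y`).
#' @param k Number of neighbours (default 4).
#' @return List with `id` (reference ids), `nn_id` (n x k id matrix),
#'   `nn_dist` (n x k distances, ascending within rows).
#' @export
knn_neighborhoods <- function(stems, k = 4L) {
  n <- nrow(stems)
  if (n <= k) stop2("need more than k = ", k, " stems, got ", n)
  x <- stems$x; y <- stems$y; id <- stems$id
  nn_id <- matrix(id[1L], n, k)
  nn_dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    ord <- order(d, id)[seq_len(k)]
    nn_id[i, ] <- id[ord]
    nn_dist[i, ] <- d[ord]
  }
  if (any(nn_dist == 0))
    stop2("coincident stems: zero nearest-neighbour distance")
  list(id = id, nn_id = nn_id, nn_dist = nn_dist)
}

#' Uniform angle index of one neighbourhood
#'
#' Sorts the four neighbour bearings, forms the four circular gaps between
#' consecutive directions (they sum to 360 degrees), and scores each gap
#' strictly smaller than the standard angle `alpha0`; W is the mean score.
#' Ties (gap exactly alpha0) score 0. A zero gap — two neighbours at the
#' same bearing — counts as smaller.
#'
#' @param reference Length-2 (x, y) of the reference stem.
#' @param neighbours 4 x 2 matrix of neighbour coordinates.
#' @param alpha0 Standard angle, degrees; 72 = 360 / (k + 1) for k = 4.
#' @return W in {0, 0.25, 0.5, 0.75, 1}.
#' @export
#' @examples
#' # four neighbours due N, E, S, W: all gaps 90 >= 72, so W = 0
#' uniform_angle_index(c(0, 0), rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0)))
uniform_angle_index <- function(reference, neighbours, alpha0 = 72) {
  neighbours <- as.matrix(neighbours)
  dx <- neighbours[, 1L] - reference[1L]
  dy <- neighbours[, 2L] - reference[2L]
  if (any(dx == 0 & dy == 0))
    stop2("neighbour coincides with the reference stem; azimuth undefined")
  az <- sort(azimuth_deg(dx, dy))
  gaps <- diff(c(az, az[1L] + 360))
  mean(gaps < alpha0)
}

#' Dominance of one neighbourhood
#'
#' Fraction of the four neighbours strictly larger than the reference
#' tree; equal sizes score 0. With DBH as the size variable, U = 1 means
#' all four neighbours are thicker than the reference.
#'
#' @param reference_size Size of the reference tree (DBH cm by default
#'   convention).
#' @param neighbour_sizes Sizes of the 4 neighbours.
#' @return U in {0, 0.25, 0.5, 0.75, 1}.
#' @export
dominance <- function(reference_size, neighbour_sizes) {
  if (any(c(reference_size, neighbour_sizes) <= 0))
    stop2("sizes must be positive")
  mean(neighbour_sizes > reference_size)
}

#' Mingling of one neighbourhood
#'
#' Fraction of the four neighbours belonging to a species different from
#' the reference tree.
#'
#' @param reference_species Species label of the reference tree.
#' @param neighbour_species Labels of the 4 neighbours.
#' @return M in {0, 0.25, 0.5, 0.75, 1}.
#' @export
mingling <- function(reference_species, neighbour_species) {
  if (!nzchar(reference_species) || !all(nzchar(neighbour_species)))
    stop2("species labels must be non-empty")
  mean(neighbour_species != reference_species)
}

#' Per-tree stand spatial structure parameters
#'
#' Computes W, U and M for every stem from its four nearest neighbours.
#' Neighbour search always uses the full stem map; stems within
#' `buffer_m` of any plot boundary are flagged as edge stems (their
#' neighbourhoods look outside the mapped window) and, under
#' `edge_policy = "exclude_buffer"`, excluded from summary means while
#' still serving as neighbours of interior stems.
#'
#' @param stems A `stem_map`.
#' @param grid Optional `quadrat_grid`; when supplied (with `terrain`)
#'   each record carries its quadrat and site type.
#' @param terrain Optional classified `terrain_table`.
#' @param k Neighbours per reference tree (default 4).
#' @param alpha0 Standard angle for W, degrees (default 72).
#' @param buffer_m Edge buffer width, m (default 5).
#' @param size_var Size variable for dominance: `"dbh"`, `"th"` or
#'   `"ba"`.
#' @return An `sssp_table` data.frame, one row per stem: coordinates,
#'   marks, `W`, `U`, `M`, `edge_flag`, neighbour ids and distances.
#' @export
sssp_table <- function(stems, grid = NULL, terrain = NULL, k = 4L,
                       alpha0 = 72, buffer_m = 5,
                       size_var = c("dbh", "th", "ba")) {
  size_var <- match.arg(size_var)
  nn <- knn_neighborhoods(stems, k = k)
  n <- nrow(stems)
  idx <- match(as.vector(nn$nn_id), stems$id)
  nb_x <- matrix(stems$x[idx], n, k)
  nb_y <- matrix(stems$y[idx], n, k)
  size <- switch(size_var,
    dbh = stems$dbh_cm, th = stems$th_m, ba = basal_area(stems$dbh_cm))
  nb_size <- matrix(size[idx], n, k)
  nb_sp <- matrix(stems$species[idx], n, k)

  W <- U <- M <- numeric(n)
  for (i in seq_len(n)) {
    W[i] <- uniform_angle_index(c(stems$x[i], stems$y[i]),
                                cbind(nb_x[i, ], nb_y[i, ]), alpha0 = alpha0)
    U[i] <- dominance(size[i], nb_size[i, ])
    M[i] <- mingling(stems$species[i], nb_sp[i, ])
  }
  pw <- attr(stems, "plot_width") %||% max(stems$x)
  ph <- attr(stems, "plot_height") %||% max(stems$y)
  edge <- stems$x < buffer_m | stems$x > pw - buffer_m |
          stems$y < buffer_m | stems$y > ph - buffer_m

  out <- data.frame(id = stems$id, x = stems$x, y = stems$y,
                    species = stems$species, lifeform = stems$lifeform,
                    dbh_cm = stems$dbh_cm, th_m = stems$th_m,
                    W = W, U = U, M = M, edge_flag = edge,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    out[[paste0("nn", j, "_id")]] <- nn$nn_id[, j]
    out[[paste0("nn", j, "_dist")]] <- nn$nn_dist[, j]
  }
  if (!is.null(grid)) {
    out$cell <- assign_quadrat(grid, stems$x, stems$y)
    if (!is.null(terrain))
      out$site_type <- terrain$site_type[match(out$cell, terrain$cell)]
  }
  structure(out, alpha0 = alpha0, buffer_m = buffer_m, size_var = size_var,
            class = c("sssp_table", "data.frame"))
}

#' Univariate distribution of a quantized structure parameter
#'
#' Relative frequencies of the five admissible values
#' {0, 0.25, 0.5, 0.75, 1}.
#'
#' @param values Quantized parameter values.
#' @return Named numeric vector of 5 relative frequencies summing to 1.
#' @export
univariate_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop2("empty input: no parameter values")
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  if (!all(values %in% levels))
    stop2("values must be quantized to {0, 0.25, 0.5, 0.75, 1}")
  freq <- vapply(levels, function(v) mean(values == v), 0)
  stats::setNames(freq, format(levels))
}

#' Group summaries of structure parameters
#'
#' Mean W, U and M by site type crossed with life form (plus "all"), per
#' quadrat means, and the univariate distribution tables per group. Under
#' `edge_policy = "exclude_buffer"` (the default) edge-flagged stems are
#' excluded from all summaries; their neighbourhoods extend beyond the
#' mapped window.
#'
#' @param records An `sssp_table`.
#' @param edge_policy `"exclude_buffer"` or `"include"`.
#' @return List with `groups` (means + n per group), `quadrat` (per-cell
#'   means, when the records carry cells) and `distributions` (long-form
#'   frequencies per group and parameter).
#' @export
group_summaries <- function(records,
                            edge_policy = c("exclude_buffer", "include")) {
  edge_policy <- match.arg(edge_policy)
  r <- records
  if (edge_policy == "exclude_buffer") r <- r[!r$edge_flag, , drop = FALSE]

  site <- if ("site_type" %in% names(r)) as.character(r$site_type)
          else rep("all", nrow(r))
  combos <- expand.grid(site_type = unique(c("all", site)),
                        lifeform = c("all", "tree", "shrub"),
                        stringsAsFactors = FALSE)
  summarize <- function(sub) {
    if (nrow(sub) == 0L)
      return(c(n = 0, W = NA_real_, U = NA_real_, M = NA_real_))
    c(n = nrow(sub), W = mean(sub$W), U = mean(sub$U), M = mean(sub$M))
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    st <- combos$site_type[i]; lf <- combos$lifeform[i]
    sub <- r[(st == "all" | site == st) &
             (lf == "all" | r$lifeform == lf), , drop = FALSE]
    cbind(combos[i, ], as.data.frame(as.list(summarize(sub))))
  })
  groups <- do.call(rbind, rows)

  quadrat <- NULL
  if ("cell" %in% names(r) && nrow(r) > 0L) {
    agg <- stats::aggregate(r[, c("W", "U", "M")], by = list(cell = r$cell),
                            FUN = mean)
    agg$n <- as.vector(table(r$cell)[as.character(agg$cell)])
    quadrat <- agg
  }

  dist_rows <- lapply(seq_len(nrow(combos)), function(i) {
    st <- combos$site_type[i]; lf <- combos$lifeform[i]
    sub <- r[(st == "all" | site == st) &
             (lf == "all" | r$lifeform == lf), , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    do.call(rbind, lapply(c("W", "U", "M"), function(par) {
      f <- univariate_distribution(sub[[par]])
      data.frame(site_type = st, lifeform = lf, parameter = par,
                 value = c(0, 0.25, 0.5, 0.75, 1), frequency = unname(f),
                 stringsAsFactors = FALSE)
    }))
  })
  distributions <- do.call(rbind, dist_rows)

  list(groups = groups, quadrat = quadrat, distributions = distributions)
}
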