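# Tree-size metrics and the rock-vs-soil statistical comparisons:
# Kruskal-Wallis tests on quadrat-level values, two-sample
# Kolmogorov-Smirnov tests on structure-parameter distributions, and
# per-site-type linear trends against topographic variables. No multiple-
# testing correction is applied (none is part of the analysis design).

#' Basal area from DBH
#'
#' Cross-sectional stem area at breast height:
#' `BA = pi * (DBH / 200)^2` m2 with DBH in cm.
#'
#' @param dbh_cm DBH in cm, at or above the 1 cm census threshold.
#' @return Basal area, m2.
#' @export
#' @examples
#' basal_area(20)  # ~0.0314 m2
basal_area <- function(dbh_cm) {
  if (any(dbh_cm < 1))
    stop2("DBH below the 1 cm census threshold")
  pi * (dbh_cm / 200)^2
}

#' Significance band of a p value
#'
#' Three-way banding at 0.05 and 0.01; boundary values fall in the less
#' significant band.
#'
#' @param p p value in [0, 1].
#' @return `"ns"`, `"significant"` or `"highly_significant"`.
#' @export
significance_band <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop2("p must lie in [0, 1]")
  if (p >= 0.05) "ns" else if (p >= 0.01) "significant" else "highly_significant"
}

test_result <- function(name, statistic, p, n_per_group) {
  structure(list(test = name, statistic = unname(statistic),
                 p_value = unname(p), n = n_per_group,
                 band = significance_band(unname(p))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s), n = %s\n",
              x$test, x$statistic, x$p_value, x$band,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Per-quadrat tree-size metrics
#'
#' Arithmetic means of DBH, TH and per-tree basal area over the stems of
#' each quadrat (plus total basal area), with site-type aggregates. Empty
#' quadrats get `NA` sentinel rows, which downstream tests drop.
#'
#' @param stems A `stem_map`.
#' @param grid A `quadrat_grid`.
#' @param terrain A classified `terrain_table`.
#' @return List with `quadrat` (per-cell `n`, `mean_dbh`, `mean_th`,
#'   `mean_ba`, `total_ba`, `site_type`) and `site_type` aggregates over
#'   stems.
#' @export
quadrat_size_metrics <- function(stems, grid, terrain) {
  cell <- assign_quadrat(grid, stems$x, stems$y)
  ba <- basal_area(stems$dbh_cm)
  qdf <- data.frame(cell = terrain$cell, site_type = terrain$site_type,
                    n = 0L, mean_dbh = NA_real_, mean_th = NA_real_,
                    mean_ba = NA_real_, total_ba = NA_real_)
  for (cl in split(seq_len(nrow(stems)), cell)) {
    k <- match(cell[cl[1L]], qdf$cell)
    qdf$n[k] <- length(cl)
    qdf$mean_dbh[k] <- mean(stems$dbh_cm[cl])
    qdf$mean_th[k] <- mean(stems$th_m[cl])
    qdf$mean_ba[k] <- mean(ba[cl])
    qdf$total_ba[k] <- sum(ba[cl])
  }
  site <- terrain$site_type[match(cell, terrain$cell)]
  sdf <- do.call(rbind, lapply(levels(site), function(st) {
    sel <- site == st
    data.frame(site_type = st, n = sum(sel),
               mean_dbh = if (any(sel)) mean(stems$dbh_cm[sel]) else NA_real_,
               mean_th = if (any(sel)) mean(stems$th_m[sel]) else NA_real_,
               mean_ba = if (any(sel)) mean(ba[sel]) else NA_real_,
               total_ba = sum(ba[sel]),
               stringsAsFactors = FALSE)
  }))
  list(quadrat = qdf, site_type = sdf)
}

#' Kruskal-Wallis rank-sum comparison of groups
#'
#' Rank-based H statistic with tie correction and a chi-square p value
#' (df = groups - 1), as in `stats::kruskal.test`, plus the three-way
#' significance band.
#'
#' @param groups List of (at least 2) numeric samples, e.g. quadrat-level
#'   metric values on rock and on soil. `NA` sentinel values are dropped.
#' @return A `test_result`.
#' @export
#' @examples
#' kruskal_wallis(list(rock = c(1, 2, 3), soil = c(4, 5, 6)))
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop2("need a list of at least two groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop2("a group is empty after dropping sentinels")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    # all observations identical: the tie correction degenerates to 0/0;
    # report no evidence of a difference
    return(test_result("Kruskal-Wallis", c(statistic = 0), 1, sizes))
  }
  g <- factor(rep(seq_along(groups), sizes))
  kt <- stats::kruskal.test(x, g)
  test_result("Kruskal-Wallis", kt$statistic, kt$p.value, sizes)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic p value. Quantized
#' structure-parameter inputs are heavily tied; the asymptotic p value is
#' then conservative/approximate (the tie warning from the underlying
#' test is expected and suppressed), while D itself is exact.
#'
#' @param x,y Numeric samples.
#' @return A `test_result`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop2("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  test_result("Kolmogorov-Smirnov", kt$statistic, kt$p.value,
              c(length(x), length(y)))
}

#' Linear trend of a metric against a topographic variable
#'
#' Ordinary least squares per group (site type): slope, intercept, R2 and
#' the slope p value. Rows with missing values (sentinels; undefined
#' aspect) are dropped. Raw aspect degrees can be regressed directly
#' (matching the field convention of plotting metrics against aspect
#' 140-340), or decomposed into sine and cosine components with
#' `aspect_components = TRUE` to avoid the 0/360 wrap.
#'
#' @param x Topographic variable (per quadrat).
#' @param y Metric (per quadrat).
#' @param group Optional grouping factor (e.g. site type); `NULL` fits a
#'   single line.
#' @param aspect_components Treat `x` as a bearing and regress on
#'   `sin(x)` and `cos(x)` instead of raw degrees.
#' @return data.frame: one row per group with `n`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `band` (slope/intercept are `NA` under the
#'   two-component aspect fit, which reports fit-level R2 and p).
#' @export
linear_trend <- function(x, y, group = NULL, aspect_components = FALSE) {
  if (is.null(group)) group <- rep("all", length(x))
  keep <- !is.na(x) & !is.na(y) & !is.na(group)
  x <- x[keep]; y <- y[keep]; group <- factor(group[keep])
  rows <- lapply(levels(group), function(gl) {
    xs <- x[group == gl]; ys <- y[group == gl]
    if (length(xs) < 3L)
      stop2("need at least 3 points per group, got ", length(xs),
            " in group '", gl, "'")
    if (stats::var(xs) == 0)
      stop2("zero variance in x within group '", gl, "'")
    if (aspect_components) {
      rad <- xs * pi / 180
      fit <- stats::lm(ys ~ sin(rad) + cos(rad))
      s <- summary(fit)
      pf <- stats::pf(s$fstatistic[1L], s$fstatistic[2L], s$fstatistic[3L],
                      lower.tail = FALSE)
      data.frame(group = gl, n = length(xs), slope = NA_real_,
                 intercept = stats::coef(fit)[[1L]],
                 r_squared = s$r.squared, p_value = unname(pf),
                 band = significance_band(unname(pf)),
                 stringsAsFactors = FALSE)
    } else if (stats::var(ys) == 0) {
      # constant response: flat line, no variance explained
      data.frame(group = gl, n = length(xs), slope = 0, intercept = ys[1L],
                 r_squared = 0, p_value = 1, band = "ns",
                 stringsAsFactors = FALSE)
    } else {
      fit <- stats::lm(ys ~ xs)
      s <- summary(fit)
      p <- if (s$sigma == 0) {  # exact fit: slope p degenerates
        if (abs(stats::coef(fit)[[2L]]) > 0) 0 else 1
      } else s$coefficients[2L, 4L]
      data.frame(group = gl, n = length(xs),
                 slope = stats::coef(fit)[[2L]],
                 intercept = stats::coef(fit)[[1L]],
                 r_squared = s$r.squared, p_value = p,
                 band = significance_band(p),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Assemble ordination-ready matrices
#'
#' Builds the three aligned per-quadrat matrices that multivariate
#' ordinations (RDA/NMDS) consume — fitting the ordinations themselves is
#' deliberately out of scope:
#' \itemize{
#'   \item response: diversity (R, N, H', E_H), structure (mean W, U, M)
#'     and size (mean DBH, TH, BA) per quadrat,
#'   \item explanatory: rock and soil area within the quadrat, elevation,
#'     convexity, aspect, slope,
#'   \item abundance: species-by-quadrat counts.
#' }
#' Quadrats with sentinel values (no stems, or undefined evenness/aspect)
#' are dropped from all three, with a notice.
#'
#' @param stems A `stem_map`.
#' @param grid A `quadrat_grid`.
#' @param terrain A classified `terrain_table`.
#' @param records Optional `sssp_table`; computed if missing.
#' @return List of aligned data.frames `response`, `explanatory`,
#'   `abundance` (rows keyed by `cell`).
#' @export
ordination_export <- function(stems, grid, terrain, records = NULL) {
  if (is.null(records)) records <- sssp_table(stems, grid, terrain)
  div <- diversity_table(stems, grid, terrain)$quadrat
  siz <- quadrat_size_metrics(stems, grid, terrain)$quadrat
  str <- group_summaries(records, edge_policy = "include")$quadrat

  cellv <- terrain$cell
  response <- data.frame(
    cell = cellv,
    R = div$R[match(cellv, div$cell)],
    N = div$N[match(cellv, div$cell)],
    shannon = div$shannon[match(cellv, div$cell)],
    evenness = div$evenness[match(cellv, div$cell)],
    W = str$W[match(cellv, str$cell)],
    U = str$U[match(cellv, str$cell)],
    M = str$M[match(cellv, str$cell)],
    mean_dbh = siz$mean_dbh[match(cellv, siz$cell)],
    mean_th = siz$mean_th[match(cellv, siz$cell)],
    mean_ba = siz$mean_ba[match(cellv, siz$cell)]
  )
  cell_area <- grid$cell_size^2
  explanatory <- data.frame(
    cell = cellv,
    rock_area = terrain$rock_fraction * cell_area,
    soil_area = (1 - terrain$rock_fraction) * cell_area,
    elevation = terrain$elevation,
    convexity = terrain$convexity,
    aspect = terrain$aspect,
    slope = terrain$slope
  )
  cell <- assign_quadrat(grid, stems$x, stems$y)
  abundance <- as.data.frame.matrix(table(cell, stems$species))
  abundance <- data.frame(cell = as.integer(rownames(abundance)), abundance,
                          check.names = FALSE)
  abundance <- abundance[match(cellv, abundance$cell), , drop = FALSE]
  abundance$cell <- cellv
  abundance[is.na(abundance)] <- 0L
  rownames(abundance) <- NULL

  keep <- stats::complete.cases(response) & stats::complete.cases(explanatory)
  if (any(!keep))
    message(sum(!keep), " quadrat(s) dropped from the ordination export ",
            "(empty or with undefined evenness/aspect)")
  list(response = response[keep, , drop = FALSE],
       explanatory = explanatory[keep, , drop = FALSE],
       abundance = abundance[keep, , drop = FALSE])
}
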