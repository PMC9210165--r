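# Readers and writers for the artifact formats (stem map CSV, substrate
# GeoJSON/WKT, elevation CSV, metric tables) and the end-to-end pipeline.
# CSV dialect: comma-separated, '.' decimal, UTF-8, mandatory header.
# Coordinates are plot-local metres (no CRS); GeoJSON carries the same
# local frame and is documented as non-geographic. Numbers are serialized
# at 9 significant digits so outputs diff reproducibly.

#' Read a stem map CSV
#'
#' Expects columns `id,x,y,species,dbh_cm,th_m,lifeform` and validates
#' the result (unique ids and coordinates, in-plot positions, DBH at or
#' above the 1 cm census threshold).
#'
#' @param path CSV file path.
#' @param plot_width,plot_height Plot extent, m.
#' @return A `stem_map`.
#' @export
read_stem_map <- function(path, plot_width, plot_height) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = "#", encoding = "UTF-8")
  required <- c("id", "x", "y", "species", "dbh_cm", "th_m", "lifeform")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop2("stem map ", path, " is missing column(s): ",
          paste(miss, collapse = ", "))
  for (col in c("x", "y", "dbh_cm", "th_m")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      stop2("non-numeric '", col, "' in row(s) ",
            paste(utils::head(bad, 5L), collapse = ", "))
    df[[col]] <- v
  }
  as_stem_map(df[required], plot_width, plot_height)
}

#' Write a stem map CSV
#'
#' @param stems A `stem_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stem_map <- function(stems, path) {
  df <- data.frame(id = stems$id,
                   x = format_num(stems$x), y = format_num(stems$y),
                   species = stems$species,
                   dbh_cm = format_num(stems$dbh_cm),
                   th_m = format_num(stems$th_m),
                   lifeform = stems$lifeform)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a substrate map (GeoJSON or WKT)
#'
#' GeoJSON: a FeatureCollection of Polygons with property
#' `substrate = "rock"` in plot-local metres. WKT: one `POLYGON (...)`
#' per line. Polygons are validated and clipped to the plot.
#'
#' @param path File path; format inferred from the `.geojson`/`.json` vs
#'   `.wkt`/`.txt` extension unless `format` is given.
#' @param plot_width,plot_height Plot extent, m.
#' @param format `"geojson"` or `"wkt"`.
#' @return A `substrate_map`.
#' @export
read_substrate <- function(path, plot_width, plot_height, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("geojson", "json")) "geojson" else "wkt"
  }
  polys <- if (format == "geojson") {
    gj <- jsonlite::read_json(path)
    if (!identical(gj$type, "FeatureCollection"))
      stop2("expected a GeoJSON FeatureCollection in ", path)
    lapply(seq_along(gj$features), function(k) {
      f <- gj$features[[k]]
      geom <- f$geometry
      if (!identical(geom$type, "Polygon"))
        stop2("feature ", k, " is not a Polygon")
      ring <- geom$coordinates[[1L]]
      m <- do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1L]]), as.numeric(pt[[2L]]))))
      if (anyNA(m)) stop2("invalid geometry in feature ", k)
      m
    })
  } else {
    lines <- trimws(readLines(path, encoding = "UTF-8"))
    lines <- lines[nzchar(lines)]
    lapply(seq_along(lines), function(k) parse_wkt_polygon(lines[k], k))
  }
  for (k in seq_along(polys)) {
    if (!polygon_is_simple(as_polygon(polys[[k]])))
      stop2("substrate polygon in feature ", k,
            " is invalid (self-intersecting)")
  }
  substrate_map(polys, plot_width, plot_height)
}

parse_wkt_polygon <- function(text, k) {
  m <- regmatches(text, regexec("^POLYGON\\s*\\(\\((.*)\\)\\)$", text,
                                ignore.case = TRUE))[[1L]]
  if (length(m) < 2L) stop2("feature ", k, ": cannot parse WKT polygon")
  pairs <- strsplit(strsplit(m[2L], ",")[[1L]], "\\s+")
  coords <- do.call(rbind, lapply(pairs, function(p) {
    p <- p[nzchar(p)]
    as.numeric(p[1:2])
  }))
  if (anyNA(coords)) stop2("feature ", k, ": non-numeric WKT coordinates")
  coords
}

#' Write a substrate map (GeoJSON or WKT)
#'
#' GeoJSON output is a FeatureCollection of rock Polygons (closed rings,
#' property `substrate = "rock"`), serialized at fixed precision so the
#' same map always produces byte-identical files.
#'
#' @param substrate A `substrate_map`.
#' @param path Output path.
#' @param format `"geojson"` or `"wkt"`.
#' @return `path`, invisibly.
#' @export
write_substrate <- function(substrate, path, format = c("geojson", "wkt")) {
  format <- match.arg(format)
  if (format == "wkt") {
    lines <- vapply(substrate$polygons, function(p) {
      p <- rbind(p, p[1L, ])
      sprintf("POLYGON ((%s))",
              paste(sprintf("%s %s", format_num(p[, 1L]), format_num(p[, 2L])),
                    collapse = ", "))
    }, "")
    writeLines(lines, path)
    return(invisible(path))
  }
  feats <- vapply(substrate$polygons, function(p) {
    p <- rbind(p, p[1L, ])
    ring <- paste(sprintf("[%s,%s]", format_num(p[, 1L]), format_num(p[, 2L])),
                  collapse = ",")
    sprintf(paste0('{"type":"Feature","properties":{"substrate":"rock"},',
                   '"geometry":{"type":"Polygon","coordinates":[[%s]]}}'),
            ring)
  }, "")
  json <- sprintf('{"type":"FeatureCollection","features":[%s]}',
                  paste(feats, collapse = ","))
  writeLines(json, path)
  invisible(path)
}

#' Read an elevation field CSV
#'
#' Columns `kind` (vertex/center), `i`, `j` (lattice indices), `x`, `y`,
#' `z`.
#'
#' @param path CSV path.
#' @return An `elevation_field` data.frame.
#' @export
read_elevation_field <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("kind", "i", "j", "x", "y", "z")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop2("elevation file is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$kind %in% c("vertex", "center")))
    stop2("elevation 'kind' must be 'vertex' or 'center'")
  structure(df[required], class = c("elevation_field", "data.frame"))
}

#' Write an elevation field CSV
#'
#' @param elevations An `elevation_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elevation_field <- function(elevations, path) {
  df <- data.frame(kind = elevations$kind, i = elevations$i, j = elevations$j,
                   x = format_num(elevations$x), y = format_num(elevations$y),
                   z = format_num(elevations$z))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_metric_table <- function(df, path, provenance) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", provenance), con)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (col in names(df)[num]) df[[col]] <- format_num(df[[col]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Small stable config fingerprint (polynomial rolling hash over the
# deparsed config, mod 2^26) for provenance headers.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 67108864
  sprintf("%07x", h)
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulation, terrain derivation and site typing,
#' diversity indices, stand spatial structure, tree-size metrics,
#' rock-vs-soil tests, ordination export. All outputs are CSV metric
#' tables stamped with a provenance header (package version, seed, config
#' hash, flags in force); identical config + seed gives byte-identical
#' output.
#'
#' @param config Either a [stand_config()] (simulate) or a list with
#'   elements `stems`, `substrate`, `elevations` (file paths) plus
#'   `plot_width`, `plot_height`.
#' @param out_dir Output directory, created if needed.
#' @param cell_size Quadrat size, m.
#' @param rock_threshold Rock-classification threshold (default 0.5).
#' @param buffer_m Edge buffer for structure summaries, m.
#' @param alpha0 Standard angle for W, degrees.
#' @param edge_policy `"exclude_buffer"` or `"include"`.
#' @return Invisibly, a list with every computed table and the output
#'   paths.
#' @export
run_pipeline <- function(config, out_dir, cell_size = 10,
                         rock_threshold = 0.5, buffer_m = 5, alpha0 = 72,
                         edge_policy = "exclude_buffer") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulate <- inherits(config, "stand_config")
  if (!simulate) {
    needed <- c("stems", "substrate", "elevations", "plot_width", "plot_height")
    miss <- setdiff(needed, names(config))
    if (length(miss) > 0L)
      stop2("pipeline config needs either a stand_config or paths; missing: ",
            paste(miss, collapse = ", "))
  }

  log_lines <- character(0)
  logmsg <- function(stage, text) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, text))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop2("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  }

  if (simulate) {
    scen <- run_stage("simulate", simulate_stand(config, cell_size = cell_size))
    stems <- scen$stems; substrate <- scen$substrate
    elevations <- scen$elevations; grid <- scen$grid
    write_stem_map(stems, file.path(out_dir, "stems.csv"))
    write_substrate(substrate, file.path(out_dir, "substrate.geojson"))
    write_elevation_field(elevations, file.path(out_dir, "elevations.csv"))
    logmsg("simulate", sprintf("n=%d pattern=%s seed=%d", nrow(stems),
                               config$pattern, config$seed))
    prov_seed <- config$seed
  } else {
    stems <- run_stage("read", read_stem_map(config$stems, config$plot_width,
                                             config$plot_height))
    substrate <- run_stage("read", read_substrate(config$substrate,
                                                  config$plot_width,
                                                  config$plot_height))
    elevations <- run_stage("read", read_elevation_field(config$elevations))
    grid <- build_quadrat_grid(config$plot_width, config$plot_height, cell_size)
    prov_seed <- NA_integer_
  }
  prov <- sprintf(
    "karststand %s; seed=%s; config=%s; cell=%g; rock_threshold=%g; buffer=%g; alpha0=%g; edge_policy=%s",
    as.character(utils::packageVersion("karststand")), prov_seed,
    config_hash(config), cell_size, rock_threshold, buffer_m, alpha0,
    edge_policy)

  terrain <- run_stage("terrain",
    terrain_table(grid, elevations, substrate, rock_threshold = rock_threshold))
  logmsg("terrain", sprintf("rock quadrats=%d soil quadrats=%d threshold=%g",
                            site_type_totals(terrain)$n_rock_quadrats,
                            site_type_totals(terrain)$n_soil_quadrats,
                            rock_threshold))
  write_metric_table(as.data.frame(terrain), file.path(out_dir, "terrain.csv"),
                     prov)

  div <- run_stage("diversity", diversity_table(stems, grid, terrain, substrate))
  write_metric_table(div$quadrat, file.path(out_dir, "diversity_quadrat.csv"),
                     prov)
  write_metric_table(div$site_type, file.path(out_dir, "diversity_site.csv"),
                     prov)
  logmsg("diversity", "both area conventions emitted (substrate and quadrat)")

  records <- run_stage("structure",
    sssp_table(stems, grid, terrain, alpha0 = alpha0, buffer_m = buffer_m))
  summaries <- group_summaries(records, edge_policy = edge_policy)
  write_metric_table(as.data.frame(records)[
    c("id", "x", "y", "species", "lifeform", "dbh_cm", "W", "U", "M",
      "edge_flag")],
    file.path(out_dir, "sssp_tree.csv"), prov)
  write_metric_table(summaries$groups, file.path(out_dir, "sssp_groups.csv"),
                     prov)
  write_metric_table(summaries$distributions,
                     file.path(out_dir, "sssp_distributions.csv"), prov)
  logmsg("structure", sprintf("alpha0=%g buffer=%g edge_policy=%s",
                              alpha0, buffer_m, edge_policy))

  sizes <- run_stage("size", quadrat_size_metrics(stems, grid, terrain))
  write_metric_table(sizes$quadrat, file.path(out_dir, "size_quadrat.csv"),
                     prov)
  write_metric_table(sizes$site_type, file.path(out_dir, "size_site.csv"), prov)

  tests <- run_stage("compare", {
    qd <- div$quadrat; qs <- sizes$quadrat
    by_site <- function(v, st) split(v, st)
    metrics <- list(richness = qd$R, abundance = qd$N, shannon = qd$shannon,
                    evenness = qd$evenness, mean_dbh = qs$mean_dbh,
                    mean_th = qs$mean_th, mean_ba = qs$mean_ba)
    do.call(rbind, lapply(names(metrics), function(mn) {
      g <- by_site(metrics[[mn]], qd$site_type)
      g <- lapply(g, function(v) v[!is.na(v)])
      if (any(lengths(g) == 0L))
        return(data.frame(metric = mn, statistic = NA_real_,
                          p_value = NA_real_, band = NA_character_))
      tr <- kruskal_wallis(g)
      data.frame(metric = mn, statistic = tr$statistic, p_value = tr$p_value,
                 band = tr$band, stringsAsFactors = FALSE)
    }))
  })
  write_metric_table(tests, file.path(out_dir, "kruskal_site.csv"), prov)
  logmsg("compare", "Kruskal-Wallis site comparisons (no multiplicity correction)")

  ords <- run_stage("ordination", ordination_export(stems, grid, terrain,
                                                    records = records))
  write_metric_table(ords$response, file.path(out_dir, "ordination_response.csv"),
                     prov)
  write_metric_table(ords$explanatory,
                     file.path(out_dir, "ordination_explanatory.csv"), prov)
  write_metric_table(ords$abundance,
                     file.path(out_dir, "ordination_abundance.csv"), prov)

  writeLines(c(paste0("# ", prov), log_lines),
             file.path(out_dir, "run_log.txt"))
  invisible(list(stems = stems, substrate = substrate, grid = grid,
                 terrain = terrain, diversity = div, records = records,
                 summaries = summaries, sizes = sizes, tests = tests,
                 ordination = ords, out_dir = out_dir))
}
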