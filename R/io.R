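#' Write a landscape bundle to a directory of plain-text files
#'
#' Rasters go to ESRI ASCII grids (`vegetation.asc`, `soil.asc`,
#' `elevation.asc`) with the categorical level vocabularies in
#' `classes.yaml`; roads to `roads.wkt` (one `LINESTRING` per line); water
#' points to `water.csv` (columns `x`, `y`).
#'
#' @param bundle a `landscape_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_esri_ascii(bundle$vegetation, file.path(dir, "vegetation.asc"))
  write_esri_ascii(bundle$soil, file.path(dir, "soil.asc"))
  write_esri_ascii(bundle$elevation, file.path(dir, "elevation.asc"))
  yaml::write_yaml(list(vegetation = bundle$vegetation$levels,
                        soil = bundle$soil$levels),
                   file.path(dir, "classes.yaml"))
  writeLines(vapply(bundle$roads, function(m) {
    sprintf("LINESTRING (%s)",
            paste(sprintf("%.3f %.3f", m[, 1], m[, 2]), collapse = ", "))
  }, ""), file.path(dir, "roads.wkt"))
  utils::write.csv(data.frame(x = bundle$water[, 1], y = bundle$water[, 2]),
                   file.path(dir, "water.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  classes <- yaml::read_yaml(file.path(dir, "classes.yaml"))
  veg <- read_esri_ascii(file.path(dir, "vegetation.asc"),
                         levels = classes$vegetation)
  soil <- read_esri_ascii(file.path(dir, "soil.asc"), levels = classes$soil)
  elev <- read_esri_ascii(file.path(dir, "elevation.asc"))
  roads <- lapply(readLines(file.path(dir, "roads.wkt")), function(l) {
    body <- sub("^LINESTRING\\s*\\(", "", sub("\\)\\s*$", "", l))
    xy <- do.call(rbind, lapply(strsplit(body, ",")[[1]], function(p) {
      as.numeric(strsplit(trimws(p), "\\s+")[[1]])
    }))
    colnames(xy) <- c("x", "y")
    xy
  })
  water <- as.matrix(utils::read.csv(file.path(dir, "water.csv")))
  structure(list(vegetation = veg, soil = soil, elevation = elev,
                 roads = roads, water = water,
                 extent = raster_extent(elev), cell_size = elev$cell_size),
            class = "landscape_bundle")
}

#' Read and write telemetry tables as CSV
#'
#' Columns: `id`, `species`, `timestamp` (ISO-8601, UTC), `x`, `y` (metres).
#'
#' @param telemetry a telemetry data.frame.
#' @param path CSV path.
#' @export
write_telemetry <- function(telemetry, path) {
  out <- telemetry
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry
#' @export
read_telemetry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  df
}

#' Abundance ranking table in report layout
#'
#' Reshapes an `abundance_ranking` into the wide taxon x vegetation x
#' season-year layout (cells are Low/Medium/High/Very High labels).
#'
#' @param ranking an `abundance_ranking`.
#' @return data.frame with one row per vegetation class, one column per
#'   season-year.
#' @export
ranking_table <- function(ranking) {
  tab <- ranking$table
  sys <- unique(tab$season_year[order(tab$year, tab$season == "winter")])
  vegs <- sort(unique(tab$vegetation))
  out <- data.frame(taxon = ranking$taxon, vegetation = vegs)
  for (sy in sys) {
    out[[sy]] <- tab$label[match(paste(vegs, sy),
                                 paste(tab$vegetation, tab$season_year))]
  }
  out
}
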