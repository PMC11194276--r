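#' In-memory planar raster grid
#'
#' A `grid_raster` is the common spatial currency of the package: a regular
#' planar grid (coordinates in metres) carrying one continuous or categorical
#' layer. Values are stored as a matrix with row 1 at the TOP of the extent
#' (raster convention), x increasing eastwards and y northwards, cell-center
#' registration. Categorical layers store integer codes plus a `levels`
#' character vector (code `i` means `levels[i]`). Missing cells are `NA`.
#'
#' @param values numeric or integer matrix, `n_rows x n_cols`, row 1 = top.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin numeric length-2, (x, y) of the LOWER-LEFT corner of the
#'   extent.
#' @param levels optional character vector of class labels for categorical
#'   layers; `values` must then be integer codes in `1..length(levels)` or NA.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size, origin = c(0, 0), levels = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("raster must have at least one row and one column")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number")
  }
  if (length(origin) != 2L || any(!is.finite(origin))) {
    stop("`origin` must be finite (x, y) of the lower-left corner")
  }
  if (!is.null(levels)) {
    codes <- values[!is.na(values)]
    if (length(codes) && (any(codes != round(codes)) ||
                          any(codes < 1) || any(codes > length(levels)))) {
      stop("categorical values must be integer codes in 1..length(levels)")
    }
  }
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), levels = levels),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  if (!is.null(x$levels)) {
    cat("categorical:", paste(x$levels, collapse = ", "), "\n")
  } else {
    rng <- suppressWarnings(range(x$values, na.rm = TRUE))
    cat(sprintf("continuous, range [%g, %g], %d NA cells\n",
                rng[1], rng[2], sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Raster extent as (xmin, xmax, ymin, ymax)
#' @param r a `grid_raster`.
#' @export
raster_extent <- function(r) {
  c(xmin = r$origin[1],
    xmax = r$origin[1] + ncol(r$values) * r$cell_size,
    ymin = r$origin[2],
    ymax = r$origin[2] + nrow(r$values) * r$cell_size)
}

#' Coordinates of every cell center
#'
#' @param r a `grid_raster`.
#' @return data.frame with columns `row`, `col`, `x`, `y` in row-major order
#'   (row 1 = top row, i.e. largest y).
#' @export
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  xs <- r$origin[1] + (seq_len(nc) - 0.5) * cs
  ytop <- r$origin[2] + nr * cs
  ys <- ytop - (seq_len(nr) - 0.5) * cs
  data.frame(row = rep(seq_len(nr), times = nc),
             col = rep(seq_len(nc), each = nr),
             x = rep(xs, each = nr),
             y = rep(ys, times = nc))
}

#' Map point coordinates to raster cells
#'
#' Cell ownership is half-open: a point lying exactly on a shared vertical
#' edge belongs to the cell to its WEST, and on a shared horizontal edge to
#' the cell to its NORTH (together: the north-west cell), so extraction is
#' deterministic. Points on the outer east/south boundary of the extent are
#' owned by the outermost cells.
#'
#' @param r a `grid_raster`.
#' @param x,y numeric vectors of point coordinates (metres).
#' @return data.frame with `row`, `col` (NA for points outside the extent).
#' @export
xy_to_cell <- function(r, x, y) {
  cs <- r$cell_size
  nr <- nrow(r$values); nc <- ncol(r$values)
  ext <- raster_extent(r)
  fx <- (x - ext["xmin"]) / cs
  col <- floor(fx) + 1L
  on_edge <- fx == floor(fx) & fx > 0
  col[on_edge] <- fx[on_edge]          # vertical edge -> west cell
  fy <- (ext["ymax"] - y) / cs         # measured down from the top
  row <- floor(fy) + 1L
  on_edge <- fy == floor(fy) & fy > 0
  row[on_edge] <- fy[on_edge]          # horizontal edge -> north cell
  outside <- x < ext["xmin"] | x > ext["xmax"] |
    y < ext["ymin"] | y > ext["ymax"]
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Raster values at point coordinates
#'
#' @inheritParams xy_to_cell
#' @param label for categorical rasters, return class labels (default) rather
#'   than integer codes.
#' @return vector of values; NA for points outside the extent or on NA cells.
#' @export
raster_lookup <- function(r, x, y, label = TRUE) {
  rc <- xy_to_cell(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  if (!is.null(r$levels) && label) {
    out <- r$levels[out]
  }
  out
}

#' Check that two rasters share the same grid
#' @param a,b `grid_raster` objects.
#' @export
rasters_aligned <- function(a, b) {
  isTRUE(all.equal(dim(a$values), dim(b$values))) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

stopifnot_aligned <- function(...) {
  rs <- list(...)
  for (i in seq_along(rs)[-1]) {
    if (!rasters_aligned(rs[[1]], rs[[i]])) {
      stop("rasters are not aligned (extent, cell size and dimensions must match)")
    }
  }
  invisible(TRUE)
}

#' Apply a function cellwise, keeping grid geometry
#' @param r a `grid_raster`.
#' @param f function applied to the value matrix.
#' @export
raster_apply <- function(r, f) {
  v <- f(r$values)
  if (!is.matrix(v)) v <- matrix(v, nrow(r$values), ncol(r$values))
  grid_raster(v, r$cell_size, r$origin)
}

#' Write a raster as ESRI ASCII grid
#'
#' Plain-text interchange format: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows top-to-bottom.
#' Categorical rasters are written as their integer codes; the `levels`
#' mapping is the caller's to record.
#'
#' @param r a `grid_raster`.
#' @param path output file path.
#' @param nodata numeric code written for NA cells.
#' @export
write_esri_ascii <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(r$origin[1], scientific = FALSE)),
    paste("yllcorner", format(r$origin[2], scientific = FALSE)),
    paste("cellsize", format(r$cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @param levels optional class labels to attach (categorical rasters are
#'   stored as integer codes).
#' @return a `grid_raster`.
#' @export
read_esri_ascii <- function(path, levels = NULL) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ESRI ASCII header in ", path)
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  if (nrow(v) != vals["nrows"] || ncol(v) != vals["ncols"]) {
    stop("ESRI ASCII body does not match header dimensions in ", path)
  }
  if ("nodata_value" %in% keys) v[v == vals["nodata_value"]] <- NA
  grid_raster(v, vals["cellsize"], c(vals["xllcorner"], vals["yllcorner"]),
              levels = levels)
}

#' Expand a categorical raster into 0/1 indicator layers
#'
#' @param r categorical `grid_raster`.
#' @param reference level to omit (the reference class); NULL keeps all.
#' @param prefix name prefix for the returned layers.
#' @return named list of continuous 0/1 `grid_raster`s, one per non-reference
#'   level present in `r$levels`.
#' @export
indicator_layers <- function(r, reference = NULL, prefix = "") {
  if (is.null(r$levels)) stop("`r` is not categorical (no levels)")
  keep <- setdiff(r$levels, reference)
  out <- lapply(keep, function(lv) {
    code <- match(lv, r$levels)
    raster_apply(r, function(v) (v == code) + 0)
  })
  names(out) <- paste0(prefix, keep)
  out
}
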