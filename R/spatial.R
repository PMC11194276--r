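#' Euclidean distance-to-feature raster
#'
#' Each cell of the template receives the planar distance (metres) from its
#' center to the nearest feature: points, polyline segments, or both. Cells
#' whose center lies on a feature get 0.
#'
#' @param features one of: a 2-column matrix of point coordinates; a list of
#'   2-column matrices, each a polyline's vertices; or a list with elements
#'   `points` and/or `lines` in those shapes.
#' @param template `grid_raster` defining the output grid.
#' @return continuous `grid_raster` of distances (m).
#' @export
distance_raster <- function(features, template) {
  pts <- NULL; lines <- NULL
  if (is.matrix(features)) {
    pts <- features
  } else if (is.list(features) && !is.null(names(features)) &&
             any(c("points", "lines") %in% names(features))) {
    pts <- features$points
    lines <- features$lines
  } else if (is.list(features)) {
    lines <- features
  }
  if ((is.null(pts) || nrow(pts) == 0) &&
      (is.null(lines) || !length(lines))) {
    stop("empty feature set")
  }
  cc <- cell_centers(template)
  d2 <- rep(Inf, nrow(cc))
  if (!is.null(pts)) {
    for (i in seq_len(nrow(pts))) {
      d2 <- pmin(d2, (cc$x - pts[i, 1])^2 + (cc$y - pts[i, 2])^2)
    }
  }
  if (!is.null(lines)) {
    for (ln in lines) {
      for (i in seq_len(nrow(ln) - 1L)) {
        d2 <- pmin(d2, segment_dist2(cc$x, cc$y,
                                     ln[i, 1], ln[i, 2],
                                     ln[i + 1L, 1], ln[i + 1L, 2]))
      }
      if (nrow(ln) == 1L) {
        d2 <- pmin(d2, (cc$x - ln[1, 1])^2 + (cc$y - ln[1, 2])^2)
      }
    }
  }
  v <- matrix(sqrt(d2), nrow(template$values), ncol(template$values))
  grid_raster(v, template$cell_size, template$origin)
}

# squared distance from points (px, py) to segment (x1,y1)-(x2,y2)
segment_dist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

#' Log transform for distance covariates
#'
#' Distance-to-feature covariates are log transformed as ln(d + 1) so that
#' cells lying on a road or water source (d = 0) remain finite.
#'
#' @param d non-negative numeric vector, matrix or `grid_raster`.
#' @return object of the same shape with values ln(d + 1).
#' @export
log_distance <- function(d) {
  if (inherits(d, "grid_raster")) return(raster_apply(d, log_distance))
  if (any(d < 0, na.rm = TRUE)) stop("distances must be non-negative")
  log1p(d)
}

#' Center and scale a continuous covariate
#'
#' Standardizes to mean 0 and standard deviation 1 (sample SD, denominator
#' n - 1) and records the transform so it can be replayed identically on
#' prediction layers.
#'
#' @param v numeric vector or `grid_raster`.
#' @param center,scale optional stored parameters to replay; computed from
#'   `v` when NULL.
#' @return for vectors, a numeric vector with attributes `center` and
#'   `scale`; for rasters, a `grid_raster` with the same attributes.
#' @export
center_scale <- function(v, center = NULL, scale = NULL) {
  if (inherits(v, "grid_raster")) {
    vals <- as.numeric(v$values)
    out <- center_scale(vals, center, scale)
    r <- grid_raster(matrix(out, nrow(v$values), ncol(v$values)),
                     v$cell_size, v$origin)
    attr(r, "center") <- attr(out, "center")
    attr(r, "scale") <- attr(out, "scale")
    return(r)
  }
  if (is.null(center)) center <- mean(v, na.rm = TRUE)
  if (is.null(scale)) scale <- sd(v, na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0) {
    stop("cannot scale a constant covariate (sd = 0)")
  }
  structure((v - center) / scale, center = center, scale = scale)
}

#' Kernel-density population range
#'
#' Gaussian-kernel utilization density of pooled locations evaluated exactly
#' on the template's cell centers (via [MASS::kde2d]), with Scott's
#' reference bandwidth per axis, sd(x) * n^(-1/6). The population range is
#' the smallest set of highest-density cells whose summed probability mass
#' reaches the isopleth (default 99%).
#'
#' @param points data.frame with `x`, `y` (>= 10 rows).
#' @param template `grid_raster` defining the evaluation grid.
#' @param isopleth utilization fraction in (0, 1); default 0.99.
#' @param bandwidth optional (hx, hy) in metres, overriding Scott's rule.
#' @return a `population_range`: list with `mask` (logical-valued
#'   `grid_raster`), `density` (`grid_raster`, integrates to 1 over cells),
#'   `isopleth`, `bandwidth`, `n_points`.
#' @export
kde_population_range <- function(points, template, isopleth = 0.99,
                                 bandwidth = NULL) {
  if (nrow(points) < 10) stop("need >= 10 points for a population range")
  if (isopleth <= 0 || isopleth >= 1) stop("isopleth must be in (0, 1)")
  n <- nrow(points)
  if (is.null(bandwidth)) {
    bandwidth <- c(sd(points$x), sd(points$y)) * n^(-1 / 6)
  }
  if (any(bandwidth <= 0)) stop("degenerate bandwidth (coincident points?)")
  nr <- nrow(template$values); nc <- ncol(template$values)
  cs <- template$cell_size
  ext <- raster_extent(template)
  gx <- ext["xmin"] + (seq_len(nc) - 0.5) * cs
  gy <- ext["ymin"] + (seq_len(nr) - 0.5) * cs
  # kde2d's kernel sd is h/4, and its grid is seq(lims[1], lims[2]) == the
  # cell-center vectors when lims are the outermost centers
  kd <- MASS::kde2d(points$x, points$y, h = 4 * bandwidth,
                    n = c(nc, nr),
                    lims = c(gx[1], gx[nc], gy[1], gy[nr]))
  dens <- t(kd$z)[nr:1, , drop = FALSE]   # kde2d: z[x, y], y ascending
  p <- dens / sum(dens)
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= isopleth)[1]
  mask <- matrix(FALSE, nr, nc)
  mask[ord[seq_len(k)]] <- TRUE
  structure(list(
    mask = grid_raster(mask + 0, cs, template$origin),
    density = grid_raster(p, cs, template$origin),
    isopleth = isopleth,
    bandwidth = unname(bandwidth),
    n_points = n
  ), class = "population_range")
}

#' Uniformly sample available locations from a population range
#'
#' Draws `ratio` available points per used point, uniform over the range's
#' mask cells (and uniform within each cell).
#'
#' @param range a `population_range` (or a logical-valued `grid_raster`
#'   mask).
#' @param n_used number of used locations being matched.
#' @param ratio available : used ratio (default 10).
#' @param seed integer RNG seed.
#' @return data.frame with `x`, `y` of length `ratio * n_used`.
#' @export
sample_available <- function(range, n_used, ratio = 10L, seed = 1L) {
  mask <- if (inherits(range, "population_range")) range$mask else range
  cells <- which(mask$values > 0)
  if (!length(cells)) stop("availability mask is empty")
  n <- as.integer(ratio * n_used)
  set.seed(seed)
  if (n == 0L) return(data.frame(x = numeric(), y = numeric()))
  drawn <- sample(cells, n, replace = TRUE)
  nr <- nrow(mask$values)
  row <- ((drawn - 1L) %% nr) + 1L
  col <- ((drawn - 1L) %/% nr) + 1L
  cs <- mask$cell_size
  ext <- raster_extent(mask)
  data.frame(
    x = unname(ext["xmin"] + (col - 1L) * cs + runif(n) * cs),
    y = unname(ext["ymax"] - (row - 1L) * cs - runif(n) * cs)
  )
}

#' Extract covariate values at point locations
#'
#' Builds one covariate row per point. A layer may be a single
#' `grid_raster` or, for time-varying covariates (e.g. seasonal prey
#' rasters), a named list of rasters keyed by season-year label; each point
#' is then joined to the raster of its own `season_year`. Categorical
#' rasters yield class labels. Points falling on an NA cell are flagged in
#' `.any_na`; points outside the raster extent are an error.
#'
#' @param points data.frame with `x`, `y` and, when any layer is
#'   time-varying, `season_year`.
#' @param layers named list of `grid_raster`s or season-year keyed lists of
#'   them.
#' @return data.frame of covariates plus logical `.any_na`.
#' @export
extract_covariates <- function(points, layers) {
  n <- nrow(points)
  out <- list()
  any_na <- rep(FALSE, n)
  for (nm in names(layers)) {
    layer <- layers[[nm]]
    if (inherits(layer, "grid_raster")) {
      check_inside(points, layer, nm)
      vals <- raster_lookup(layer, points$x, points$y)
    } else {
      if (is.null(points$season_year)) {
        stop("points need a `season_year` column for time-varying layer ", nm)
      }
      vals <- rep(NA_real_, n)
      if (!is.null(layer[[1]]$levels)) vals <- rep(NA_character_, n)
      for (sy in unique(points$season_year)) {
        if (is.null(layer[[sy]])) {
          stop("layer ", nm, " has no raster for season-year ", sy)
        }
        i <- points$season_year == sy
        check_inside(points[i, , drop = FALSE], layer[[sy]], nm)
        vals[i] <- raster_lookup(layer[[sy]], points$x[i], points$y[i])
      }
    }
    any_na <- any_na | is.na(vals)
    out[[nm]] <- vals
  }
  out <- as.data.frame(out, optional = TRUE)
  out$.any_na <- any_na
  out
}

check_inside <- function(points, r, nm) {
  ext <- raster_extent(r)
  bad <- which(points$x < ext["xmin"] | points$x > ext["xmax"] |
                 points$y < ext["ymin"] | points$y > ext["ymax"])
  if (length(bad)) {
    stop("point(s) outside extent of layer ", nm, ": rows ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L))
  }
}
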