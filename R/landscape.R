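#' @importFrom stats rnorm runif rpois rbinom quantile dnorm sd cor
NULL

VEG_CLASSES <- c("barren", "desert_scrub", "developed", "forest", "grassland",
                 "sagebrush", "shrubland", "agriculture", "riparian", "other")
SOIL_CLASSES <- c("silt", "fine_sand", "blocky_loam", "gravel")

normalize_class <- function(x) gsub("[ -]+", "_", tolower(trimws(x)))

# Gaussian random field on the torus: white noise smoothed by circular FFT
# convolution with a Gaussian kernel of the given range (in cells). The
# marginal scale is irrelevant downstream because fields are thresholded by
# empirical quantiles or rescaled to a target range.
smooth_field <- function(n_rows, n_cols, range_cells) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells <= 0) return(z)
  dr <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dc <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  k <- outer(dnorm(dr, sd = range_cells), dnorm(dc, sd = range_cells))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (n_rows * n_cols)
}

# Threshold a continuous field into categories at empirical quantiles so the
# realized class proportions match the requested mixture up to cell rounding.
threshold_field <- function(field, mixture, levels_all) {
  mixture <- mixture[mixture > 0]
  cuts <- quantile(field, probs = cumsum(mixture), type = 7, names = FALSE)
  cuts[length(cuts)] <- Inf
  code <- matrix(findInterval(field, c(-Inf, cuts[-length(cuts)])),
                 nrow(field), ncol(field))
  codes_all <- match(names(mixture), levels_all)
  matrix(codes_all[code], nrow(field), ncol(field))
}

#' Generate a synthetic desert landscape
#'
#' Produces aligned vegetation, soil and elevation rasters plus road
#' polylines and water points, emulating a Great Basin cold-desert study
#' area. Categorical layers are drawn by thresholding smoothed Gaussian
#' random fields at the quantiles of the requested class mixture, so patches
#' are spatially autocorrelated (as real vegetation is) and realized class
#' proportions match the mixture up to cell rounding.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{n_rows, n_cols}{grid dimensions (positive integers).}
#'     \item{cell_size}{cell edge, metres.}
#'     \item{origin}{(x, y) lower-left corner; default c(0, 0).}
#'     \item{veg_mixture}{named proportions over vegetation classes from
#'       \{barren, desert_scrub, developed, forest, grassland, sagebrush,
#'       shrubland, agriculture, riparian, other\}; must sum to 1.}
#'     \item{soil_mixture}{named proportions over \{silt, fine_sand,
#'       blocky_loam, gravel\}; must sum to 1. Default 0.3/0.3/0.25/0.15.}
#'     \item{elev_range}{(min, max) elevation in metres; default
#'       c(1298, 3317).}
#'     \item{smoothness}{field correlation range in cells; default 6.}
#'     \item{n_roads, n_water}{feature counts; default 4 and 6.}
#'   }
#' @param seed integer RNG seed; the result is a pure function of
#'   (config, seed).
#' @return a `landscape_bundle`: list with `vegetation`, `soil`, `elevation`
#'   (`grid_raster`s), `roads` (list of coordinate matrices), `water`
#'   (coordinate matrix) and `extent`.
#' @export
generate_landscape <- function(config, seed = 1L) {
  nr <- config$n_rows; nc <- config$n_cols
  if (is.null(nr) || is.null(nc) || nr < 1 || nc < 1) {
    stop("configuration error: grid dimensions must be positive")
  }
  cs <- config$cell_size
  if (is.null(cs) || cs <= 0) stop("configuration error: cell_size must be > 0")
  origin <- config$origin %||% c(0, 0)
  veg_mix <- config$veg_mixture
  names(veg_mix) <- normalize_class(names(veg_mix))
  if (any(!names(veg_mix) %in% VEG_CLASSES)) {
    stop("configuration error: unknown vegetation class: ",
         paste(setdiff(names(veg_mix), VEG_CLASSES), collapse = ", "))
  }
  if (abs(sum(veg_mix) - 1) > 1e-6) {
    stop("configuration error: vegetation mixture must sum to 1")
  }
  soil_mix <- config$soil_mixture %||%
    c(silt = 0.3, fine_sand = 0.3, blocky_loam = 0.25, gravel = 0.15)
  names(soil_mix) <- normalize_class(names(soil_mix))
  if (any(!names(soil_mix) %in% SOIL_CLASSES)) {
    stop("configuration error: unknown soil class: ",
         paste(setdiff(names(soil_mix), SOIL_CLASSES), collapse = ", "))
  }
  if (abs(sum(soil_mix) - 1) > 1e-6) {
    stop("configuration error: soil mixture must sum to 1")
  }
  elev_range <- config$elev_range %||% c(1298, 3317)
  smoothness <- config$smoothness %||% 6
  n_roads <- config$n_roads %||% 4L
  n_water <- config$n_water %||% 6L

  set.seed(seed)
  veg <- grid_raster(threshold_field(smooth_field(nr, nc, smoothness),
                                     veg_mix, VEG_CLASSES),
                     cs, origin, levels = VEG_CLASSES)
  soil <- grid_raster(threshold_field(smooth_field(nr, nc, smoothness * 1.5),
                                      soil_mix, SOIL_CLASSES),
                      cs, origin, levels = SOIL_CLASSES)
  ef <- smooth_field(nr, nc, smoothness * 2)
  ef <- (ef - min(ef)) / (max(ef) - min(ef))
  elev <- grid_raster(elev_range[1] + ef * diff(elev_range), cs, origin)

  ext <- raster_extent(elev)
  roads <- lapply(seq_len(n_roads), function(i) {
    # a gently wandering polyline crossing the extent
    nv <- 8L
    if (runif(1) < 0.5) {
      xs <- seq(ext["xmin"], ext["xmax"], length.out = nv)
      ys <- runif(1, ext["ymin"], ext["ymax"]) +
        cumsum(rnorm(nv, sd = (ext["ymax"] - ext["ymin"]) / 20))
      ys <- pmin(pmax(ys, ext["ymin"]), ext["ymax"])
    } else {
      ys <- seq(ext["ymin"], ext["ymax"], length.out = nv)
      xs <- runif(1, ext["xmin"], ext["xmax"]) +
        cumsum(rnorm(nv, sd = (ext["xmax"] - ext["xmin"]) / 20))
      xs <- pmin(pmax(xs, ext["xmin"]), ext["xmax"])
    }
    cbind(x = xs, y = ys)
  })
  water <- cbind(x = runif(n_water, ext["xmin"], ext["xmax"]),
                 y = runif(n_water, ext["ymin"], ext["ymax"]))

  structure(list(vegetation = veg, soil = soil, elevation = elev,
                 roads = roads, water = water, extent = ext,
                 cell_size = cs),
            class = "landscape_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth simulation parameters
#'
#' Bundles the known selection coefficients and survey rates that the
#' synthetic module simulates from, so downstream fits can be checked by
#' parameter recovery. Defaults reflect the study conditions the package
#' emulates: strong vegetation-driven rodent capture means (forest highest),
#' leporid sighting rates peaking in desert scrub, and seasonal fox
#' coefficients with the adaptive-compromise sign structure — predator-RPU
#' and prey selection positive and clearly stronger in winter than summer,
#' silt and fine sand selected over blocky loam over gravel. Predator-RPU
#' coefficients are on the scale of the max-normalized (0, 1] RPU surface
#' the predator stage emits; prey coefficients are per rank unit (1--4).
#'
#' @param beta_coyote,beta_fox_summer,beta_fox_winter named coefficient
#'   vectors (log selection strength per covariate).
#' @param veg_capture_means named per-vegetation Poisson mean captures per
#'   grid per session.
#' @param veg_leporid_rates named per-vegetation sighting intensity per unit
#'   availability per night.
#' @param seed integer.
#' @return a `truth_parameters` list.
#' @export
truth_parameters <- function(
    beta_coyote = c(prey = 0.25, elevation = -0.6, road_dist = 0.3,
                    water_dist = -0.4),
    beta_fox_summer = c(coyote_rpu = 0.4, prey = 0.0,
                        soil_silt = 0.84, soil_fine_sand = 0.66,
                        soil_gravel = 0.29, road_dist = 0.04),
    beta_fox_winter = c(coyote_rpu = 1.5, prey = 0.3,
                        soil_silt = 0.51, soil_fine_sand = 0.41,
                        soil_gravel = -0.68, road_dist = -0.2),
    veg_capture_means = c(barren = 14, desert_scrub = 20, forest = 34,
                          grassland = 15, sagebrush = 7, shrubland = 5),
    veg_leporid_rates = c(barren = 1.5, desert_scrub = 4, developed = 0.8,
                          grassland = 2, sagebrush = 3, shrubland = 2),
    seed = 1L) {
  if (any(veg_capture_means < 0) || any(veg_leporid_rates < 0)) {
    stop("capture means and sighting rates must be non-negative")
  }
  structure(list(beta_coyote = beta_coyote,
                 beta_fox_summer = beta_fox_summer,
                 beta_fox_winter = beta_fox_winter,
                 veg_capture_means = veg_capture_means,
                 veg_leporid_rates = veg_leporid_rates,
                 seed = as.integer(seed)),
            class = "truth_parameters")
}

#' Write/read truth parameters as YAML
#' @param truth a `truth_parameters` object.
#' @param path file path.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(lapply(unclass(truth), as.list), path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(truth_parameters, lapply(raw, function(x) unlist(x)))
}
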