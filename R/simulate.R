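#' Simulate telemetry from an exponential resource selection surface
#'
#' Locations are drawn as an independent inhomogeneous point process whose
#' intensity over cells is proportional to exp(beta %*% x): exactly the
#' exponential RSF the fitting stage assumes, with no movement
#' autocorrelation (second-order selection treats within-season locations as
#' exchangeable). Each sampled cell position is jittered uniformly within the
#' cell.
#'
#' @param layers named list of continuous `grid_raster` covariate layers;
#'   every name in `beta` must appear here. Categorical covariates enter as
#'   0/1 indicator layers (see [indicator_layers()]).
#' @param beta named numeric vector of selection coefficients.
#' @param n_points number of locations to draw.
#' @param mask optional logical matrix (or logical-valued `grid_raster`)
#'   restricting availability; points fall only where TRUE. Default: all
#'   cells with complete covariates.
#' @param seed integer RNG seed.
#' @param id,species identifiers copied into the output table.
#' @param start first fix time (POSIXct or string); fixes are spaced
#'   `interval_hours` apart.
#' @param interval_hours spacing between consecutive fixes (default 4, the
#'   GPS duty cycle emulated).
#' @return data.frame (TelemetryTable) with columns `id`, `species`,
#'   `timestamp`, `x`, `y`.
#' @export
simulate_telemetry <- function(layers, beta, n_points, mask = NULL,
                               seed = 1L, id = "a1", species = "animal",
                               start = "2011-06-01 00:00:00",
                               interval_hours = 4) {
  if (length(beta) && is.null(names(beta))) stop("`beta` must be named")
  missing_cov <- setdiff(names(beta), names(layers))
  if (length(missing_cov)) {
    stop("specification error: beta references missing covariate(s): ",
         paste(missing_cov, collapse = ", "))
  }
  template <- if (length(layers)) layers[[1]] else stop("need >= 1 layer")
  if (length(layers) > 1) do.call(stopifnot_aligned, layers)

  eta <- matrix(0, nrow(template$values), ncol(template$values))
  ok <- !is.na(eta)
  for (nm in names(beta)) {
    v <- layers[[nm]]$values
    ok <- ok & !is.na(v)
    v[is.na(v)] <- 0
    eta <- eta + beta[[nm]] * v
  }
  if (!is.null(mask)) {
    m <- if (inherits(mask, "grid_raster")) mask$values else mask
    ok <- ok & !is.na(m) & (m > 0)
  }
  if (!any(ok)) stop("availability mask is empty")

  cells <- which(ok)
  w <- exp(eta[cells] - max(eta[cells]))
  set.seed(seed)
  if (is.character(start)) start <- as.POSIXct(start, tz = "UTC")
  if (n_points == 0) {
    return(data.frame(id = character(), species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric()))
  }
  drawn <- sample(cells, n_points, replace = TRUE, prob = w)
  nr <- nrow(template$values)
  row <- ((drawn - 1L) %% nr) + 1L
  col <- ((drawn - 1L) %/% nr) + 1L
  cs <- template$cell_size
  ext <- raster_extent(template)
  x <- ext["xmin"] + (col - 1L) * cs + runif(n_points) * cs
  y <- ext["ymax"] - (row - 1L) * cs - runif(n_points) * cs
  data.frame(id = id, species = species,
             timestamp = start + (seq_len(n_points) - 1L) * interval_hours * 3600,
             x = unname(x), y = unname(y))
}

#' Simulate small-mammal trapping sessions
#'
#' One record per grid x session; the individual count on a grid is Poisson
#' with a vegetation-specific mean (captures are ingested as raw
#' individuals-per-grid counts, so no trap-level detail is simulated).
#'
#' @param veg_capture_means named non-negative Poisson means
#'   (individuals/grid/session) per vegetation class.
#' @param grid_assignments named character vector: grid id -> vegetation
#'   class (the study design uses 16 grids).
#' @param sessions data.frame with columns `year` and `session`
#'   ("early"/"late"), one row per trapping session.
#' @param seed integer RNG seed.
#' @return data.frame with `grid_id`, `vegetation`, `year`, `session`,
#'   `count`.
#' @export
simulate_trapping <- function(veg_capture_means, grid_assignments, sessions,
                              seed = 1L) {
  if (any(veg_capture_means < 0)) stop("capture means must be >= 0")
  names(veg_capture_means) <- normalize_class(names(veg_capture_means))
  veg <- normalize_class(grid_assignments)
  unknown <- setdiff(unique(veg), names(veg_capture_means))
  if (length(unknown)) {
    stop("configuration error: unknown vegetation class: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(sessions)), function(i) {
    data.frame(grid_id = names(grid_assignments) %||%
                 paste0("g", seq_along(veg)),
               vegetation = unname(veg),
               year = sessions$year[i], session = sessions$session[i],
               count = rpois(length(veg), veg_capture_means[veg]))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate leporid spotlight surveys
#'
#' Counts per (transect, vegetation class) are Poisson with mean
#' rate x availability x effort, where availability is the proportion of
#' that class within the 400 m detection strip of the transect and effort is
#' the number of survey nights. Detection is perfect; each sighting record
#' carries its vegetation class.
#'
#' @param veg_leporid_rates named non-negative sighting intensities per unit
#'   availability per night.
#' @param transects data.frame with columns `transect_id`, `vegetation`,
#'   `availability` (proportion in [0,1]; per-transect sums must be <= 1).
#' @param surveys data.frame with columns `year`, `season`.
#' @param nights survey nights pooled per transect per survey (default 3).
#' @param seed integer RNG seed.
#' @return data.frame of individual sightings: `transect_id`, `year`,
#'   `season`, `vegetation` (zero counts produce no rows).
#' @export
simulate_spotlight <- function(veg_leporid_rates, transects, surveys,
                               nights = 3L, seed = 1L) {
  if (any(veg_leporid_rates < 0)) stop("configuration error: negative rate")
  names(veg_leporid_rates) <- normalize_class(names(veg_leporid_rates))
  transects$vegetation <- normalize_class(transects$vegetation)
  tot <- tapply(transects$availability, transects$transect_id, sum)
  if (any(tot > 1 + 1e-9)) {
    stop("per-transect availability proportions must sum to <= 1")
  }
  unknown <- setdiff(unique(transects$vegetation), names(veg_leporid_rates))
  if (length(unknown)) {
    stop("configuration error: unknown vegetation class: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(surveys)), function(i) {
    mu <- veg_leporid_rates[transects$vegetation] *
      transects$availability * nights
    counts <- rpois(length(mu), mu)
    keep <- rep(seq_along(counts), counts)
    if (!length(keep)) return(NULL)
    data.frame(transect_id = transects$transect_id[keep],
               year = surveys$year[i], season = surveys$season[i],
               vegetation = transects$vegetation[keep])
  }))
  if (is.null(out)) {
    out <- data.frame(transect_id = character(), year = integer(),
                      season = character(), vegetation = character())
  }
  rownames(out) <- NULL
  out
}
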