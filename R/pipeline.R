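#' Default pipeline configuration
#'
#' Consolidates the analysis constants: summer is April--September and
#' winter October--March; the prey layer weights small mammals 2/3 and
#' leporids 1/3; ten available locations are drawn per used location; an
#' animal needs at least 30 locations in a season to enter that season's
#' fit; candidate models are base (predator RPU + prey), base + soil, and
#' full (base + soil + road distance); covariates correlated above 0.7 are
#' screened out; model evaluation uses fivefold cross-validation; the
#' population range is a 99% kernel density isopleth.
#'
#' @param ... overrides for any default element.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ratio = 10L,
    min_locations = 30L,
    prey_weights = c(2 / 3, 1 / 3),
    isopleth = 0.99,
    cv_folds = 5L,
    correlation_threshold = 0.7,
    log_water_distance = TRUE,
    seed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(abs(sum(cfg$prey_weights) - 1) < 1e-9,
            cfg$ratio >= 1, cfg$isopleth > 0, cfg$isopleth < 1)
  cfg
}

# season_year labels for available rows, paired ratio-per-used
pair_available_sy <- function(used_sy, ratio) rep(used_sy, each = ratio)

#' Build the seasonal prey rasters from survey records
#'
#' Runs the full prey-index chain: trapping records are summarized to mean
#' individuals per grid, spotlight sightings standardized by availability,
#' both quartile-ranked against their pooled study-period values, the
#' vegetation raster reclassified per season-year, and the two rank rasters
#' combined 2/3 : 1/3.
#'
#' @param trapping trapping records ([simulate_trapping()] schema).
#' @param sightings spotlight sightings ([simulate_spotlight()] schema).
#' @param transects transect availability table.
#' @param vegetation categorical vegetation `grid_raster`.
#' @param weights prey weights (small mammal, leporid).
#' @param session_to_season map for trapping sessions.
#' @return list: `prey` (named list of season-year `grid_raster`s),
#'   `rank_sm`, `rank_lep` (`abundance_ranking`s).
#' @export
build_prey_rasters <- function(trapping, sightings, transects, vegetation,
                               weights = c(2 / 3, 1 / 3),
                               session_to_season = c(early = "summer",
                                                     late = "winter")) {
  sm <- summarize_captures(trapping, session_to_season)
  lep <- summarize_sightings(sightings, transects)
  rank_sm <- rank_abundance(sm, "small_mammal")
  rank_lep <- rank_abundance(lep, "leporid")
  sys <- union(unique(rank_sm$table$season_year),
               unique(rank_lep$table$season_year))
  prey <- lapply(sys, function(sy) {
    sm_r <- if (sy %in% rank_sm$table$season_year) {
      reclassify_vegetation(vegetation, rank_sm, sy)
    } else {
      raster_apply(vegetation, function(v) matrix(NA_real_, nrow(v), ncol(v)))
    }
    lep_r <- if (sy %in% rank_lep$table$season_year) {
      reclassify_vegetation(vegetation, rank_lep, sy)
    } else {
      raster_apply(vegetation, function(v) matrix(NA_real_, nrow(v), ncol(v)))
    }
    combine_prey(sm_r, lep_r, weights)
  })
  names(prey) <- sys
  list(prey = prey, rank_sm = rank_sm, rank_lep = rank_lep)
}

# cellwise mean of aligned rasters, NA only where all inputs are NA
mean_raster <- function(rasters) {
  do.call(stopifnot_aligned, rasters)
  arr <- simplify2array(lapply(rasters, function(r) r$values))
  v <- apply(arr, c(1, 2), function(z) {
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  })
  grid_raster(v, rasters[[1]]$cell_size, rasters[[1]]$origin)
}

#' Fit the dominant-predator (coyote) stage
#'
#' For each season with telemetry: derives the availability domain as the
#' 99% KDE range of all predator locations, samples available points 10:1,
#' extracts prey abundance (at each point's season-year), centered/scaled
#' elevation, vegetation (barren reference), log road distance and water
#' distance (log per `log_water_distance`), fits the exponential RSF,
#' cross-validates AUC, and predicts relative probability of use (RPU)
#' across the landscape using the season's mean prey raster.
#'
#' @param config list with elements `landscape` (a `landscape_bundle`),
#'   `telemetry` (data.frame `id`, `timestamp`, `x`, `y`), `prey` (named
#'   list of season-year prey `grid_raster`s) plus the [pipeline_config()]
#'   constants.
#' @return list with per-season `fit`, `design`, `cv`, `rpu`, plus `range`,
#'   `layers` (the transformed covariate rasters) and `counts`.
#' @export
run_coyote_stage <- function(config) {
  cfg <- utils::modifyList(pipeline_config(), config)
  land <- cfg$landscape
  tel <- cfg$telemetry
  template <- land$elevation
  sy <- season_of(tel$timestamp)
  tel <- cbind(tel, sy[, c("season", "season_year")])

  road_dist <- log_distance(distance_raster(land$roads, template))
  water_raw <- distance_raster(land$water, template)
  water_dist <- if (isTRUE(cfg$log_water_distance)) log_distance(water_raw)
  else water_raw
  elev_scaled <- center_scale(land$elevation)
  transforms <- list(
    road_dist = "log1p",
    water_dist = if (isTRUE(cfg$log_water_distance)) "log1p" else "identity",
    elevation = list(center = attr(elev_scaled, "center"),
                     scale = attr(elev_scaled, "scale"))
  )

  range_ <- kde_population_range(tel, template, isopleth = cfg$isopleth)
  layers <- list(prey = cfg$prey, elevation = elev_scaled,
                 vegetation = land$vegetation,
                 road_dist = road_dist, water_dist = water_dist)

  seasons <- intersect(c("summer", "winter"), unique(tel$season))
  out <- list()
  for (s in seasons) {
    used_pts <- tel[tel$season == s, , drop = FALSE]
    if (nrow(used_pts) == 0) next
    avail <- sample_available(range_, nrow(used_pts), cfg$ratio,
                              seed = cfg$seed + match(s, c("summer", "winter")))
    avail$season_year <- pair_available_sy(used_pts$season_year, cfg$ratio)
    used_cov <- extract_covariates(used_pts, layers)
    avail_cov <- extract_covariates(avail, layers)
    design <- build_design(used_cov, avail_cov,
                           categorical_refs = c(vegetation = "barren"))
    fit <- fit_rsf(design, transforms = transforms)
    cv <- kfold_auc(design, k = cfg$cv_folds, seed = cfg$seed)
    season_prey <- mean_raster(
      cfg$prey[grepl(paste0("^", s, "_"), names(cfg$prey))])
    rpu <- predict_rpu(fit, list(prey = season_prey,
                                 elevation = elev_scaled,
                                 vegetation = land$vegetation,
                                 road_dist = road_dist,
                                 water_dist = water_dist),
                       apply_transforms = FALSE, rescale = "max")
    out[[s]] <- list(fit = fit, design = design, cv = cv, rpu = rpu,
                     n_used = design$n_used, n_available = design$n_available)
  }
  if (!length(out)) warning("no season had telemetry; nothing fitted")
  missing_season <- setdiff(c("summer", "winter"), names(out))
  if (length(missing_season)) {
    warning("no telemetry for season(s): ",
            paste(missing_season, collapse = ", "), "; skipped")
  }
  list(seasons = out, range = range_, layers = layers,
       transforms = transforms,
       counts = list(
         n_locations = nrow(tel),
         per_season = vapply(out, function(o) o$n_used, 0)
       ))
}

subset_design <- function(design, covs) {
  keep <- c("case", covs,
            intersect(c("animal_id", "season_year"), names(design$data)))
  d <- design
  d$data <- design$data[, keep, drop = FALSE]
  d$covariates <- covs
  d
}

#' Fit the subordinate-carnivore (kit fox) stage
#'
#' Filters animals to those with at least `min_locations` locations in a
#' season, pools all retained locations into a 99% KDE population range,
#' samples available points 10:1 from it, extracts predator RPU (that
#' season's raster), prey abundance (the point's season-year), soil (blocky
#' loam reference) and log road distance, screens continuous covariates for
#' |r| > 0.7, and fits the three candidate models per season: base
#' (predator RPU + prey), base + soil, and full (+ road distance), compared
#' by AICc with parsimony flags, with Wald CIs and zero-overlap flags for
#' the full model, cross-validated AUC and a residual semivariogram.
#'
#' @param config list with `landscape`, `telemetry` (columns `id`,
#'   `timestamp`, `x`, `y`), `prey` plus [pipeline_config()] constants.
#' @param coyote_rpu named list: season ("summer", "winter") -> RPU
#'   `grid_raster` from [run_coyote_stage()].
#' @return a run report: per-season `fits`, `comparison`, `ci`, `cv`,
#'   `semivariogram`, `design`; plus `range` and `counts`.
#' @export
run_kitfox_stage <- function(config, coyote_rpu) {
  cfg <- utils::modifyList(pipeline_config(), config)
  land <- cfg$landscape
  tel <- cfg$telemetry
  template <- land$elevation
  sy <- season_of(tel$timestamp)
  tel <- cbind(tel, sy[, c("season", "season_year")])

  # minimum-locations filter, per animal x season
  key <- paste(tel$id, tel$season)
  n_by <- table(key)
  keep <- key %in% names(n_by)[n_by >= cfg$min_locations]
  dropped_animals <- length(setdiff(unique(tel$id[!keep]),
                                    unique(tel$id[keep])))
  tel <- tel[keep, , drop = FALSE]
  if (nrow(tel) == 0) stop("no animal passes the minimum-locations filter")

  range_ <- kde_population_range(tel, template, isopleth = cfg$isopleth)
  road_dist <- log_distance(distance_raster(land$roads, template))

  out <- list()
  counts <- list()
  for (s in intersect(c("summer", "winter"), unique(tel$season))) {
    used_pts <- tel[tel$season == s, , drop = FALSE]
    if (is.null(coyote_rpu[[s]])) {
      warning("no predator RPU raster for ", s, "; season skipped")
      next
    }
    avail <- sample_available(range_, nrow(used_pts), cfg$ratio,
                              seed = cfg$seed + 10L +
                                match(s, c("summer", "winter")))
    avail$season_year <- pair_available_sy(used_pts$season_year, cfg$ratio)
    layers <- list(coyote_rpu = coyote_rpu[[s]], prey = cfg$prey,
                   soil = land$soil, road_dist = road_dist)
    used_cov <- extract_covariates(used_pts, layers)
    avail_cov <- extract_covariates(avail, layers)
    screen <- correlation_screen(
      used_cov[, c("coyote_rpu", "prey", "road_dist")],
      threshold = cfg$correlation_threshold)
    design <- build_design(used_cov, avail_cov,
                           categorical_refs = c(soil = "blocky_loam"))
    base_covs <- intersect(c("coyote_rpu", "prey"), screen$retained)
    full_covs <- c(base_covs, "soil",
                   intersect("road_dist", screen$retained))
    model_covs <- list(base = base_covs,
                       soil = c(base_covs, "soil"),
                       full = full_covs)
    fits <- lapply(model_covs, function(cv_) {
      fit_rsf(subset_design(design, cv_))
    })
    comparison <- compare_models(fits)
    full_fit <- fits$full
    cv <- kfold_auc(subset_design(design, full_covs), k = cfg$cv_folds,
                    seed = cfg$seed)
    # residual semivariogram of the full model on a subsample of rows
    coords <- rbind(used_pts[, c("x", "y")], avail[, c("x", "y")])
    p <- full_fit$fitted
    resid <- (design$data$case - p) / sqrt(p * (1 - p))
    idx <- seq_len(nrow(design$data))
    if (length(idx) > 1200L) {
      set.seed(cfg$seed)
      idx <- sort(sample(idx, 1200L))
    }
    sv <- residual_semivariogram(resid[idx], coords[idx, , drop = FALSE])
    out[[s]] <- list(fits = fits, comparison = comparison,
                     ci = wald_ci(full_fit), cv = cv,
                     semivariogram = sv, screen = screen, design = design)
    counts[[s]] <- list(n_animals = length(unique(used_pts$id)),
                        n_used = design$n_used,
                        n_available = design$n_available,
                        n_dropped_rows = design$n_dropped)
  }
  list(seasons = out, range = range_,
       counts = c(counts, list(animals_excluded = dropped_animals)))
}

#' Write run artifacts to disk
#'
#' Serializes coefficient tables, model comparisons, CV results and rasters,
#' plus a JSON sidecar with likelihoods and convergence and a
#' machine-readable manifest of every output file with its MD5 hash.
#'
#' @param coyote result of [run_coyote_stage()] (or NULL).
#' @param kitfox result of [run_kitfox_stage()] (or NULL).
#' @param out_dir output directory; refuses to overwrite an existing
#'   non-empty directory unless `force = TRUE`.
#' @param seed seed recorded in the sidecar.
#' @param force overwrite existing outputs.
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
report <- function(coyote = NULL, kitfox = NULL, out_dir, seed = NA,
                   force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory ", out_dir,
         " already has contents; use force = TRUE to overwrite")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  sidecar <- list(seed = seed)
  if (!is.null(coyote)) {
    for (s in names(coyote$seasons)) {
      st <- coyote$seasons[[s]]
      put_csv(wald_ci(st$fit), sprintf("coyote_%s_coefficients.csv", s))
      p <- file.path(out_dir, sprintf("coyote_%s_rpu.asc", s))
      write_esri_ascii(st$rpu, p); files <- c(files, p)
      sidecar[[paste0("coyote_", s)]] <- list(
        log_likelihood = st$fit$log_likelihood, k = st$fit$k,
        n_used = st$fit$n_used, n_available = st$fit$n_available,
        converged = st$fit$converged, mean_auc = st$cv$mean_auc,
        auc_band = st$cv$band)
    }
  }
  if (!is.null(kitfox)) {
    for (s in names(kitfox$seasons)) {
      st <- kitfox$seasons[[s]]
      put_csv(st$ci, sprintf("kitfox_%s_coefficients.csv", s))
      put_csv(as.data.frame(st$comparison),
              sprintf("kitfox_%s_model_comparison.csv", s))
      put_csv(data.frame(fold = seq_along(st$cv$fold_auc),
                         auc = st$cv$fold_auc),
              sprintf("kitfox_%s_cv.csv", s))
      put_csv(st$semivariogram, sprintf("kitfox_%s_semivariogram.csv", s))
      sidecar[[paste0("kitfox_", s)]] <- list(
        best_model = attr(st$comparison, "best"),
        decisive = attr(st$comparison, "decisive"),
        mean_auc = st$cv$mean_auc, auc_band = st$cv$band)
    }
  }
  sp <- file.path(out_dir, "run_sidecar.json")
  jsonlite::write_json(sidecar, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, sp)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
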