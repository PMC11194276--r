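# shared fixtures: everything is generated in code at test time

study_mixture <- c(desert_scrub = 0.313, grassland = 0.211, sagebrush = 0.174,
                   forest = 0.148, barren = 0.109, shrubland = 0.042,
                   developed = 0.003)

small_landscape <- function(seed = 11, n = 80, cell = 100) {
  generate_landscape(list(n_rows = n, n_cols = n, cell_size = cell,
                          veg_mixture = study_mixture),
                     seed = seed)
}

uniform_mask <- function(template) {
  raster_apply(template, function(v) v * 0 + 1)
}

# binary layer: left half of the columns 1, right half 0
binary_layer <- function(template) {
  nc <- ncol(template$values)
  v <- matrix(0, nrow(template$values), nc)
  v[, seq_len(nc %/% 2)] <- 1
  grid_raster(v, template$cell_size, template$origin)
}

# simulate telemetry from known beta, assemble a 10:1 design and fit
recovery_fit <- function(layers, beta, n_used, seed, ratio = 10,
                         refs = c(soil = "blocky_loam",
                                  vegetation = "barren"),
                         sim_layers = layers) {
  tel <- simulate_telemetry(sim_layers, beta, n_used, seed = seed)
  used <- extract_covariates(data.frame(x = tel$x, y = tel$y), layers)
  mask <- uniform_mask(layers[[1]])
  av <- sample_available(mask, n_used, ratio, seed = seed + 100000L)
  avail <- extract_covariates(av, layers)
  design <- build_design(used, avail, categorical_refs = refs)
  list(design = design, fit = fit_rsf(design))
}

# telemetry for one animal within one season-year: fixes are spaced so the
# whole batch stays inside the six-month season window
season_telemetry <- function(layers, beta, n, season, year, seed,
                             id = "a1", species = "animal") {
  start <- if (season == "summer") sprintf("%d-04-05 00:00:00", year)
  else sprintf("%d-10-05 00:00:00", year)
  interval <- max(1, floor(170 * 24 / max(n, 1)))
  simulate_telemetry(layers, beta, n, seed = seed, id = id,
                     species = species, start = start,
                     interval_hours = interval)
}

# a ready-made synthetic study: landscape, prey rasters for 2011-2012 and
# the covariate layers both pipeline stages consume
make_study <- function(seed = 101, n = 60) {
  L <- small_landscape(seed = seed, n = n)
  tp <- truth_parameters()
  grids <- stats::setNames(
    rep(c("barren", "desert_scrub", "forest", "grassland", "sagebrush",
          "shrubland"), length.out = 16), paste0("g", 1:16))
  sessions <- expand.grid(year = 2011:2012, session = c("early", "late"))
  trap <- simulate_trapping(tp$veg_capture_means, grids, sessions,
                            seed = seed + 1)
  transects <- expand.grid(transect_id = paste0("t", 1:8),
                           vegetation = c("barren", "desert_scrub",
                                          "developed", "grassland",
                                          "sagebrush", "shrubland"))
  transects$availability <- 0.15
  surveys <- expand.grid(year = 2011:2012, season = c("summer", "winter"))
  spot <- simulate_spotlight(tp$veg_leporid_rates, transects, surveys,
                             seed = seed + 2)
  prey <- build_prey_rasters(trap, spot, transects, L$vegetation)$prey
  list(landscape = L, prey = prey, truth = tp,
       season_years = names(prey))
}

# coyote telemetry across all season-years from the truth coefficients
study_coyote_telemetry <- function(study, n_per_sy = 250, seed = 400) {
  L <- study$landscape
  road <- log_distance(distance_raster(L$roads, L$elevation))
  water <- log_distance(distance_raster(L$water, L$elevation))
  elev <- center_scale(L$elevation)
  b <- study$truth$beta_coyote
  out <- list()
  for (sy in study$season_years) {
    parts <- strsplit(sy, "_")[[1]]
    lay <- list(prey = study$prey[[sy]], elevation = elev,
                road_dist = road, water_dist = water)
    out[[sy]] <- season_telemetry(
      lay, c(prey = unname(b["prey"]), elevation = unname(b["elevation"]),
             road_dist = unname(b["road_dist"]),
             water_dist = unname(b["water_dist"])),
      n_per_sy, parts[1], as.integer(parts[2]),
      seed = seed + match(sy, study$season_years), id = "c1",
      species = "coyote")
  }
  do.call(rbind, out)
}

# binomial log-likelihood of a design at arbitrary coefficients
design_loglik <- function(design, beta) {
  df <- design$data
  X <- stats::model.matrix(igprsf:::design_formula(design), df)
  eta <- drop(X %*% beta[colnames(X)])
  sum(df$case * eta - log1p(exp(eta)))
}
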