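#!/usr/bin/env Rscript
# Stage 1 — simulate the study system.
#
# Generates a synthetic Great Basin cold-desert landscape with the study
# area's vegetation mixture, known ("truth") selection coefficients, two
# years of small-mammal trapping (16 grids x 2 sessions/yr) and leporid
# spotlight surveys, coyote GPS telemetry (one collared animal per
# season-year batch, 4-h fixes) and kit fox VHF telemetry (6 animals,
# >= 30 locations per season). Everything downstream is checkable against
# the truth parameters written alongside.

suppressPackageStartupMessages(library(igprsf))
seed <- 20260920L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

land <- generate_landscape(list(
  n_rows = 100, n_cols = 100, cell_size = 100,
  veg_mixture = c(desert_scrub = 0.313, grassland = 0.211, sagebrush = 0.174,
                  forest = 0.148, barren = 0.109, shrubland = 0.042,
                  developed = 0.003)), seed = seed)
write_landscape(land, file.path(out, "landscape"))

truth <- truth_parameters(seed = seed)
write_truth_yaml(truth, file.path(out, "truth.yaml"))

grids <- stats::setNames(
  rep(c("barren", "desert_scrub", "forest", "grassland", "sagebrush",
        "shrubland"), length.out = 16), paste0("g", 1:16))
sessions <- expand.grid(year = 2011:2012, session = c("early", "late"))
trapping <- simulate_trapping(truth$veg_capture_means, grids, sessions,
                              seed = seed + 1L)
write.csv(trapping, file.path(out, "trapping.csv"), row.names = FALSE)

transects <- expand.grid(transect_id = paste0("t", 1:8),
                         vegetation = c("barren", "desert_scrub", "developed",
                                        "grassland", "sagebrush", "shrubland"))
transects$availability <- 0.15
surveys <- expand.grid(year = 2011:2012, season = c("summer", "winter"))
spotlight <- simulate_spotlight(truth$veg_leporid_rates, transects, surveys,
                                seed = seed + 2L)
write.csv(transects, file.path(out, "transects.csv"), row.names = FALSE)
write.csv(spotlight, file.path(out, "spotlight.csv"), row.names = FALSE)

# telemetry is drawn from the truth RSFs over the (not-yet-built) prey
# layer, so build it here exactly as stage 2 will
prey <- build_prey_rasters(trapping, spotlight, transects,
                           land$vegetation)$prey
road <- log_distance(distance_raster(land$roads, land$elevation))
water <- log_distance(distance_raster(land$water, land$elevation))
elev <- center_scale(land$elevation)
soil_ind <- indicator_layers(land$soil, reference = "blocky_loam",
                             prefix = "soil_")

season_tel <- function(layers, beta, n, season, year, s, id, species) {
  start <- sprintf("%d-%s 00:00:00", year,
                   if (season == "summer") "04-05" else "10-05")
  simulate_telemetry(layers, beta, n, seed = s, id = id, species = species,
                     start = start,
                     interval_hours = max(1, floor(170 * 24 / n)))
}

bc <- truth$beta_coyote
coyote_tel <- do.call(rbind, lapply(seq_along(prey), function(i) {
  p <- strsplit(names(prey)[i], "_")[[1]]
  season_tel(list(prey = prey[[i]], elevation = elev, road_dist = road,
                  water_dist = water),
             c(prey = unname(bc["prey"]), elevation = unname(bc["elevation"]),
               road_dist = unname(bc["road_dist"]),
               water_dist = unname(bc["water_dist"])),
             400, p[1], as.integer(p[2]), seed + 100L + i, "c1", "coyote")
}))
write_telemetry(coyote_tel, file.path(out, "telemetry_coyote.csv"))

# fox telemetry needs the coyote RPU surface; at simulation time the truth
# surface is exp(beta_coyote' x), max-normalized like the fitted one
rpu_truth <- lapply(c(summer = "summer", winter = "winter"), function(s) {
  sy <- names(prey)[grepl(paste0("^", s), names(prey))]
  prey_mean <- Reduce(function(a, b) raster_apply(a, function(v)
    (v + b$values)), prey[sy][-1], prey[sy][[1]])
  prey_mean <- raster_apply(prey_mean, function(v) v / length(sy))
  eta <- bc[["prey"]] * prey_mean$values + bc[["elevation"]] * elev$values +
    bc[["road_dist"]] * road$values + bc[["water_dist"]] * water$values
  raster_apply(elev, function(v) exp(eta) / max(exp(eta), na.rm = TRUE))
})

fox_tel <- do.call(rbind, lapply(seq_along(prey), function(i) {
  p <- strsplit(names(prey)[i], "_")[[1]]
  b <- if (p[1] == "summer") truth$beta_fox_summer else truth$beta_fox_winter
  lay <- c(list(coyote_rpu = rpu_truth[[p[1]]], prey = prey[[i]],
                road_dist = road), soil_ind)
  do.call(rbind, lapply(1:6, function(a) {
    season_tel(lay, b, 180, p[1], as.integer(p[2]),
               seed + 200L + 31L * a + i, paste0("f", a), "kit fox")
  }))
}))
write_telemetry(fox_tel, file.path(out, "telemetry_fox.csv"))

cat(sprintf(
  "simulated: %d veg classes on a %d x %d grid; %d trapping records; %d sightings;\n%d coyote fixes; %d fox fixes (6 animals) -> %s\n",
  length(unique(as.vector(land$vegetation$values))), 100, 100, nrow(trapping),
  nrow(spotlight), nrow(coyote_tel), nrow(fox_tel), out))
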