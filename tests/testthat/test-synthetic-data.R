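test_that("generated landscapes match the requested class mixture", {
  L <- generate_landscape(list(n_rows = 120, n_cols = 120, cell_size = 100,
                               veg_mixture = study_mixture), seed = 42)
  freq <- table(factor(L$vegetation$levels[L$vegetation$values],
                       levels = names(study_mixture))) / (120 * 120)
  expect_true(all(abs(as.numeric(freq) - unname(study_mixture)) <= 0.03))
  # aligned geometry across all layers
  expect_true(rasters_aligned(L$vegetation, L$soil))
  expect_true(rasters_aligned(L$vegetation, L$elevation))
  expect_true(all(is.finite(L$elevation$values)))
  expect_true(all(L$soil$values %in% seq_along(L$soil$levels)))
})

test_that("degenerate mixture and determinism contracts hold", {
  L1 <- generate_landscape(list(n_rows = 30, n_cols = 30, cell_size = 50,
                                veg_mixture = c(desert_scrub = 1)), seed = 3)
  expect_true(all(L1$vegetation$levels[L1$vegetation$values] == "desert_scrub"))

  cfg <- list(n_rows = 40, n_cols = 40, cell_size = 50,
              veg_mixture = c(grassland = 0.5, forest = 0.5))
  La <- generate_landscape(cfg, seed = 9)
  Lb <- generate_landscape(cfg, seed = 9)
  expect_identical(La$vegetation$values, Lb$vegetation$values)
  expect_identical(La$elevation$values, Lb$elevation$values)
  expect_identical(La$roads, Lb$roads)
})

test_that("landscape configuration errors are caught", {
  expect_error(generate_landscape(list(n_rows = 0, n_cols = 10, cell_size = 1,
                                       veg_mixture = c(barren = 1))),
               "dimensions")
  expect_error(generate_landscape(list(n_rows = 10, n_cols = 10, cell_size = 1,
                                       veg_mixture = c(tundra = 1))),
               "unknown vegetation class")
  expect_error(generate_landscape(list(n_rows = 10, n_cols = 10, cell_size = 1,
                                       veg_mixture = c(barren = 0.7))),
               "sum to 1")
})

test_that("telemetry with zero coefficients is uniform over cells", {
  tmpl <- grid_raster(matrix(0, 20, 20), 100)
  z <- uniform_mask(tmpl)
  tel <- simulate_telemetry(list(z = z), c(z = 0), 10000, seed = 21)
  rc <- xy_to_cell(tmpl, tel$x, tel$y)
  counts <- table(factor(rc$row, levels = 1:20),
                  factor(rc$col, levels = 1:20))
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("telemetry cell intensity is proportional to exp(beta x)", {
  tmpl <- grid_raster(matrix(0, 100, 100), 100)
  z <- binary_layer(tmpl)
  tel <- simulate_telemetry(list(z = z), c(z = 1), 20000, seed = 7)
  frac1 <- mean(raster_lookup(z, tel$x, tel$y) == 1)
  expect_lt(abs(frac1 - exp(1) / (exp(1) + 1)), 0.01)
})

test_that("telemetry table contract: schema, mask, determinism, errors", {
  tmpl <- grid_raster(matrix(0, 10, 10), 10)
  z <- uniform_mask(tmpl)
  empty <- simulate_telemetry(list(z = z), c(z = 0), 0, seed = 1)
  expect_named(empty, c("id", "species", "timestamp", "x", "y"))
  expect_equal(nrow(empty), 0)

  mask <- matrix(FALSE, 10, 10); mask[1:3, 1:3] <- TRUE
  tel <- simulate_telemetry(list(z = z), c(z = 0), 500, mask = mask, seed = 5)
  rc <- xy_to_cell(tmpl, tel$x, tel$y)
  expect_true(all(rc$row <= 3 & rc$col <= 3))

  t1 <- simulate_telemetry(list(z = z), c(z = 0), 50, seed = 8)
  t2 <- simulate_telemetry(list(z = z), c(z = 0), 50, seed = 8)
  expect_identical(t1, t2)
  expect_error(simulate_telemetry(list(z = z), c(w = 1), 10),
               "missing covariate")
})

test_that("trapping counts are Poisson around the vegetation means", {
  grids <- stats::setNames(rep("desert_scrub", 1), "g1")
  sessions <- data.frame(year = rep(2011, 1000), session = "early")
  rec <- simulate_trapping(c(desert_scrub = 18.6), grids, sessions, seed = 2)
  expect_equal(nrow(rec), 1000)
  expect_lt(abs(mean(rec$count) - 18.6), 0.5)

  zero <- simulate_trapping(c(barren = 0), c(g1 = "barren"),
                            data.frame(year = 2011, session = "late"),
                            seed = 1)
  expect_true(all(zero$count == 0))
  r1 <- simulate_trapping(c(barren = 4), c(g1 = "barren"), sessions, seed = 3)
  r2 <- simulate_trapping(c(barren = 4), c(g1 = "barren"), sessions, seed = 3)
  expect_identical(r1, r2)
  expect_error(simulate_trapping(c(barren = 4), c(g1 = "lava"), sessions),
               "unknown vegetation class")
})

test_that("spotlight sightings follow rate x availability x effort", {
  transects <- data.frame(transect_id = "t1",
                          vegetation = c("desert_scrub", "grassland"),
                          availability = c(0.5, 0.3))
  # expected nightly total 4.1*0.5 + 3.4*0.3 = 3.07 leporids/transect/night
  rates <- c(desert_scrub = 4.1, grassland = 3.4)
  surveys <- data.frame(year = seq_len(500), season = "summer")
  s <- simulate_spotlight(rates, transects, surveys, nights = 3, seed = 12)
  nightly <- nrow(s) / (500 * 3)
  expect_lt(abs(nightly - 3.07) / 3.07, 0.1)
  expect_true(all(s$vegetation %in% c("desert_scrub", "grassland")))

  none <- simulate_spotlight(c(desert_scrub = 0, grassland = 0), transects,
                             surveys[1:5, ], seed = 1)
  expect_equal(nrow(none), 0)
  # unavailable class is never sighted
  tr0 <- data.frame(transect_id = "t1",
                    vegetation = c("desert_scrub", "sagebrush"),
                    availability = c(0.9, 0))
  s0 <- simulate_spotlight(c(desert_scrub = 2, sagebrush = 50), tr0,
                           surveys[1:50, ], seed = 4)
  expect_false("sagebrush" %in% s0$vegetation)
  expect_error(simulate_spotlight(c(desert_scrub = -1), transects, surveys),
               "negative rate")
})

test_that("truth parameters round-trip through YAML", {
  tp <- truth_parameters(seed = 77)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(tp, p)
  tp2 <- read_truth_yaml(p)
  expect_equal(tp2$beta_coyote, tp$beta_coyote)
  expect_equal(tp2$veg_capture_means, tp$veg_capture_means)
  expect_equal(tp2$seed, 77L)
})

test_that("RSF fitting recovers simulated coefficients within 2 SE", {
  # end-to-end recovery property: >= 90% of replicates within 2 SE at
  # n_used = 2000
  L <- small_landscape(seed = 31, n = 60)
  layers <- list(elevation = center_scale(L$elevation),
                 z = binary_layer(L$elevation))
  truth <- c(elevation = -0.6, z = 0.8)
  seeds <- 5000 + seq_len(100)
  hit <- vapply(seeds, function(sd) {
    r <- recovery_fit(layers, truth, n_used = 2000, seed = sd)
    ci <- wald_ci(r$fit)
    i <- match(names(truth), ci$term)
    all(abs(ci$estimate[i] - truth) <= 2 * ci$se[i])
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})
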