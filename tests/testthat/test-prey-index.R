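# independent oracle for the quartile ranking: hand-rolled type-7 quantile
# interpolation plus the <=Q rule, written without quantile()/findInterval
oracle_quartile <- function(values, pool = values) {
  s <- sort(pool[is.finite(pool)])
  n <- length(s)
  qat <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h) + 1
    if (lo >= n) return(s[n])
    s[lo] + (h - floor(h)) * (s[lo + 1] - s[lo])
  }
  q <- c(qat(0.25), qat(0.5), qat(0.75))
  vapply(values, function(v) {
    if (is.na(v)) return(NA_integer_)
    if (v <= q[1]) 1L else if (v <= q[2]) 2L else if (v <= q[3]) 3L else 4L
  }, 1L)
}

test_that("capture summaries are mean individuals per grid", {
  rec <- data.frame(
    grid_id = c("g1", "g2", "g3", "g1", "g2", "g3"),
    vegetation = c("forest", "forest", "barren", "forest", "forest", "barren"),
    year = 2011,
    session = rep(c("early", "late"), each = 3),
    count = c(12, 24, 59, 0, 0, 0))
  s <- summarize_captures(rec)
  expect_equal(s$value[s$vegetation == "forest" & s$season == "summer"], 18)
  expect_equal(s$value[s$vegetation == "barren" & s$season == "summer"], 59)
  expect_equal(s$value[s$season == "winter"], c(0, 0))
  expect_equal(unique(s$season_year[s$season == "winter"]), "winter_2011")
  empty <- summarize_captures(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("leporid standardization reproduces the worked example", {
  idx <- standardize_leporids(
    c(desert_scrub = 40, grassland = 7, sagebrush = 5),
    c(desert_scrub = 50, grassland = 30, sagebrush = 10))
  expect_equal(unname(idx), c(0.8, 7 / 30, 0.5))
  # ratio invariance when counts and availability double
  idx2 <- standardize_leporids(
    c(desert_scrub = 80, grassland = 14, sagebrush = 10),
    c(desert_scrub = 100, grassland = 60, sagebrush = 20))
  expect_equal(unname(idx2), unname(idx))
  expect_equal(unname(standardize_leporids(c(barren = 0), c(barren = 30))), 0)
  expect_true(is.na(standardize_leporids(c(forest = 0), c(forest = 0))))
  expect_error(standardize_leporids(c(forest = 3), c(forest = 0)),
               "data-consistency")
})

test_that("quartile ranks follow the pooled <= Q1/Q2/Q3 rule", {
  expect_equal(as.integer(quartile_rank(1:8)), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(as.integer(quartile_rank(rep(5, 6))), rep(1L, 6))
  # printed small-mammal cuts: pool with quartiles exactly (9, 17, 25)
  pool <- c(1, 9, 17, 25, 33)
  r <- quartile_rank(18.6, pool = pool)
  expect_equal(attr(r, "thresholds"), c(9, 17, 25))
  expect_equal(as.integer(r), 3L)
  expect_error(quartile_rank(NA_real_), "finite")
})

test_that("quartile ranking matches the brute-force oracle on random input", {
  set.seed(99)
  for (i in 1:1000) {
    v <- switch(1 + i %% 4,
                rnorm(sample(4:40, 1)),
                rpois(sample(4:40, 1), 5),
                runif(sample(2:10, 1)) * 100,
                round(rnorm(sample(4:30, 1)), 1))  # ties likely
    expect_identical(as.integer(quartile_rank(v)), oracle_quartile(v))
  }
})

test_that("quartile ranking is monotone", {
  set.seed(7)
  for (i in 1:50) {
    v <- rnorm(30)
    r <- as.integer(quartile_rank(v))
    o <- order(v)
    expect_true(all(diff(r[o]) >= 0))
  }
})

test_that("vegetation reclassification maps classes to ranks, else NA", {
  v <- matrix(c(4, 4, 9, NA), 2, 2)
  veg <- grid_raster(v, 1, levels = igprsf:::VEG_CLASSES)
  r <- reclassify_vegetation(veg, c(forest = 4))
  expect_equal(r$values, matrix(c(4, 4, NA, NA), 2, 2))  # riparian unranked
  # ranking-object interface selects the season-year column
  tab <- data.frame(vegetation = "forest", season = "summer", year = 2011,
                    season_year = "summer_2011", value = 30)
  rk <- rank_abundance(tab, "small_mammal")
  r2 <- reclassify_vegetation(veg, rk, "summer_2011")
  expect_equal(r2$values[1, 1], rk$table$rank[1])
})

test_that("prey combination weights ranks 2/3 : 1/3 with NA fallback", {
  sm <- grid_raster(matrix(c(3, 4, 2, NA), 2, 2), 1)
  lep <- grid_raster(matrix(c(3, 1, NA, NA), 2, 2), 1)
  prey <- combine_prey(sm, lep)
  expect_equal(prey$values[1, 1], 3)
  expect_equal(prey$values[2, 1], 2 / 3 * 4 + 1 / 3 * 1)  # = 3
  expect_equal(prey$values[1, 2], 2)          # single-source fallback
  expect_true(is.na(prey$values[2, 2]))
  strict <- combine_prey(sm, lep, strict = TRUE)
  expect_true(is.na(strict$values[1, 2]))
  # bounded in [1, 4] wherever defined
  set.seed(1)
  a <- grid_raster(matrix(sample(1:4, 100, TRUE), 10, 10), 1)
  b <- grid_raster(matrix(sample(1:4, 100, TRUE), 10, 10), 1)
  p <- combine_prey(a, b)
  expect_true(all(p$values >= 1 & p$values <= 4))
  expect_equal(p$values, 2 / 3 * a$values + 1 / 3 * b$values)
  shifted <- grid_raster(matrix(1, 2, 2), 1, origin = c(5, 5))
  expect_error(combine_prey(sm, shifted), "alignment")
  expect_error(combine_prey(sm, lep, weights = c(0.5, 0.3)), "sum to 1")
})

test_that("full prey chain: surveys to seasonal rasters in [1, 4]", {
  L <- small_landscape(seed = 15, n = 40)
  tp <- truth_parameters()
  grids <- stats::setNames(
    rep(c("barren", "desert_scrub", "forest", "grassland", "sagebrush",
          "shrubland"), length.out = 16), paste0("g", 1:16))
  sessions <- expand.grid(year = 2011:2012, session = c("early", "late"))
  trap <- simulate_trapping(tp$veg_capture_means, grids, sessions, seed = 5)
  transects <- expand.grid(transect_id = paste0("t", 1:8),
                           vegetation = c("barren", "desert_scrub",
                                          "grassland", "sagebrush"))
  transects$availability <- 0.22
  surveys <- expand.grid(year = 2011:2012, season = c("summer", "winter"))
  spot <- simulate_spotlight(tp$veg_leporid_rates, transects, surveys,
                             seed = 6)
  pr <- build_prey_rasters(trap, spot, transects, L$vegetation)
  expect_setequal(names(pr$prey),
                  c("summer_2011", "winter_2011", "summer_2012",
                    "winter_2012"))
  vals <- pr$prey$summer_2011$values
  expect_true(all(vals[!is.na(vals)] >= 1 & vals[!is.na(vals)] <= 4))
  # every ranked class present in the input got a rank
  expect_false(any(is.na(pr$rank_sm$table$rank)))
  expect_true(all(pr$rank_sm$table$rank %in% 1:4))
})
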