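test_that("design assembly: reference coding, ratio, dropped rows", {
  set.seed(8)
  soil_lv <- c("silt", "fine_sand", "gravel", "blocky_loam")
  used <- data.frame(soil = sample(soil_lv, 100, TRUE))
  avail <- data.frame(soil = sample(soil_lv, 1000, TRUE))
  d <- build_design(used, avail)
  expect_equal(nrow(d$data), 1100)
  expect_equal(d$n_available / d$n_used, 10)
  expect_equal(levels(d$data$soil)[1], "blocky_loam")
  fit <- fit_rsf(d)
  # 3 soil indicators + intercept
  expect_equal(fit$k, 4)
  expect_setequal(names(fit$beta),
                  c("(Intercept)", "soilsilt", "soilfine_sand", "soilgravel"))

  expect_error(build_design(used, avail[0, , drop = FALSE]), "zero available")
  expect_error(build_design(data.frame(soil = "peat"),
                            data.frame(soil = c("silt", "gravel"))),
               "inestimable")
  expect_error(build_design(data.frame(a = 1), data.frame(b = 1)),
               "schema mismatch")

  # NA-flagged rows are dropped and counted
  used_na <- data.frame(z = c(1, NA, 2), .any_na = c(FALSE, TRUE, FALSE))
  avail_ok <- data.frame(z = rnorm(30), .any_na = FALSE)
  d2 <- build_design(used_na, avail_ok)
  expect_equal(d2$n_dropped, 1)
  expect_equal(d2$n_used, 2)
})

test_that("row order does not change the fitted model", {
  set.seed(5)
  used <- data.frame(z = rnorm(200, 1))
  avail <- data.frame(z = rnorm(2000))
  f1 <- fit_rsf(build_design(used, avail))
  perm <- function(df) df[sample(nrow(df)), , drop = FALSE]
  f2 <- fit_rsf(build_design(perm(used), perm(avail)))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-10)
})

test_that("single-binary design reproduces the closed-form slope ln 4", {
  used <- data.frame(z = rep(c(1, 0), c(80, 20)))
  avail <- data.frame(z = rep(c(1, 0), c(500, 500)))
  fit <- fit_rsf(build_design(used, avail))
  expect_lt(abs(fit$beta[["z"]] - log(4)), 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-6)
})

test_that("degenerate designs are rejected with informative errors", {
  used <- data.frame(z = rep(1, 50))
  avail <- data.frame(z = rep(1, 500))
  expect_error(fit_rsf(build_design(used, avail)), "constant column")
  # perfect separation: used and available never overlap in z
  sep <- build_design(data.frame(z = rep(1, 100)),
                      data.frame(z = rep(c(0, 1), c(900, 100)) * 0))
  expect_error(fit_rsf(sep), "separation|constant")
})

test_that("duplicating every row keeps beta and shrinks SEs by sqrt(2)", {
  set.seed(6)
  used <- data.frame(z = rnorm(150, 0.8))
  avail <- data.frame(z = rnorm(1500))
  d1 <- build_design(used, avail)
  d2 <- build_design(rbind(used, used), rbind(avail, avail))
  f1 <- fit_rsf(d1); f2 <- fit_rsf(d2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  se1 <- sqrt(diag(f1$vcov)); se2 <- sqrt(diag(f2$vcov))
  expect_equal(unname(se1 / se2), rep(sqrt(2), 2), tolerance = 1e-6)
  expect_equal(f2$log_likelihood, 2 * f1$log_likelihood, tolerance = 1e-8)
})

test_that("likelihood at the fitted beta dominates the truth", {
  L <- small_landscape(seed = 23, n = 50)
  layers <- list(elevation = center_scale(L$elevation),
                 z = binary_layer(L$elevation))
  truth <- c(elevation = -0.5, z = 0.7)
  for (s in 1:5) {
    r <- recovery_fit(layers, truth, n_used = 500, seed = 300 + s)
    beta_truth <- r$fit$beta
    beta_truth[names(truth)] <- truth
    expect_gte(design_loglik(r$design, r$fit$beta),
               design_loglik(r$design, beta_truth))
  }
})

test_that("Wald intervals match the closed arithmetic and nest by level", {
  fit <- structure(list(beta = c(coyote_rpu = 0.14),
                        vcov = matrix(0.0128^2, 1, 1,
                                      dimnames = list("coyote_rpu",
                                                      "coyote_rpu")),
                        converged = TRUE),
                   class = "rsf_fit")
  ci <- wald_ci(fit)
  expect_equal(ci$lower, 0.14 - qnorm(0.975) * 0.0128, tolerance = 1e-10)
  expect_equal(round(ci$lower, 3), 0.115)
  expect_equal(round(ci$upper, 3), 0.165)
  expect_true(ci$significant)

  fit$beta <- c(coyote_rpu = 0)
  ci0 <- wald_ci(fit)
  expect_equal(ci0$lower, -ci0$upper)
  expect_false(ci0$significant)

  ci99 <- wald_ci(fit, level = 0.99)
  expect_lt(ci99$lower, ci0$lower)
  expect_gt(ci99$upper, ci0$upper)
})

test_that("RPU prediction is exp(beta x) excluding the intercept", {
  set.seed(12)
  n <- 10
  z1 <- grid_raster(matrix(rnorm(n * n), n, n), 50)
  z2 <- grid_raster(matrix(rnorm(n * n), n, n), 50)
  soil <- grid_raster(matrix(sample(1:4, n * n, TRUE), n, n), 50,
                      levels = igprsf:::SOIL_CLASSES)
  used <- extract_covariates(
    as.data.frame(sample_available(uniform_mask(z1), 40, 10, seed = 1)),
    list(z1 = z1, z2 = z2, soil = soil))
  avail <- extract_covariates(
    as.data.frame(sample_available(uniform_mask(z1), 400, 10, seed = 2)),
    list(z1 = z1, z2 = z2, soil = soil))
  fit <- fit_rsf(build_design(used, avail))
  rpu <- predict_rpu(fit, list(z1 = z1, z2 = z2, soil = soil))
  # brute-force per-cell recomputation
  b <- fit$beta
  lv <- igprsf:::SOIL_CLASSES
  oracle <- exp(b[["z1"]] * z1$values + b[["z2"]] * z2$values +
                  matrix(vapply(lv[soil$values], function(l) {
                    nm <- paste0("soil", l)
                    if (nm %in% names(b)) b[[nm]] else 0
                  }, 0), n, n))
  expect_equal(rpu$values, oracle, tolerance = 1e-12)
  expect_true(all(rpu$values > 0))
  expect_error(predict_rpu(fit, list(z1 = z1, soil = soil)), "missing layer")
})

test_that("RPU prediction: zero covariates give 1 and log-linearity holds", {
  fit <- structure(list(
    beta = c("(Intercept)" = -2, z = 0.5),
    xlevels = list(),
    transforms = NULL,
    formula = case ~ z), class = "rsf_fit")
  z <- grid_raster(matrix(c(0, 0, 1, 2), 2, 2), 1)
  rpu <- predict_rpu(fit, list(z = z))
  expect_equal(rpu$values[1, 1], 1)              # exp(0), intercept excluded
  expect_equal(rpu$values[2, 2] / rpu$values[1, 2], exp(0.5))
  # strictly monotone in a positively weighted covariate
  ord <- order(z$values)
  expect_true(all(diff(rpu$values[ord]) >= 0))
})

test_that("stored transforms are replayed identically at prediction", {
  fit <- structure(list(
    beta = c("(Intercept)" = 0, road_dist = -0.3, elevation = 0.4),
    xlevels = list(),
    transforms = list(road_dist = "log1p",
                      elevation = list(center = 2000, scale = 500)),
    formula = case ~ road_dist + elevation), class = "rsf_fit")
  road_raw <- grid_raster(matrix(c(0, exp(1) - 1, 10, 100), 2, 2), 1)
  elev_raw <- grid_raster(matrix(c(2000, 2500, 1500, 3000), 2, 2), 1)
  rpu <- predict_rpu(fit, list(road_dist = road_raw, elevation = elev_raw))
  oracle <- exp(-0.3 * log1p(road_raw$values) +
                  0.4 * (elev_raw$values - 2000) / 500)
  expect_equal(rpu$values, oracle)
})

test_that("coefficients are recovered without bias across replicates", {
  L <- small_landscape(seed = 41, n = 50)
  layers <- list(elevation = center_scale(L$elevation),
                 z = binary_layer(L$elevation))
  truth <- c(elevation = -0.6, z = 0.8)
  est <- t(vapply(1:30, function(s) {
    r <- recovery_fit(layers, truth, n_used = 1000, seed = 700 + s)
    r$fit$beta[names(truth)]
  }, c(elevation = 0, z = 0)))
  expect_lt(abs(mean(est[, "elevation"]) - truth["elevation"]), 0.05)
  expect_lt(abs(mean(est[, "z"]) - truth["z"]), 0.05)
})
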