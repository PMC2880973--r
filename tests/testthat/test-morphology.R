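test_that("shape metrics land on closed-form circularities", {
  disc <- shape_metrics(raster_disc(50))
  expect_gte(disc$circularity, 0.90)
  expect_lte(disc$circularity, 1.00)
  sq <- shape_metrics(raster_rect(100, 100))
  expect_equal(sq$circularity, pi / 4, tolerance = 0.03 / (pi / 4))
  rect <- shape_metrics(raster_rect(200, 20))
  expect_equal(rect$circularity, 40 * pi / 484, tolerance = 0.03 / 0.26)
  # elongated shapes have high aspect ratio
  expect_gt(rect$major / rect$minor, 5)
  expect_equal(sq$area, 10000)
})

test_that("circularity is invariant to translation, rotation and scale", {
  m <- raster_rect(60, 24)
  base <- shape_metrics(m)$circularity
  shifted <- cbind(matrix(0L, nrow(m), 7), m)
  expect_equal(shape_metrics(shifted)$circularity, base, tolerance = 1e-12)
  rotated <- t(m)
  expect_equal(shape_metrics(rotated)$circularity, base, tolerance = 1e-12)
  doubled <- raster_rect(120, 48)
  expect_equal(shape_metrics(doubled)$circularity, base, tolerance = 0.05)
  expect_equal(shape_metrics(doubled)$area, 4 * shape_metrics(m)$area)
})

test_that("degenerate masks are rejected", {
  expect_error(shape_metrics(raster_rect(4, 4)), "20 pixels")
  two <- raster_rect(10, 10, pad = 2)
  two2 <- cbind(two, matrix(0L, nrow(two), 3), two)
  expect_error(shape_metrics(two2), "one connected component")
})

test_that("mean intensity is averaged over the mask only", {
  m <- raster_rect(10, 10)
  img <- matrix(7, nrow(m), ncol(m))
  img[m == 0] <- 1000
  expect_equal(shape_metrics(m, img)$mean_intensity, 7)
})

test_that("EM recovers planted mixture parameters", {
  sim <- simulate_morphology(data.frame(w2 = 0.7, mu1 = 0.35, mu2 = 0.85,
                                        sigma1 = 0.08, sigma2 = 0.05),
                             n_cells = 1000, seed = 3)
  fit <- fit_two_component_mixture(sim$cells$circularity)
  expect_equal(fit$w[2], 0.7, tolerance = 0.05 / 0.7)
  expect_lte(abs(fit$mu[1] - 0.35), 0.03)
  expect_lte(abs(fit$mu[2] - 0.85), 0.03)
  expect_lte(fit$mu[1], fit$mu[2])
  expect_true(fit$converged)
})

test_that("single-component data is flagged as degenerate or absorbing", {
  for (s in c(6, 16, 26)) {
    set.seed(s)
    x <- pmin(pmax(stats::rnorm(600, 0.6, 0.06), 1e-3), 1)
    fit <- suppressWarnings(fit_two_component_mixture(x))
    expect_true(max(fit$w) >= 0.95 || fit$overlap)
  }
  # a well-separated planted mixture is not flagged
  sim <- simulate_morphology(data.frame(w2 = 0.5, mu1 = 0.35, mu2 = 0.85,
                                        sigma1 = 0.08, sigma2 = 0.05),
                             n_cells = 600, seed = 2)
  expect_false(fit_two_component_mixture(sim$cells$circularity)$overlap)
})

test_that("EM log-likelihood never decreases and inputs are validated", {
  set.seed(7)
  cases <- list(
    c(stats::rnorm(400, 0.3, 0.05), stats::rnorm(200, 0.8, 0.07)),
    stats::runif(300, 0.1, 0.9),
    c(stats::rnorm(100, 0.5, 0.02), stats::rnorm(500, 0.55, 0.1)))
  for (x in cases) {
    x <- pmin(pmax(x, 1e-3), 1)
    fit <- suppressWarnings(fit_two_component_mixture(x))
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
  expect_error(fit_two_component_mixture(rep(0.5, 100)), "identical")
  expect_error(fit_two_component_mixture(stats::runif(30)), "at least 50")
  expect_warning(fit_two_component_mixture(
    pmin(pmax(stats::rnorm(40, 0.5, 0.2), 1e-3), 1), allow_small = TRUE),
    "only 40")
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  sim <- simulate_morphology(data.frame(w2 = 0.6, mu1 = 0.3, mu2 = 0.8,
                                        sigma1 = 0.07, sigma2 = 0.05),
                             n_cells = 800, seed = 9)
  fit <- fit_two_component_mixture(sim$cells$circularity)
  mc <- Mclust(sim$cells$circularity, G = 2, modelNames = "V",
               verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("population trajectory tracks a planted pulse in the round fraction", {
  tr <- data.frame(w2 = c(0.1, 0.1, 0.4, 0.1, 0.1, 0.1),
                   mu1 = 0.35, mu2 = 0.85, sigma1 = 0.08, sigma2 = 0.05)
  sim <- simulate_morphology(tr, n_cells = 500, seed = 4)
  gc <- simulate_growth_curve(n_points = 6, lag_h = 6)
  traj <- population_trajectory(sim$cells, gc)
  expect_equal(which.max(traj$table$w2), 3)
  expect_true(all(traj$table$mu1 <= traj$table$mu2))
  expect_equal(traj$table$od600, gc$od600)
  # flat trajectory stays flat within tolerance
  tr2 <- data.frame(w2 = 0.3, mu1 = 0.35, mu2 = 0.85,
                    sigma1 = 0.08, sigma2 = 0.05)[rep(1, 6), ]
  sim2 <- simulate_morphology(tr2, n_cells = 500, seed = 5)
  traj2 <- population_trajectory(sim2$cells, gc)
  expect_true(all(abs(traj2$table$w2 - 0.3) <= 0.05))
  # cell order within a timepoint does not matter
  shuf <- sim$cells[sample(nrow(sim$cells)), ]
  traj3 <- population_trajectory(shuf, gc)
  expect_equal(traj3$table, traj$table)
  bad <- sim$cells
  bad$timepoint[1] <- 99
  expect_error(population_trajectory(bad, gc), "missing from growth curve")
})

test_that("gas-vesicle index is the population median", {
  expect_equal(gas_vesicle_index(c(1, 2, 100)), 2)
  expect_equal(gas_vesicle_index(c(1, 3)), 2)
  set.seed(10)
  x <- stats::runif(1001, 50, 200)
  expect_equal(gas_vesicle_index(x), sort(x)[501])
  expect_error(gas_vesicle_index(numeric(0)), "no intensity")
})
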