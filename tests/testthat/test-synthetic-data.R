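test_that("simulated growth starts exactly at the inoculation density", {
  gc <- simulate_growth_curve()
  expect_identical(gc$od600[1], 0.02)
  gc2 <- simulate_growth_curve(od0 = 0.05, lag_h = 12)
  expect_identical(gc2$od600[1], 0.05)
})

test_that("noiseless logistic curves are monotone and bounded", {
  for (lag in c(0, 10)) {
    gc <- simulate_growth_curve(mu_max = 0.3, od_max = 0.9, lag_h = lag,
                                secondary_rise = 0, n_points = 40)
    expect_true(all(diff(gc$od600) >= 0))
    expect_true(all(gc$od600 <= 0.9))
  }
  # a secondary rise can push OD past the logistic ceiling late in growth
  gc2 <- simulate_growth_curve(mu_max = 0.3, od_max = 0.9,
                               secondary_rise = 0.3, n_points = 60)
  expect_gt(max(gc2$od600), 0.95)
  expect_error(simulate_growth_curve(n_points = 3), ">= 4")
  expect_error(simulate_growth_curve(mu_max = -1), "mu_max")
  expect_error(simulate_growth_curve(od0 = 2, od_max = 1), "od0")
})

test_that("expression simulator is deterministic and validates inputs", {
  ph <- study_phases()
  a <- simulate_expression(c(5, 5, 2, 2, 2, 10), ph, seed = 42)
  b <- simulate_expression(c(5, 5, 2, 2, 2, 10), ph, seed = 42)
  expect_identical(a$matrix$log10_ratio, b$matrix$log10_ratio)
  expect_identical(a$matrix$lambda, b$matrix$lambda)
  expect_identical(a$truth$gene_labels, b$truth$gene_labels)
  c2 <- simulate_expression(c(5, 5, 2, 2, 2, 10), ph, seed = 43)
  expect_false(identical(a$matrix$log10_ratio, c2$matrix$log10_ratio))
  expect_error(simulate_expression(c(0, 0, 0, 0, 0, 0), ph), "zero genes")
})

test_that("noise-free archetype templates honour their defining contrasts", {
  ph <- study_phases()
  sim <- simulate_expression(c(10, 10, 5, 5, 5, 0), ph, effect = 1,
                             sigma_add = 1e-4, sigma_mult = 1e-4, seed = 1,
                             with_lambda = FALSE)
  r <- oriented_ratios(sim$matrix)
  phl <- sample_phases(sim$matrix, ph)
  seg <- function(g, p) mean(r[g, phl == p])
  labs <- sim$truth$gene_labels
  for (g in names(labs)[labs == "EXP_HIGH"])
    expect_gt(seg(g, "EXPONENTIAL"), seg(g, "STATIONARY"))
  for (g in names(labs)[labs == "STAT_HIGH"])
    expect_gt(seg(g, "STATIONARY"), seg(g, "EXPONENTIAL"))
  for (g in names(labs)[labs == "TRANSIENT_UP_EXP"]) {
    expect_gt(seg(g, "EXPONENTIAL"), seg(g, "EARLY"))
    expect_gt(seg(g, "EXPONENTIAL"), seg(g, "STATIONARY"))
  }
  for (g in names(labs)[labs == "TRANSIENT_UP_TRANSITION"])
    expect_gt(seg(g, "TRANSITION"), seg(g, "STATIONARY"))
})

test_that("a null-only matrix yields no persistent significant calls", {
  ph <- study_phases()
  sim <- simulate_expression(c(0, 0, 0, 0, 0, 100), ph,
                             sigma_add = 0.05, sigma_mult = 0.05, seed = 7)
  expect_length(persistent_significant_set(sim$matrix, 15, 4), 0)
})

test_that("morphology simulator respects weights and truncation", {
  tr1 <- data.frame(w2 = 0, mu1 = 0.4, mu2 = 0.9, sigma1 = 0.05, sigma2 = 0.05)
  sim <- simulate_morphology(tr1, n_cells = 200, seed = 2)
  expect_true(all(sim$truth$component == 1))
  expect_true(all(abs(sim$cells$circularity - 0.4) < 0.3))
  # empirical component-2 fraction within the 99% binomial interval
  tr2 <- data.frame(w2 = 0.4, mu1 = 0.35, mu2 = 0.85,
                    sigma1 = 0.08, sigma2 = 0.05)
  sim2 <- simulate_morphology(tr2, n_cells = 500, seed = 3)
  k <- sum(sim2$truth$component == 2)
  expect_gte(k, stats::qbinom(0.005, 500, 0.4))
  expect_lte(k, stats::qbinom(0.995, 500, 0.4))
  expect_true(all(sim2$cells$circularity > 0 & sim2$cells$circularity <= 1))
  # perimeter encodes the drawn circularity exactly
  expect_equal(4 * pi * sim2$cells$area / sim2$cells$perimeter^2,
               sim2$cells$circularity, tolerance = 1e-9)
  # low circularity means elongated
  expect_true(cor(sim2$cells$circularity,
                  sim2$cells$major / sim2$cells$minor) < -0.9)
  a <- simulate_morphology(tr2, n_cells = 100, seed = 5)
  b <- simulate_morphology(tr2, n_cells = 100, seed = 5)
  expect_identical(a$cells, b$cells)
  expect_error(simulate_morphology(
    data.frame(w2 = 1.2, mu1 = 0.4, mu2 = 0.9, sigma1 = 0.05, sigma2 = 0.05)),
    "w2")
})

test_that("metabolite simulator plants the requested fold and patterns", {
  sim <- simulate_metabolites(n_features = 20, n_concordant = 4, fold = 4,
                              noise_cv = 0, replicates = 3, seed = 1)
  f <- filter_significant_features(sim$features)
  planted <- f$feature_id %in% sim$truth$concordant
  expect_equal(f$fold[planted], rep(4, 4), tolerance = 1e-9)
  expect_true(all(f$retained[planted]))
  expect_false(any(f$retained[!planted]))
  a <- simulate_metabolites(n_features = 10, n_concordant = 2, seed = 9)
  b <- simulate_metabolites(n_features = 10, n_concordant = 2, seed = 9)
  expect_identical(a$features, b$features)
  expect_error(simulate_metabolites(n_features = 5, n_concordant = 6),
               "exceeds")
  expect_error(simulate_metabolites(replicates = 1), "replicates")
})

test_that("simulators leave the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_growth_curve(noise_sd = 0.05, seed = 1))
  invisible(simulate_metabolites(n_features = 5, n_concordant = 1, seed = 1))
  invisible(simulate_morphology(
    data.frame(w2 = 0.5, mu1 = 0.4, mu2 = 0.8, sigma1 = 0.05, sigma2 = 0.05),
    n_cells = 50, seed = 1))
  expect_identical(.Random.seed, before)
})
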