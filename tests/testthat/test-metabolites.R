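phase_labels6 <- c("EARLY", "EARLY", "EXPONENTIAL", "EXPONENTIAL",
                   "STATIONARY", "STATIONARY")

test_that("phase aggregation standardizes the three-phase profile", {
  # non-logged phase means (1, 0.1, 1) -> (+0.707, -1.414, +0.707)
  em <- tiny_expression_matrix(matrix(log10(c(1, 1, 0.1, 0.1, 1, 1)), 1))
  prof <- phase_aggregate(em, phase_labels6, "VNG0001G")
  expect_equal(unname(prof), c(0.7071, -1.4142, 0.7071), tolerance = 1e-4)
  # averaging two identical genes changes nothing
  em2 <- tiny_expression_matrix(matrix(log10(c(1, 1, 0.1, 0.1, 1, 1)),
                                       2, 6, byrow = TRUE))
  expect_equal(phase_aggregate(em2, phase_labels6, em2$gene_ids), prof)
  # flat profile has no variance to standardize
  flat <- tiny_expression_matrix(matrix(0.5, 1, 6))
  expect_error(phase_aggregate(flat, phase_labels6, "VNG0001G"), "zero variance")
  expect_error(phase_aggregate(em, rep("EARLY", 6), "VNG0001G"),
               "no samples in phase")
})

make_feature <- function(id, early, exponential, stationary) {
  data.frame(feature_id = id, mz = 100, rt_min = 5,
             phase = rep(c("EARLY", "EXPONENTIAL", "STATIONARY"),
                         times = c(length(early), length(exponential),
                                   length(stationary))),
             replicate = c(seq_along(early), seq_along(exponential),
                           seq_along(stationary)),
             abundance = c(early, exponential, stationary))
}

test_that("the significance/fold filter applies both rules", {
  no_change <- make_feature("f1", c(10, 10, 10), c(10, 10, 10), c(10, 10, 10))
  expect_false(filter_significant_features(no_change)$retained)
  # fold exactly 3 with a tiny p-value is retained (inclusive bound)
  at3 <- make_feature("f2", c(1, 1.0001, 0.9999), c(1, 1, 1),
                      c(3.0001, 2.9999, 3))
  row <- filter_significant_features(at3)
  expect_equal(row$fold, 3, tolerance = 1e-9)
  expect_lt(row$p, 1e-4)
  expect_true(row$retained)
  # significant but under 3-fold: rejected
  weak <- make_feature("f3", c(1, 1.001, 0.999), c(1, 1, 1), c(2, 2.001, 1.999))
  expect_false(filter_significant_features(weak)$retained)
  # zero phase mean: infinite fold, passes the fold rule
  zero <- make_feature("f4", c(0, 0, 0), c(1, 1, 1), c(5, 5.01, 4.99))
  expect_message(rz <- filter_significant_features(zero), "zero phase mean")
  expect_true(is.infinite(rz$fold))
  expect_error(filter_significant_features(
    make_feature("f5", c(1, 2), c(1), c(3))), "replicates")
})

test_that("planted concordant features are recovered without false positives", {
  tp <- fp <- numeric(10)
  for (s in 1:10) {
    sim <- simulate_metabolites(n_features = 150, n_concordant = 10,
                                noise_cv = 0.1, seed = s)
    f <- suppressMessages(filter_significant_features(sim$features))
    tp[s] <- sum(f$retained & f$feature_id %in% sim$truth$concordant)
    fp[s] <- sum(f$retained & !f$feature_id %in% sim$truth$concordant)
  }
  # power frozen from a pilot run at these settings: ~8 of 10 on average
  expect_gte(mean(tp), 7)
  expect_gte(stats::median(tp), 8)
  expect_equal(sum(fp), 0)
  # noiseless planted features all pass
  sim0 <- simulate_metabolites(n_features = 30, n_concordant = 5,
                               fold = 4, noise_cv = 0, seed = 1)
  f0 <- filter_significant_features(sim0$features)
  expect_true(all(f0$retained[f0$feature_id %in% sim0$truth$concordant]))
})

test_that("filter thresholds act monotonically", {
  sim <- simulate_metabolites(n_features = 80, n_concordant = 15,
                              fold = 3.5, noise_cv = 0.15, seed = 6)
  base <- suppressMessages(
    filter_significant_features(sim$features, p_threshold = 0.01, min_fold = 2))
  for (pt in c(0.005, 0.001)) {
    tighter <- suppressMessages(
      filter_significant_features(sim$features, p_threshold = pt, min_fold = 2))
    expect_true(all(tighter$feature_id[tighter$retained] %in%
                    base$feature_id[base$retained]))
  }
  for (mf in c(3, 4)) {
    tighter <- suppressMessages(
      filter_significant_features(sim$features, p_threshold = 0.01, min_fold = mf))
    expect_true(all(tighter$feature_id[tighter$retained] %in%
                    base$feature_id[base$retained]))
  }
})

test_that("concordance scoring is a bounded symmetric correlation", {
  expect_equal(concordance_score(c(1, 0.1, 1), c(1, 0.1, 1)), 1)
  expect_equal(concordance_score(c(1, 0.1, 1), -c(1, 0.1, 1)), -1)
  expect_equal(concordance_score(c(1, 0, 1), c(0, 0.5, 1)), 0)
  a <- c(2, -1, 0.5); b <- c(0, 1, 3)
  expect_equal(concordance_score(a, b), concordance_score(b, a))
  expect_equal(concordance_score(5 * a - 2, b), concordance_score(a, b))
  expect_error(concordance_score(c(1, 1, 1), b), "zero-variance")
  expect_error(concordance_score(c(1, 2), b), "3 finite")
})

test_that("a matching gene group outscores a monotone comparator on a pulse", {
  # metabolite high-low-high; matching gene group shares the shape,
  # the comparator increases monotonically through growth
  sim <- simulate_metabolites(n_features = 20, n_concordant = 3,
                              gene_group_profile = c(1, 0.2, 1),
                              fold = 1, noise_cv = 0, seed = 2)
  met <- metabolite_profile(sim$features, sim$truth$concordant[1])
  matching <- c(1, 0.2, 1)
  comparator <- c(0.5, 1, 2)
  expect_equal(concordance_score(met, matching), 1, tolerance = 1e-9)
  expect_gt(concordance_score(met, matching),
            concordance_score(met, comparator))
  # still holds under modest noise
  simn <- simulate_metabolites(n_features = 20, n_concordant = 3,
                               gene_group_profile = c(1, 0.2, 1),
                               fold = 1, noise_cv = 0.1, seed = 3)
  metn <- metabolite_profile(simn$features, simn$truth$concordant[1])
  expect_gt(concordance_score(metn, matching),
            concordance_score(metn, comparator))
})
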