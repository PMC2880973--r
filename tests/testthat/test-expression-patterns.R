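test_that("row normalization centers and scales with population sd", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("g1", NULL))
  expect_equal(unname(row_normalize(m)[1, ]),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotence
  n1 <- row_normalize(m)
  expect_equal(row_normalize(n1), n1, tolerance = 1e-12)
  # constant row fails, naming the gene
  bad <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
                dimnames = list(c("flatgene", "ok"), NULL))
  expect_error(row_normalize(bad), "flatgene")
  # missing values are normalized over observed entries only
  mm <- matrix(c(1, 2, 3, NA), 1, dimnames = list("g1", NULL))
  out <- row_normalize(mm)
  expect_equal(mean(out[1, ], na.rm = TRUE), 0)
  expect_equal(mean(out[1, ]^2, na.rm = TRUE), 1)
})

test_that("K-means clustering is deterministic and respects closed forms", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10, dimnames = list(sprintf("g%02d", 1:20), NULL))
  one <- cluster_profiles(m, K = 1, seed = 1)
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(m)))
  expect_true(all(one$cluster == 1))
  # identical rows land in the same cluster
  m2 <- rbind(m, dup1 = m["g01", ])
  cl <- cluster_profiles(m2, K = 4, seed = 2)$cluster
  expect_equal(unname(cl["dup1"]), unname(cl["g01"]))
  # same seed, same answer; different seed allowed to differ
  a <- cluster_profiles(m, K = 3, seed = 7)
  b <- cluster_profiles(m, K = 3, seed = 7)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$wss, b$wss)
  expect_error(cluster_profiles(m, K = 21, seed = 1), "exceeds")
})

test_that("restarts never report a worse objective than any single start", {
  set.seed(5)
  m <- matrix(rnorm(300), 30, 10, dimnames = list(sprintf("g%02d", 1:30), NULL))
  multi <- cluster_profiles(m, K = 4, seed = 9, n_restarts = 20)
  singles <- vapply(1:5, function(i)
    cluster_profiles(m, K = 4, seed = 9, n_restarts = i)$wss, numeric(1))
  expect_true(all(multi$wss <= singles + 1e-9))
})

test_that("archetype rules follow the documented precedence", {
  labels <- c("EARLY", "EXPONENTIAL", "TRANSITION", "STATIONARY")
  prof <- function(e, x, t, s) c(e, x, t, s)
  # pulse fires before step: (0, 1, 0, -1) is a transient, not EXP_HIGH
  expect_equal(classify_archetype(prof(0, 1, 0, -1), labels), "TRANSIENT_UP_EXP")
  expect_equal(classify_archetype(prof(0, -1, 0, 1), labels), "TRANSIENT_DOWN_EXP")
  expect_equal(classify_archetype(prof(0, 0, 1, 0), labels), "TRANSIENT_UP_TRANSITION")
  expect_equal(classify_archetype(prof(1, 1, -1, -1), labels), "EXP_HIGH")
  expect_equal(classify_archetype(prof(-1, -1, 1, 1), labels), "STAT_HIGH")
  expect_equal(classify_archetype(prof(0, 0, 0, 0), labels), "OTHER")
  # shift invariance: rules use differences only
  for (shift in c(-3, 0.7, 12)) {
    expect_equal(classify_archetype(prof(0, 1, 0, -1) + shift, labels),
                 "TRANSIENT_UP_EXP")
    expect_equal(classify_archetype(prof(1, 1, -1, -1) + shift, labels),
                 "EXP_HIGH")
  }
  # a rule needing an empty segment is skipped with a message; rules whose
  # segments are all present still apply
  short <- c("EXPONENTIAL", "STATIONARY")
  expect_message(out <- classify_archetype(c(-1, 1), short), "skipped")
  expect_equal(out, "STAT_HIGH")
  expect_equal(suppressMessages(classify_archetype(c(1, -1), short)), "OTHER")
})

test_that("planted archetypes are recovered through the full path", {
  ph <- study_phases()
  sim <- simulate_expression(c(60, 60, 25, 25, 25, 120), ph,
                             effect = 1.0, sigma_add = 0.1, sigma_mult = 0.1,
                             seed = 17)
  expect_gte(archetype_recovery(sim, ph, K = 10, seed = 1), 0.9)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # all 10 plasmid genes drawn in a 10-gene set from a 20-gene universe
  universe <- sprintf("g%02d", 1:20)
  res <- replicon_enrichment(universe[1:10], universe[1:10], universe)
  expect_equal(res$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$direction, "over")
  # proportional representation is never significant
  res2 <- replicon_enrichment(universe[c(1:3, 11:16)], universe[1:6], universe)
  expect_gt(res2$p_value, 0.4)
  expect_error(replicon_enrichment(character(0), universe[1:5], universe), "empty")
  expect_error(replicon_enrichment("zz", universe[1:5], universe), "outside")
})

test_that("enrichment tail agrees with brute-force subset enumeration", {
  for (N in c(6, 9, 12)) {
    universe <- sprintf("u%02d", 1:N)
    for (K in c(2, N %/% 2)) {
      for (n in c(2, N %/% 2, N - 1)) {
        sets <- utils::combn(N, n)
        kk <- colSums(sets <= K)
        for (k in unique(kk)) {
          got <- replicon_enrichment(universe[sets[, match(k, kk)]],
                                     universe[1:K], universe)
          brute <- if (got$direction == "over") mean(kk >= k) else mean(kk <= k)
          expect_equal(got$p_value, brute, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("over-representation p is monotone in the overlap", {
  universe <- c(sprintf("c%02d", 1:10), sprintf("o%02d", 1:30))
  ps <- vapply(4:9, function(k) {
    set <- c(sprintf("c%02d", 1:k), sprintf("o%02d", 1:(10 - k)))
    res <- replicon_enrichment(set, sprintf("c%02d", 1:10), universe)
    expect_equal(res$direction, "over")
    res$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})
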