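test_that("a parcel equal to the scores maps to r = 1 with minimal p_unc", {
  set.seed(71)
  n <- 30
  s <- rnorm(n)
  g <- cbind(s, matrix(rnorm(n * 9), n, 9))
  m <- map_univariate(g, s, n_perm = 99, seed = 1)
  expect_equal(m$r[1], 1, tolerance = 1e-10)
  expect_equal(m$p_unc[1], 1 / 100)
  expect_equal(m$p_fwe[1], 1 / 100)
  expect_equal(m$n, rep(n, 10))
})

test_that("permutation maps are seed-reproducible and monotone in p", {
  set.seed(72)
  g <- matrix(rnorm(25 * 12), 25, 12)
  s <- rnorm(25)
  m1 <- map_univariate(g, s, n_perm = 59, seed = 5)
  m2 <- map_univariate(g, s, n_perm = 59, seed = 5)
  expect_identical(m1$p_fwe, m2$p_fwe)
  expect_true(all(m1$p_fwe >= m1$p_unc))
  m3 <- map_univariate(g, s, n_perm = 59, seed = 6)
  expect_false(identical(m3$p_unc, m1$p_unc)) # different null draw

  expect_error(map_univariate(g, rep(1, 25), n_perm = 10), "constant score")
  expect_error(map_univariate(g[1:5, ], s[1:5], n_perm = 10), "at least 10 subjects")
})

test_that("constant parcels yield NA rows, not errors", {
  set.seed(73)
  g <- matrix(rnorm(20 * 5), 20, 5)
  g[, 3] <- 2
  m <- map_univariate(g, rnorm(20), n_perm = 19, seed = 1)
  expect_true(is.na(m$r[3]) && is.na(m$p_fwe[3]))
  expect_false(anyNA(m$r[-3]))
})

test_that("covariates are residualized Freedman-Lane style", {
  set.seed(74)
  n <- 60
  z <- rnorm(n) # confounder drives both sides
  s <- z + rnorm(n, 0, 0.3)
  g <- cbind(z + rnorm(n, 0, 0.3), matrix(rnorm(n * 7), n, 7))
  raw <- map_univariate(g, s, n_perm = 199, seed = 2)
  adj <- map_univariate(g, s, covariates = cbind(z), n_perm = 199, seed = 2)
  # the confounded parcel is strong before adjustment, weak after
  expect_gt(abs(raw$r[1]), 0.8)
  expect_lt(abs(adj$r[1]), 0.4)
})

test_that("interaction maps are zero for identical arms and antisymmetric", {
  set.seed(75)
  n <- 15
  g_half <- matrix(rnorm(n * 8), n, 8)
  s_half <- rnorm(n)
  g <- rbind(g_half, g_half)
  s <- c(s_half, s_half)
  arm <- rep(c("a", "b"), each = n)
  m <- interaction_map(g, s, arm, n_perm = 19, seed = 1)
  expect_lt(max(abs(m$t)), 1e-8)

  # label swap negates the interaction statistic
  set.seed(76)
  g2 <- matrix(rnorm(2 * n * 8), 2 * n, 8)
  s2 <- rnorm(2 * n)
  m1 <- interaction_map(g2, s2, arm, n_perm = 19, seed = 1)
  m2 <- interaction_map(g2, s2, rev(arm), n_perm = 19, seed = 1)
  expect_equal(m1$t, -m2$t, tolerance = 1e-9)

  expect_error(interaction_map(g2, s2, rep("a", 2 * n), n_perm = 5), "two levels")
  expect_error(
    interaction_map(g2[1:12, ], s2[1:12], rep(c("a", "b"), 6), n_perm = 5),
    "at least 10"
  )
})

test_that("planted arm-specific slopes are detected by the interaction map", {
  set.seed(77)
  n <- 96
  arm <- rep(c("a", "b"), each = n)
  s <- rnorm(2 * n)
  hits <- 0
  n_rep <- 20
  for (b in seq_len(n_rep)) {
    g <- matrix(rnorm(2 * n * 10), 2 * n, 10)
    g[arm == "a", 1] <- g[arm == "a", 1] + 0.6 * s[arm == "a"]
    m <- interaction_map(g, s, arm, n_perm = 99, seed = b)
    hits <- hits + (which.max(abs(m$t)) == 1 && m$p_fwe[1] <= 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("map strength comparison has df P-1 and t = 0 against itself", {
  set.seed(78)
  g <- matrix(rnorm(20 * 718), 20, 718)
  s <- rnorm(20)
  m <- map_univariate(g, s, n_perm = 19, seed = 1)
  self <- compare_map_strength(m, m)
  expect_equal(self$t, 0)
  expect_equal(self$p, 1)
  expect_equal(self$df, 717)

  m2 <- map_univariate(matrix(rnorm(20 * 718), 20, 718), s, n_perm = 19, seed = 2)
  cmp <- compare_map_strength(m, m2, mode = "signed")
  expect_equal(cmp$df, 717)
  bad <- m2[1:100, ]
  expect_error(compare_map_strength(m, bad), "different parcel sets")
})

test_that("stronger planted coupling wins the paired strength test", {
  set.seed(79)
  wins <- 0
  n_rep <- 20
  for (b in seq_len(n_rep)) {
    n <- 50
    s <- rnorm(n)
    strong <- matrix(rnorm(n * 60), n, 60) + outer(s, runif(60, 0.2, 0.6))
    weak <- matrix(rnorm(n * 60), n, 60)
    ma <- map_univariate(strong, s, n_perm = 9, seed = b)
    mb <- map_univariate(weak, s, n_perm = 9, seed = b)
    wins <- wins + (compare_map_strength(ma, mb)$t > 0)
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("map correlation is 1 against itself and null between independent maps", {
  set.seed(80)
  g <- matrix(rnorm(40 * 100), 40, 100)
  s <- rnorm(40)
  m <- map_univariate(g, s, n_perm = 9, seed = 1)
  expect_equal(correlate_maps(m, m)$r, 1, tolerance = 1e-12)

  rs <- replicate(30, {
    m1 <- map_univariate(matrix(rnorm(40 * 100), 40, 100), rnorm(40), n_perm = 9, seed = 1)
    m2 <- map_univariate(matrix(rnorm(40 * 100), 40, 100), rnorm(40), n_perm = 9, seed = 1)
    correlate_maps(m1, m2)$r
  })
  expect_lt(abs(mean(rs)), 3 / sqrt(99 * 30))

  # maps driven by the same heterogeneous coupling profile correlate strongly:
  # with per-parcel couplings spanning 0..0.9 and n = 120, the profile
  # variance dominates the estimation noise of each map
  s2 <- rnorm(120)
  w <- runif(100, 0, 0.9)
  m1 <- map_univariate(matrix(rnorm(120 * 100), 120, 100) + outer(s2, w), s2, n_perm = 9, seed = 1)
  m2 <- map_univariate(matrix(rnorm(120 * 100), 120, 100) + outer(s2, w), s2, n_perm = 9, seed = 1)
  expect_gt(correlate_maps(m1, m2)$r, 0.5)
})

test_that("Bonferroni follow-ups multiply and cap p-values", {
  set.seed(81)
  agg <- matrix(rnorm(50 * 12), 50, 12,
    dimnames = list(NULL, paste0("net", 1:12))
  )
  s <- rnorm(50)
  fw <- network_followups(agg, s)
  expect_equal(fw$p_bonf, pmin(1, fw$p_unc * 12), tolerance = 1e-12)
  expect_true(all(fw$p_bonf >= fw$p_unc))
  expect_error(network_followups(agg, s, n_tests = 5), "at least the number")

  # widening the family size scales the adjustment accordingly
  fw24 <- network_followups(agg, s, n_tests = 24)
  expect_equal(fw24$p_bonf, pmin(1, fw$p_unc * 24), tolerance = 1e-12)
})
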