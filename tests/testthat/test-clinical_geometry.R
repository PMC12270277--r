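test_that("deltas follow the from-minus-to convention", {
  vals <- list(
    baseline = rbind(c(2, 3), c(4, 0), c(1, 1)),
    week8 = rbind(c(1, 1), c(2, 2), c(1, 0))
  )
  panel <- toy_panel(vals)
  d <- compute_deltas(panel, "baseline", "week8")
  expect_equal(unname(d[1, ]), c(1, 2))
  expect_equal(unname(d[2, ]), c(2, -2))
  expect_equal(unname(d[3, ]), c(0, 1))
  expect_error(compute_deltas(panel, "week8", "week8"), "must differ")

  # duplicated visit data gives an all-zero matrix
  vals0 <- list(baseline = vals$baseline, week8 = vals$baseline)
  d0 <- compute_deltas(toy_panel(vals0))
  expect_true(all(d0 == 0))
})

test_that("rank-1 noise-free input is fully explained by PC1 with loadings +/- w", {
  set.seed(41)
  w <- rnorm(6)
  w <- w / sqrt(sum(w^2))
  u <- rnorm(20)
  x <- outer(u, w)
  m <- fit_pca(x, standardize = FALSE)
  expect_equal(m$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(sum(m$loadings[, 1] * w)), 1, tolerance = 1e-10)
})

test_that("variance-explained matches an independent eigendecomposition oracle", {
  set.seed(42)
  for (k in 1:4) {
    x <- matrix(rnorm(5 * 4), 5, 4)
    m <- fit_pca(x, standardize = FALSE)
    ev <- eigen(cov(scale(x, scale = FALSE)), symmetric = TRUE)$values
    ev <- ev[ev > 1e-12]
    expect_equal(m$var_explained[seq_along(ev)], ev / sum(ev), tolerance = 1e-10)
  }
})

test_that("PCA scores are centered with diagonal covariance and idempotent signs", {
  set.seed(43)
  x <- matrix(rnorm(30 * 8), 30, 8)
  m <- fit_pca(x)
  expect_equal(unname(colMeans(m$scores)), rep(0, ncol(m$scores)), tolerance = 1e-10)
  cs <- cov(m$scores)
  expect_equal(cs, diag(diag(cs)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(abs(crossprod(m$loadings) - diag(ncol(m$loadings))) < 1e-10))
  expect_true(all(diff(m$var_explained) <= 1e-12))
  expect_equal(sum(m$var_explained), 1, tolerance = 1e-10)

  # orientation is idempotent: refitting the oriented reconstruction flips nothing
  m2 <- fit_pca(x)
  expect_equal(m$loadings, m2$loadings)
})

test_that("PC1 scores correlate positively with HRSD total reduction", {
  spec <- small_spec(n_subjects = 60L, seed = 44)
  clin <- generate_clinical(spec)
  d <- compute_deltas(clin$panel)
  m <- fit_pca(d)
  hrsd_total <- rowSums(d[, grepl("^HRSD", colnames(d))])
  expect_gt(cor(m$scores[, 1], hrsd_total), 0)
})

test_that("zero-variance columns are dropped with a warning and zero loadings", {
  set.seed(45)
  x <- cbind(matrix(rnorm(40), 10, 4), 0)
  colnames(x) <- paste0("it", 1:5)
  expect_warning(m <- fit_pca(x), "zero-variance")
  expect_equal(m$loadings["it5", ], rep(0, ncol(m$loadings)), ignore_attr = TRUE)
})

test_that("permutation significance flags a planted factor and errors on n_perm = 0", {
  spec <- small_spec(n_subjects = 80L, seed = 46)
  clin <- generate_clinical(spec)
  d <- compute_deltas(clin$panel)
  p <- pc_significance(d, n_perm = 199, seed = 1)
  expect_equal(unname(p[1]), 1 / 200)
  expect_error(pc_significance(d, n_perm = 0), "at least 1")
  # reproducible under the same seed
  expect_identical(p, pc_significance(d, n_perm = 199, seed = 1))
})

test_that("permutation significance is calibrated under the null", {
  # isotropic noise: PC1 var-explained p should be uniform enough that
  # rejections at alpha = 0.2 stay near 0.2 (binomial 95% band)
  set.seed(47)
  rej <- 0
  n_rep <- 60
  for (b in seq_len(n_rep)) {
    x <- matrix(rnorm(24 * 8), 24, 8)
    p <- pc_significance(x, n_perm = 49, seed = b)
    rej <- rej + (p[1] <= 0.2)
  }
  expect_gt(rej / n_rep, 0.2 - 1.96 * sqrt(0.2 * 0.8 / n_rep) - 0.02)
  expect_lt(rej / n_rep, 0.2 + 1.96 * sqrt(0.2 * 0.8 / n_rep) + 0.02)
})

test_that("split-half reliability is 1 on duplicated data and sign-invariant", {
  set.seed(48)
  x <- matrix(rnorm(12 * 6), 12, 6)
  dup <- rbind(x, x)
  # stratify on copy pairs: every split puts one copy of each row in each
  # half, so the halves hold identical data and loadings match exactly
  pairs <- rep(seq_len(12), 2)
  r <- split_half_reliability(dup,
    n_splits = 20, seed = 1, n_components = 2,
    strata = pairs
  )
  expect_equal(unname(r), c(1, 1), tolerance = 1e-10)

  # reliability is invariant to global sign flips of the data (loadings flip)
  r2 <- split_half_reliability(-dup,
    n_splits = 20, seed = 1, n_components = 2,
    strata = pairs
  )
  expect_equal(r, r2, tolerance = 1e-12)
  expect_error(split_half_reliability(x[1:6, ]), "at least 8")
})

test_that("retention rule keeps only significant, reliable components", {
  keep <- retain_components(
    perm_p = c(0.001, 0.001, 0.2),
    reliability_r = c(0.95, 0.3, 0.9)
  )
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE))
})
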