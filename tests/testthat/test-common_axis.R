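test_that("identical groups give similarity 1 and pooled projection consistency", {
  set.seed(51)
  x <- matrix(rnorm(20 * 6), 20, 6)
  rownames(x) <- sprintf("A%02d", 1:20)
  y <- x
  rownames(y) <- sprintf("B%02d", 1:20)
  ax <- fit_common(list(g1 = x, g2 = y))
  expect_equal(abs(ax$similarity["g1", "g2"]), 1, tolerance = 1e-10)
  expect_equal(abs(ax$similarity["g1", "pooled"]), 1, tolerance = 1e-10)

  # projection consistency: pooled scores equal projecting each row
  proj <- project_scores(ax$pooled, rbind(x, y), components = 1)
  expect_equal(unname(drop(proj)), unname(ax$scores$score), tolerance = 1e-10)
})

test_that("groups sharing a planted geometry have highly correlated loadings", {
  spec <- small_spec(n_subjects = 192L, seed = 52)
  clin <- generate_clinical(spec)
  ax <- fit_common(compute_deltas(clin$panel))
  expect_gte(abs(ax$similarity["sertraline", "placebo"]), 0.9)
  # pooled PC1 close to each group's PC1
  expect_gte(abs(ax$similarity["sertraline", "pooled"]), 0.95)
})

test_that("orthogonal group geometries yield null-level similarity", {
  set.seed(53)
  p <- 40
  w1 <- rnorm(p)
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- rnorm(p)
  w2 <- w2 - sum(w2 * w1) * w1
  w2 <- w2 / sqrt(sum(w2^2))
  x1 <- outer(rnorm(60, 0, 2), w1) + matrix(rnorm(60 * p, 0, 0.3), 60, p)
  x2 <- outer(rnorm(60, 0, 2), w2) + matrix(rnorm(60 * p, 0, 0.3), 60, p)
  colnames(x1) <- colnames(x2) <- paste0("it", seq_len(p))
  ax <- fit_common(list(a = x1, b = x2))
  expect_lt(abs(ax$similarity["a", "b"]), 3 / sqrt(p - 1))
})

test_that("score comparisons use pooled-variance t with the design df", {
  set.seed(54)
  scores <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:192),
    group = rep(c("sertraline", "placebo"), c(93, 99)),
    score = rnorm(192)
  )
  tt <- compare_scores(scores)
  expect_equal(tt$df, 190)

  # identical groups: t is exactly zero
  same <- scores
  same$group <- rep(c("a", "b"), 96)
  same$score <- rep(rnorm(96), each = 2)
  expect_equal(compare_scores(same)$t, 0)

  # shift invariance and antisymmetry under relabeling
  t1 <- compare_scores(scores)$t
  shifted <- scores
  shifted$score <- scores$score + 100
  expect_equal(compare_scores(shifted)$t, t1, tolerance = 1e-9)
  # reversing row order makes the other group appear first: t flips sign
  relab <- scores[rev(seq_len(nrow(scores))), ]
  expect_equal(compare_scores(relab)$t, -t1, tolerance = 1e-12)

  expect_error(
    compare_scores(tibble::tibble(group = c("a", "b", "b"), score = 1:3)),
    "at least 2"
  )
})

test_that("baseline PCA equals delta PCA on identical matrices and tracks severity", {
  spec <- small_spec(n_subjects = 150L, seed = 55)
  clin <- generate_clinical(spec)
  base <- baseline_pca(clin$panel)
  # baseline PC1 scores correlate with the planted severity latent
  expect_gt(cor(base$scores[, 1], clin$truth$s), 0.6)
  # and baseline geometry resembles the improvement geometry (lambda ~ |w|)
  ax <- fit_common(compute_deltas(clin$panel))
  expect_gt(abs(cor(base$loadings[, 1], ax$pooled$loadings[, 1])), 0.4)
})

test_that("baseline severity predicts improvement scores at the planted correlation", {
  spec <- cohort_spec(n_subjects = 400L, n_parcels = 10L, seed = 56)
  clin <- generate_clinical(spec)
  ax <- fit_common(compute_deltas(clin$panel))
  base <- baseline_pca(clin$panel)
  # align by subject id: pooled-axis rows are grouped by arm
  r <- cor(base$scores[ax$scores$subject_id, 1], ax$scores$score)
  # planted rho = 0.20, attenuated by estimation noise in both scores
  expect_gt(r, 0.05)
  expect_lt(r, 0.35)
})

test_that("predict_improvement reports correlations and interaction F", {
  set.seed(57)
  n <- 100
  ids <- sprintf("S%03d", 1:n)
  arm <- rep(c("sertraline", "placebo"), n / 2)
  y <- rnorm(n)
  preds <- tibble::tibble(
    subject_id = ids, self = y,
    noisevar = rnorm(n)
  )
  tab <- suppressWarnings( # perfect fit: anova warns about unreliable F
    predict_improvement(setNames(y, ids), preds, setNames(arm, ids))
  )
  self_row <- tab[tab$predictor == "self", ]
  expect_equal(self_row$r_pooled, 1, tolerance = 1e-12)
  expect_equal(self_row$interaction_df2, n - 4)

  # identical data in both arms: interaction F is (numerically) zero
  x <- rnorm(n / 2)
  yy <- 0.5 * x + rnorm(n / 2, 0, 0.5)
  tab2 <- predict_improvement(
    setNames(c(yy, yy), ids),
    tibble::tibble(subject_id = ids, x = c(x, x)),
    setNames(rep(c("a", "b"), each = n / 2), ids)
  )
  expect_lt(tab2$interaction_F, 1e-16)

  # collinear predictor set errors with the aliased name
  dat_alias <- tibble::tibble(subject_id = ids, bad = rep(1, n))
  expect_error(
    predict_improvement(setNames(y, ids), dat_alias, setNames(arm, ids)),
    "aliased"
  )
})

test_that("arm-specific planted association produces an interaction signal", {
  set.seed(58)
  n <- 192
  ids <- sprintf("S%03d", 1:n)
  arm <- rep(c("a", "b"), n / 2)
  x <- rnorm(n)
  y <- ifelse(arm == "a", 0.5 * x, 0) + rnorm(n, 0, sqrt(1 - 0.25))
  tab <- predict_improvement(
    setNames(y, ids),
    tibble::tibble(subject_id = ids, x = x), setNames(arm, ids)
  )
  expect_lt(tab$interaction_p, 0.05)
  expect_equal(tab$interaction_df2, 188)
})

test_that("null predictors keep the interaction near its nominal size", {
  set.seed(59)
  n_rep <- 100
  rej <- 0
  for (b in seq_len(n_rep)) {
    n <- 60
    ids <- sprintf("S%02d", 1:n)
    tab <- predict_improvement(
      setNames(rnorm(n), ids),
      tibble::tibble(subject_id = ids, x = rnorm(n)),
      setNames(rep(c("a", "b"), n / 2), ids)
    )
    rej <- rej + (tab$interaction_p < 0.05)
  }
  expect_lt(rej / n_rep, 0.05 + 1.96 * sqrt(0.05 * 0.95 / n_rep) + 0.03)
})

test_that("severity split is a configurable two-level factor", {
  x <- c(1, 2, 3, 10, 11, 12)
  s <- severity_split(x)
  expect_equal(levels(s), c("low", "high"))
  expect_equal(sum(s == "high"), 3)
  expect_equal(sum(severity_split(x, threshold = 0) == "high"), 6)
})
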