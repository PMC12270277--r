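# Explicit projection-matrix oracle for sequential (Type I) sums of squares:
# project y on growing column blocks and difference the residual SS.
seq_ss_oracle <- function(blocks, y) {
  X <- matrix(1, length(y), 1)
  rss <- sum(qr.resid(qr(X), y)^2)
  out <- numeric(length(blocks))
  for (i in seq_along(blocks)) {
    X <- cbind(X, blocks[[i]])
    rss_new <- sum(qr.resid(qr(X), y)^2)
    out[i] <- rss - rss_new
    rss <- rss_new
  }
  c(out, rss)
}

make_long_toy <- function(n_subj = 10, n_net = 3, seed = 91, planted = 0,
                          base_slope = 0.1) {
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(n_subj))
  score <- rnorm(n_subj)
  treatment <- rep(c("a", "b"), length.out = n_subj)
  age <- runif(n_subj, 20, 60)
  gender <- sample(c("F", "M"), n_subj, replace = TRUE, prob = c(0.6, 0.4))
  site <- rep(sprintf("site%d", 1:2), each = n_subj / 2)
  net <- sprintf("net%d", seq_len(n_net))
  long <- expand.grid(subject_id = subj, network = net, stringsAsFactors = FALSE)
  i <- match(long$subject_id, subj)
  long$score <- score[i]
  long$treatment <- treatment[i]
  long$age <- age[i]
  long$gender <- gender[i]
  long$site <- site[i]
  long$gbc <- rnorm(nrow(long), sd = 0.3) + base_slope * score[i] +
    planted * score[i] * (long$treatment == "a")
  tibble::as_tibble(long)
}

test_that("rm_anova matches an explicit projection-matrix oracle on a balanced toy", {
  long <- make_long_toy(n_subj = 6, n_net = 2, seed = 92)
  long$site <- "site1" # keep the toy minimal: no site/gender variation
  long$gender <- "F"
  an <- rm_anova(long, covariates = "age")

  # oracle: between stratum on subject means, within stratum on the rest
  subj <- unique(long[, c("subject_id", "score", "treatment", "age")])
  ybar <- tapply(long$gbc, long$subject_id, mean)[subj$subject_id]
  n_net <- 2
  trt <- as.numeric(factor(subj$treatment)) - 1
  blocks_b <- list(
    cbind(subj$age), cbind(subj$score), cbind(trt), cbind(subj$score * trt)
  )
  ss_b <- seq_ss_oracle(blocks_b, sqrt(n_net) * ybar) # subject totals scale
  got_b <- an[an$stratum == "subject_id", ]
  expect_equal(got_b$sumsq, ss_b, tolerance = 1e-8)

  # F statistics are consistent with their own stratum residual
  for (st in unique(an$stratum)) {
    sub <- an[an$stratum == st, ]
    mse <- sub$sumsq[sub$term == "Residuals"] / sub$df[sub$term == "Residuals"]
    rows <- sub$term != "Residuals"
    expect_equal(sub$statistic[rows], (sub$sumsq[rows] / sub$df[rows]) / mse,
      tolerance = 1e-8
    )
  }
  # dfs within each stratum add up to the stratum total
  expect_equal(sum(an$df[an$stratum == "subject_id"]), 6 - 1)
  expect_equal(sum(an$df[an$stratum == "Within"]), 6 * (2 - 1))
})

test_that("rm_anova reproduces the design dfs of a full cohort layout", {
  long <- make_long_toy(n_subj = 192, n_net = 12, seed = 93)
  set.seed(93)
  i <- match(long$subject_id, unique(long$subject_id))
  long$site <- sample(rep(sprintf("site%d", 1:4), 48))[i]
  long$treatment <- sample(rep(c("a", "b"), 96))[i]
  an <- rm_anova(long)
  expect_equal(an$df[an$stratum == "subject_id" & an$term == "Residuals"], 183)
  expect_equal(an$df[an$stratum == "Within" & an$term == "Residuals"], 2068)
  expect_equal(
    an$df[an$stratum == "Within" & an$term == "score:treatment:network"], 11
  )
})

test_that("rm_anova rejects unbalanced or rank-deficient inputs", {
  long <- make_long_toy(n_subj = 8, n_net = 3, seed = 94)
  expect_error(rm_anova(long[-1, ]), "unbalanced")
  long2 <- make_long_toy(n_subj = 8, n_net = 3, seed = 95)
  long2$age <- 40 # constant covariate aliases the intercept
  expect_error(rm_anova(long2), "rank-deficient")
})

test_that("rm_anova reduces to one-way repeated-measures ANOVA when degenerate", {
  # one treatment level, constant score, no covariates: the within stratum
  # must equal the classical subject x network two-way closed form
  long <- make_long_toy(n_subj = 12, n_net = 4, seed = 96)
  long$treatment <- "a"
  long$score <- 0
  long$gbc <- long$gbc + rep(c(0, 0.5, 1, 0), each = 12)
  wide <- matrix(long$gbc[order(long$network, long$subject_id)], 12, 4)
  grand <- mean(wide)
  ss_net <- 12 * sum((colMeans(wide) - grand)^2)
  ss_err <- sum((wide - outer(rowMeans(wide), rep(1, 4)) -
    outer(rep(1, 12), colMeans(wide)) + grand)^2)
  f_closed <- (ss_net / 3) / (ss_err / (11 * 3))

  an <- rm_anova(long, covariates = character(0))
  net_row <- an[an$stratum == "Within" & an$term == "network", ]
  expect_equal(net_row$sumsq, ss_net, tolerance = 1e-8)
  expect_equal(net_row$statistic, f_closed, tolerance = 1e-8)
  expect_equal(net_row$df, 3)
  expect_equal(an$df[an$stratum == "Within" & an$term == "Residuals"], 33)
})

test_that("per_group_model matches lm/anova and flags aliasing", {
  long <- make_long_toy(n_subj = 20, n_net = 3, seed = 97)
  one_arm <- long[long$treatment == "a", ]
  an <- per_group_model(one_arm, covariates = c("age", "gender"))
  oracle <- anova(lm(score ~ age + gender + gbc * network, data = one_arm))
  expect_equal(an$sumsq, oracle$`Sum Sq`, tolerance = 1e-10)
  expect_equal(an$statistic, oracle$`F value`, tolerance = 1e-10)

  aliased <- one_arm
  aliased$gbc <- aliased$age # gbc aliases the covariate exactly
  expect_error(per_group_model(aliased, covariates = c("age", "gender")), "aliased|rank-deficient")
})

test_that("per_group_model detects a planted slope only in the planted arm", {
  set.seed(98)
  detected <- c(a = 0, b = 0)
  n_rep <- 15
  for (b in seq_len(n_rep)) {
    long <- make_long_toy(n_subj = 60, n_net = 4, seed = 100 + b, base_slope = 0)
    # plant: in arm a only, score depends on gbc
    i_a <- long$treatment == "a"
    long$score[i_a] <- long$score[i_a] + 2.5 * long$gbc[i_a]
    for (arm in c("a", "b")) {
      an <- per_group_model(long[long$treatment == arm, ])
      detected[arm] <- detected[arm] + (an$p[an$term == "gbc"] < 0.05)
    }
  }
  expect_gte(detected[["a"]] / n_rep, 0.8)
  expect_lte(detected[["b"]] / n_rep, 0.3)
})
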