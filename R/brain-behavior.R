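new_brain_map <- function(df, label, n_perm, seed) {
  attr(df, "label") <- label
  attr(df, "n_perm") <- n_perm
  attr(df, "seed") <- seed
  class(df) <- unique(c("brain_map", class(df)))
  df
}

# Residualize columns of y on [1, covariates]; returns residuals and fitted.
residualize <- function(y, covariates) {
  X <- cbind(1, as.matrix(covariates))
  q <- qr(X)
  if (q$rank < ncol(X)) stop_symgeo("rank-deficient covariate matrix")
  fit <- qr.fitted(q, y)
  list(res = y - fit, fit = fit)
}

#' Mass-univariate brain-behavior map with permutation FWE
#'
#' Correlates a behavioral score with GBC in every parcel (two-tailed
#' Pearson), then controls the family-wise error rate with the
#' max-statistic permutation method: subject labels of the score are
#' permuted, the per-parcel absolute correlations recomputed, and each
#' parcel's statistic compared both to its own permutation distribution
#' (`p_unc`) and to the distribution of the maximum across parcels
#' (`p_fwe`), with the add-one convention. When covariates are supplied
#' both sides are residualized on them first and the residualized scores
#' are permuted (Freedman-Lane).
#'
#' @param gbc Subjects-by-parcels GBC matrix.
#' @param scores Numeric behavioral vector (length = subjects).
#' @param covariates Optional numeric matrix/data frame of nuisance
#'   covariates.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param label Map label.
#' @return A `brain_map` tibble: `parcel_id`, `n`, `r`, `beta`, `t`,
#'   `p_unc`, `p_fwe` (NA rows for constant parcels).
#' @export
map_univariate <- function(gbc, scores, covariates = NULL, n_perm = 1000,
                           seed = 1, label = "gbc~score") {
  gbc <- as.matrix(gbc)
  n <- nrow(gbc)
  if (n < 10) stop_symgeo("need at least 10 subjects")
  if (length(scores) != n) stop_symgeo("scores length must match gbc rows")
  if (sd(scores) == 0) stop_symgeo("constant score vector")
  if (n_perm < 1) stop_symgeo("`n_perm` must be at least 1")
  q <- 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    q <- ncol(covariates)
    scores <- residualize(scores, covariates)$res
    gbc <- residualize(gbc, covariates)$res
  }
  ok <- apply(gbc, 2, sd) > 0
  G <- gbc[, ok, drop = FALSE]
  r <- drop(cor(scores, G))
  df <- n - 2 - q
  tval <- r * sqrt(df / pmax(1 - r^2, 1e-15))
  beta <- drop(cov(G, scores)) / var(scores)

  perm_scores <- matrix(0, n, n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) perm_scores[, b] <- scores[sample.int(n)]
  })
  Rp <- abs(cor(perm_scores, G)) # n_perm x parcels
  maxs <- apply(Rp, 1, max)
  p_unc <- (1 + colSums(Rp >= rep(abs(r), each = n_perm))) / (n_perm + 1)
  p_fwe <- (1 + vapply(abs(r), function(v) sum(maxs >= v), 0)) / (n_perm + 1)

  out <- tibble::tibble(
    parcel_id = seq_len(ncol(gbc)),
    n = n, r = NA_real_, beta = NA_real_, t = NA_real_,
    p_unc = NA_real_, p_fwe = NA_real_
  )
  out$r[ok] <- r
  out$beta[ok] <- beta
  out$t[ok] <- tval
  out$p_unc[ok] <- p_unc
  out$p_fwe[ok] <- p_fwe
  new_brain_map(out, label, n_perm, seed)
}

#' Treatment-interaction brain-behavior map
#'
#' Per parcel, fits `gbc ~ score * arm (+ covariates)` and maps the t
#' statistic of the score-by-arm interaction. Family-wise error is
#' controlled by Freedman-Lane permutation: parcel data are residualized
#' on the reduced (no-interaction) model, the residual rows permuted, the
#' reduced fit added back and the interaction t recomputed, taking the
#' maximum across parcels.
#'
#' @param gbc Subjects-by-parcels GBC matrix.
#' @param scores Behavioral vector.
#' @param arm Two-level treatment factor (each level n >= 10).
#' @param covariates Optional nuisance covariates.
#' @param n_perm,seed,label As in [map_univariate()].
#' @return A `brain_map` tibble; `r` holds the partial correlation
#'   equivalent of the interaction t.
#' @export
interaction_map <- function(gbc, scores, arm, covariates = NULL,
                            n_perm = 1000, seed = 1, label = "interaction") {
  gbc <- as.matrix(gbc)
  n <- nrow(gbc)
  arm <- factor(arm)
  if (nlevels(arm) != 2) stop_symgeo("`arm` must have exactly two levels")
  if (min(table(arm)) < 10) stop_symgeo("each arm needs at least 10 subjects")
  a <- as.numeric(arm == levels(arm)[2])
  X0 <- cbind(intercept = 1, score = scores, arm = a)
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  X <- cbind(X0, interaction = scores * a)
  k <- ncol(X)
  qX <- qr(X)
  if (qX$rank < k) stop_symgeo("rank-deficient design (aliased columns)")
  XtXinv_int <- solve(crossprod(X))[k, k]

  int_t <- function(Y) {
    cf <- qr.coef(qX, Y)
    res <- qr.resid(qX, Y)
    s2 <- colSums(res^2) / (n - k)
    cf[k, ] / sqrt(pmax(s2 * XtXinv_int, 1e-300))
  }
  ok <- apply(gbc, 2, sd) > 0
  G <- gbc[, ok, drop = FALSE]
  t_obs <- int_t(G)

  q0 <- qr(X0)
  fit0 <- qr.fitted(q0, G)
  res0 <- qr.resid(q0, G)
  p_unc <- p_fwe <- rep(1, ncol(G))
  cnt_unc <- rep(0, ncol(G))
  cnt_fwe <- rep(0, ncol(G))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      tp <- abs(int_t(fit0 + res0[sample.int(n), , drop = FALSE]))
      cnt_unc <- cnt_unc + (tp >= abs(t_obs))
      cnt_fwe <- cnt_fwe + (max(tp) >= abs(t_obs))
    }
  })
  dfres <- n - k
  out <- tibble::tibble(
    parcel_id = seq_len(ncol(gbc)),
    n = n, r = NA_real_, beta = NA_real_, t = NA_real_,
    p_unc = NA_real_, p_fwe = NA_real_
  )
  out$t[ok] <- t_obs
  out$r[ok] <- t_obs / sqrt(t_obs^2 + dfres) # partial r of the interaction
  out$beta[ok] <- qr.coef(qX, G)[k, ]
  out$p_unc[ok] <- (1 + cnt_unc) / (n_perm + 1)
  out$p_fwe[ok] <- (1 + cnt_fwe) / (n_perm + 1)
  new_brain_map(out, label, n_perm, seed)
}

#' Paired comparison of two maps' strength across parcels
#'
#' Paired two-sided t-test across parcels on the Fisher-z transformed
#' correlations, by default on absolute values (map "strength"); a signed
#' mode is available. `df = P - 1`. A map compared against itself gives a
#' difference of exactly zero and t is defined as 0.
#'
#' @param map_a,map_b `brain_map` tibbles over the same parcel set.
#' @param mode `"abs"` (default) or `"signed"`.
#' @return Tibble: mean difference, t, df, p, number of parcels.
#' @export
compare_map_strength <- function(map_a, map_b, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  if (!identical(map_a$parcel_id, map_b$parcel_id)) {
    stop_symgeo("maps cover different parcel sets")
  }
  za <- fisher_z(map_a$r)
  zb <- fisher_z(map_b$r)
  if (mode == "abs") {
    za <- abs(za)
    zb <- abs(zb)
  }
  d <- za - zb
  d <- d[is.finite(d)]
  P <- length(d)
  if (P < 2) stop_symgeo("need at least 2 common parcels")
  sdd <- sd(d)
  tval <- if (sdd == 0) 0 else mean(d) / (sdd / sqrt(P))
  tibble::tibble(
    mean_diff = mean(d), t = tval, df = P - 1,
    p = if (sdd == 0) 1 else 2 * pt(-abs(tval), P - 1), n_parcels = P
  )
}

#' Spatial correlation between two brain-behavior maps
#'
#' Pearson correlation across parcels of the Fisher-z transformed map
#' statistics.
#'
#' @param map_a,map_b `brain_map` tibbles over the same parcel set.
#' @return Tibble with `r`, `p`, `n_parcels`.
#' @export
correlate_maps <- function(map_a, map_b) {
  if (nrow(map_a) != nrow(map_b)) stop_symgeo("maps have different lengths")
  za <- fisher_z(map_a$r)
  zb <- fisher_z(map_b$r)
  keep <- is.finite(za) & is.finite(zb)
  ct <- cor.test(za[keep], zb[keep])
  tibble::tibble(
    r = unname(ct$estimate), p = ct$p.value,
    n_parcels = sum(keep)
  )
}

#' Per-network (or per-structure) follow-up correlations with Bonferroni
#'
#' Correlates aggregated GBC with the behavioral score separately per
#' level and applies a Bonferroni correction with a configurable family
#' size.
#'
#' @param agg Subjects-by-levels aggregated GBC matrix.
#' @param scores Behavioral vector.
#' @param n_tests Bonferroni family size; must be at least the number of
#'   levels (default: number of levels).
#' @return Tibble: level, n, r, p_unc, p_bonf.
#' @export
network_followups <- function(agg, scores, n_tests = ncol(agg)) {
  agg <- as.matrix(agg)
  if (n_tests < ncol(agg)) {
    stop_symgeo("`n_tests` must be at least the number of levels tested (", ncol(agg), ")")
  }
  rows <- lapply(seq_len(ncol(agg)), function(j) {
    ct <- cor.test(agg[, j], scores)
    tibble::tibble(
      level = colnames(agg)[j] %||% as.character(j),
      n = sum(stats::complete.cases(agg[, j], scores)),
      r = unname(ct$estimate), p_unc = ct$p.value,
      p_bonf = min(1, ct$p.value * n_tests)
    )
  })
  dplyr::bind_rows(rows)
}
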