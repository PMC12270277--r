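#' Pooled common axis of symptom improvement across groups
#'
#' Runs a PCA pooling all groups' change matrices, plus a separate PCA per
#' group, sign-aligns every group's first component to the pooled one, and
#' tabulates the loading-correlation similarity between all pairs. Each
#' subject's common-axis score is the projection of their standardized
#' delta row onto the pooled PC1, which coincides exactly with the pooled
#' PCA scores.
#'
#' @param deltas Either a named list of subjects-by-items matrices sharing
#'   one item set, or a single `delta_matrix` carrying a `groups`
#'   attribute.
#' @param standardize As in [fit_pca()].
#' @return A `common_axis`: list with `pooled` (pc_model), `by_group`
#'   (list of pc_models), `scores` (tibble subject_id, group, score), and
#'   `similarity` (correlation matrix of PC1 loadings, groups + pooled).
#' @export
fit_common <- function(deltas, standardize = TRUE) {
  if (is.matrix(deltas)) {
    groups <- attr(deltas, "groups")
    if (is.null(groups)) stop_symgeo("matrix input needs a `groups` attribute")
    deltas <- split.data.frame(as_plain_matrix(deltas), groups)
    deltas <- lapply(deltas, as.matrix)
  }
  items <- lapply(deltas, colnames)
  if (length(unique(vapply(items, paste, "", collapse = "\r"))) != 1) {
    stop_symgeo("groups must share an identical item set")
  }
  pooled_x <- do.call(rbind, deltas)
  pooled <- fit_pca(pooled_x, standardize = standardize)
  by_group <- lapply(deltas, fit_pca, standardize = standardize)
  for (g in names(by_group)) {
    if (cor(by_group[[g]]$loadings[, 1], pooled$loadings[, 1]) < 0) {
      by_group[[g]]$loadings[, 1] <- -by_group[[g]]$loadings[, 1]
      by_group[[g]]$scores[, 1] <- -by_group[[g]]$scores[, 1]
    }
    by_group[[g]]$group <- g
  }
  L <- cbind(
    vapply(by_group, function(m) m$loadings[, 1], numeric(nrow(pooled$loadings))),
    pooled = pooled$loadings[, 1]
  )
  scores <- tibble::tibble(
    subject_id = rownames(pooled_x) %||% sprintf("row%d", seq_len(nrow(pooled_x))),
    group = rep(names(deltas), vapply(deltas, nrow, 0L)),
    score = pooled$scores[, 1]
  )
  structure(
    list(
      pooled = pooled, by_group = by_group, scores = scores,
      similarity = cor(L)
    ),
    class = "common_axis"
  )
}

#' @export
print.common_axis <- function(x, ...) {
  cat(
    "<common_axis> groups:", paste(names(x$by_group), collapse = ", "),
    "| pooled PC1 explains",
    sprintf("%.1f%%", 100 * x$pooled$var_explained[1]), "\n"
  )
  print(round(x$similarity, 3))
  invisible(x)
}

#' Two-sample comparisons of common-axis scores
#'
#' Pooled-variance two-sample two-sided t-tests between every pair of
#' groups (`df = n1 + n2 - 2`), with Cohen's d on the pooled sd.
#'
#' @param axis A `common_axis`, or a tibble with `score` and `group`
#'   columns.
#' @param grouping Optional vector of group labels overriding the axis
#'   grouping (e.g. arm-by-response cells).
#' @return Tibble: group pair, per-group n, t, df, p, Cohen's d.
#' @export
compare_scores <- function(axis, grouping = NULL) {
  tab <- if (inherits(axis, "common_axis")) axis$scores else tibble::as_tibble(axis)
  if (!is.null(grouping)) tab$group <- grouping
  lv <- unique(tab$group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- tab$score[tab$group == pr[1]]
    b <- tab$score[tab$group == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      stop_symgeo("each group needs at least 2 subjects")
    }
    n1 <- length(a)
    n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    tval <- if (sp2 == 0) 0 else (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    tibble::tibble(
      group1 = pr[1], group2 = pr[2], n1 = n1, n2 = n2,
      t = tval, df = df, p = 2 * pt(-abs(tval), df),
      cohens_d = if (sp2 == 0) 0 else (mean(a) - mean(b)) / sqrt(sp2)
    )
  })
  dplyr::bind_rows(rows)
}

#' PCA of baseline symptom severity
#'
#' The same machinery as [fit_pca()] applied to baseline item values
#' instead of change scores; the first component is oriented so higher
#' scores mean higher overall (HRSD-anchored) severity.
#'
#' @param panel A `clinical_panel`.
#' @param visit Visit to analyse (default `"baseline"`).
#' @param subjects Optional subject subset.
#' @param standardize As in [fit_pca()].
#' @return A `pc_model`.
#' @export
baseline_pca <- function(panel, visit = "baseline", subjects = NULL,
                         standardize = TRUE) {
  m <- panel_matrix(panel, visit, subjects)
  fit_pca(m, standardize = standardize)
}

#' Baseline predictors of common-axis improvement
#'
#' For each candidate predictor, fits the sequential linear model
#' `score ~ predictor * arm` and reports the pooled and per-arm Pearson
#' correlations (or per-arm one-way F for factor predictors such as a
#' severity split), together with the predictor-by-treatment interaction F.
#'
#' @param scores Named numeric vector (or tibble subject_id/score) of
#'   common-axis scores.
#' @param predictors Tibble of per-subject predictors; first column must be
#'   `subject_id`.
#' @param arm Named vector (or tibble) of treatment arms.
#' @return A `prediction_table` tibble with one row per predictor.
#' @export
predict_improvement <- function(scores, predictors, arm) {
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$subject_id)
  if (is.data.frame(arm)) arm <- setNames(arm$arm, arm$subject_id)
  ids <- intersect(names(scores), predictors$subject_id)
  ids <- intersect(ids, names(arm))
  y <- scores[ids]
  armf <- factor(arm[ids])
  if (nlevels(armf) < 2) stop_symgeo("need two treatment arms")
  rows <- lapply(setdiff(names(predictors), "subject_id"), function(pname) {
    xv <- predictors[[pname]][match(ids, predictors$subject_id)]
    dat <- data.frame(y = y, x = xv, arm = armf)
    fit <- lm(y ~ x * arm, data = dat)
    if (anyNA(coef(fit))) {
      stop_symgeo("aliased (collinear) design for predictor ", pname)
    }
    an <- anova(fit)
    int_row <- grep(":", rownames(an))
    per_arm <- lapply(levels(armf), function(a) {
      sel <- dat$arm == a
      if (is.numeric(xv)) {
        ct <- cor.test(dat$x[sel], dat$y[sel])
        tibble::tibble(r = unname(ct$estimate), stat = unname(ct$statistic), p = ct$p.value)
      } else if (length(unique(dat$x[sel])) < 2) {
        tibble::tibble(r = NA_real_, stat = NA_real_, p = NA_real_)
      } else {
        af <- anova(lm(y ~ x, data = dat[sel, ]))
        tibble::tibble(r = NA_real_, stat = af$`F value`[1], p = af$`Pr(>F)`[1])
      }
    })
    pooled_r <- if (is.numeric(xv)) unname(cor.test(xv, y)$estimate) else NA_real_
    pooled_p <- if (is.numeric(xv)) cor.test(xv, y)$p.value else anova(lm(y ~ x, dat))$`Pr(>F)`[1]
    tibble::tibble(
      predictor = pname,
      r_pooled = pooled_r, p_pooled = pooled_p,
      r_arm1 = per_arm[[1]]$r, p_arm1 = per_arm[[1]]$p,
      r_arm2 = per_arm[[2]]$r, p_arm2 = per_arm[[2]]$p,
      interaction_F = an$`F value`[int_row],
      interaction_df1 = an$Df[int_row],
      interaction_df2 = an$Df[nrow(an)],
      interaction_p = an$`Pr(>F)`[int_row]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "arms") <- levels(armf)
  class(out) <- unique(c("prediction_table", class(out)))
  out
}

#' Median split of a baseline severity score
#'
#' Two-level high/low factor used for severity-by-treatment analyses; the
#' cut defaults to the median but is configurable.
#'
#' @param x Numeric severity values.
#' @param threshold Cut point (default `median(x)`).
#' @return Factor with levels `low`, `high`.
#' @export
severity_split <- function(x, threshold = stats::median(x)) {
  factor(ifelse(x > threshold, "high", "low"), levels = c("low", "high"))
}
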