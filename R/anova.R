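tidy_aov_summary <- function(sm) {
  strata <- names(sm)
  rows <- lapply(strata, function(snm) {
    tab <- sm[[snm]][[1]]
    tibble::tibble(
      stratum = sub("^Error: ", "", snm),
      term = trimws(rownames(tab)),
      df = tab$Df,
      sumsq = tab$`Sum Sq`,
      meansq = tab$`Mean Sq`,
      statistic = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
      p = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("anova_table", class(out)))
  out
}

check_balanced <- function(data, subject, within) {
  tab <- table(data[[subject]], data[[within]])
  if (any(tab != 1)) {
    stop_symgeo(
      "unbalanced within-subject design: every subject must contribute ",
      "exactly one row per ", within, " level"
    )
  }
}

#' Repeated-measures ANOVA of aggregated GBC with a network error stratum
#'
#' Fits `gbc ~ age + gender + site + score * treatment * network` with
#' subject as the within-subject error stratum: subject-constant terms
#' (covariates, score, treatment, score:treatment) are tested against the
#' between-subject residual, and network terms (network and its
#' interactions with score and treatment) against the subject-by-network
#' residual. Sums of squares are sequential (Type I) in the stated order,
#' covariates first. With a complete cohort of 192 subjects, 4 sites,
#' binary gender and continuous age this yields denominator df 183 in the
#' between stratum and, with 12 networks, 2068 in the within stratum.
#'
#' @param data Long tibble: one row per (subject, network) with columns
#'   `gbc`, `score`, `treatment`, `age`, `gender`, `site` and the
#'   within-subject factor.
#' @param within Name of the within-subject factor column (default
#'   `"network"`).
#' @param subject Subject id column (default `"subject_id"`).
#' @param covariates Between-subject covariate columns fitted first.
#' @return An `anova_table` tibble (stratum, term, df, SS, MS, F, p) with
#'   attributes recording the model and SS type.
#' @export
rm_anova <- function(data, within = "network", subject = "subject_id",
                     covariates = c("age", "gender", "site")) {
  data <- as.data.frame(data)
  needed <- c(subject, within, "gbc", "score", "treatment", covariates)
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop_symgeo("missing columns: ", paste(miss, collapse = ", "))
  check_balanced(data, subject, within)
  data[[subject]] <- factor(data[[subject]])
  data[[within]] <- factor(data[[within]])
  data$treatment <- factor(data$treatment)
  for (cv in covariates) {
    if (is.character(data[[cv]])) data[[cv]] <- factor(data[[cv]])
  }
  # degenerate designs reduce gracefully: a single-level treatment or a
  # constant score drops out, leaving up to the classic one-way layout
  has_trt <- nlevels(data$treatment) >= 2
  has_score <- sd(data$score) > 0
  fixed <- if (has_trt && has_score) {
    sprintf("score * treatment * %s", within)
  } else if (has_score) {
    sprintf("score * %s", within)
  } else if (has_trt) {
    sprintf("treatment * %s", within)
  } else {
    within
  }
  rhs <- paste(c(covariates, fixed), collapse = " + ")
  fml <- stats::as.formula(paste("gbc ~", rhs, "+ Error(", subject, ")"))
  # rank check on the between-subject design
  between_terms <- c(
    covariates, if (has_score) "score", if (has_trt) "treatment",
    if (has_score && has_trt) "score:treatment"
  )
  if (length(between_terms)) {
    subj_dat <- unique(data[, c(subject, "score", "treatment", covariates)])
    Xb <- stats::model.matrix(
      stats::as.formula(paste("~", paste(between_terms, collapse = "+"))),
      subj_dat
    )
    if (qr(Xb)$rank < ncol(Xb)) stop_symgeo("rank-deficient between-subject design")
  }
  fit <- aov(fml, data = data)
  out <- tidy_aov_summary(summary(fit))
  attr(out, "model") <- paste("gbc ~", rhs, "+ Error(", subject, ")")
  attr(out, "ss_type") <- "sequential (Type I)"
  out
}

#' Per-arm long-format model of improvement scores on aggregated GBC
#'
#' Within one treatment group, fits the ordinary least-squares model
#' `score ~ age + gender + site + gbc * network` on the long
#' (subject-by-network) table and reports the sequential ANOVA. Because the
#' score repeats across a subject's rows, the residual rows are pooled
#' rather than subject-stratified; denominator dfs therefore scale with
#' subjects times network levels.
#'
#' @param data Long tibble for a single arm (columns as in [rm_anova()]).
#' @param within Within-subject factor column (default `"network"`).
#' @param covariates Covariate columns fitted first.
#' @return An `anova_table` tibble.
#' @export
per_group_model <- function(data, within = "network",
                            covariates = c("age", "gender", "site")) {
  data <- as.data.frame(data)
  data[[within]] <- factor(data[[within]])
  for (cv in covariates) {
    if (is.character(data[[cv]])) data[[cv]] <- factor(data[[cv]])
  }
  fml <- stats::as.formula(paste(
    "score ~", paste(covariates, collapse = " + "),
    sprintf("+ gbc * %s", within)
  ))
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) stop_symgeo("rank-deficient design (aliased terms)")
  an <- anova(fit)
  out <- tibble::tibble(
    stratum = "pooled-rows",
    term = trimws(rownames(an)),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p = an$`Pr(>F)`
  )
  attr(out, "model") <- deparse(fml)
  attr(out, "ss_type") <- "sequential (Type I)"
  class(out) <- unique(c("anova_table", class(out)))
  out
}
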