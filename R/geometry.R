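#' Item-level change matrix between two visits
#'
#' Change is `value(from_visit) - value(to_visit)`, so for symptom-coded
#' items a positive delta means symptom reduction (improvement). Only
#' subjects complete at both visits are retained.
#'
#' @param panel A `clinical_panel`.
#' @param from_visit,to_visit Visits to difference (must differ).
#' @param subjects Optional subject subset.
#' @return A `delta_matrix`: numeric subjects-by-items matrix with
#'   attributes `orientation` (`"from_minus_to"`), `stage` label, and
#'   subject-level `groups` (treatment arm) when the panel carries arms.
#' @export
compute_deltas <- function(panel, from_visit = "baseline", to_visit = "week8",
                           subjects = NULL) {
  if (identical(from_visit, to_visit)) {
    stop_symgeo("`from_visit` and `to_visit` must differ")
  }
  subjects <- subjects %||%
    withCallingHandlers(
      analysis_set(panel, c(from_visit, to_visit)),
      message = function(m) invokeRestart("muffleMessage")
    )
  a <- panel_matrix(panel, from_visit, subjects)
  b <- panel_matrix(panel, to_visit, subjects)
  d <- a - b
  cov <- subject_covariates(panel)
  arm_col <- if (to_visit == "week16" && "arm_stage2" %in% names(cov)) "arm_stage2" else "arm"
  groups <- if (arm_col %in% names(cov)) {
    setNames(cov[[arm_col]], cov$subject_id)[rownames(d)]
  }
  structure(d,
    class = c("delta_matrix", "matrix"),
    orientation = "from_minus_to",
    stage = paste(from_visit, "to", to_visit),
    groups = groups
  )
}

# strip delta_matrix attributes for plain matrix math
as_plain_matrix <- function(x) {
  attr(x, "orientation") <- NULL
  attr(x, "stage") <- NULL
  attr(x, "groups") <- NULL
  class(x) <- "matrix"
  x
}

standardize_columns <- function(x, standardize) {
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  xs <- scale(x[, keep, drop = FALSE], center = TRUE, scale = standardize)
  list(xs = xs, keep = keep, center = attr(xs, "scaled:center"),
       scale = if (standardize) attr(xs, "scaled:scale") else NULL)
}

#' Principal component model of an item change (or score) matrix
#'
#' SVD-based PCA on column-centered and, by default, column-standardized
#' data. Zero-variance columns are dropped with a warning and re-inserted
#' as zero loadings. The first component's sign is oriented so its scores
#' correlate positively with the anchor: total reduction over HRSD items
#' when item names carry an `HRSD` prefix, otherwise the row sums of the
#' input. Remaining components get a deterministic sign (largest-magnitude
#' loading positive). Orientation is idempotent.
#'
#' @param x Subjects-by-items matrix (e.g. a `delta_matrix`).
#' @param standardize Z-score columns before the SVD (default TRUE);
#'   FALSE gives covariance-PCA.
#' @return A `pc_model`: list with `loadings` (items x components,
#'   orthonormal), `scores` (subjects x components, zero mean, diagonal
#'   covariance), `var_explained`, `sdev`, standardization record, and
#'   bookkeeping fields.
#' @export
fit_pca <- function(x, standardize = TRUE) {
  x <- as_plain_matrix(x)
  if (nrow(x) <= 2) stop_symgeo("PCA needs at least 3 subjects")
  if (all(x == 0)) stop_symgeo("all-zero input matrix")
  st <- standardize_columns(x, standardize)
  if (!all(st$keep)) {
    warning(sum(!st$keep), " zero-variance column(s) dropped from PCA: ",
      paste(utils::head(colnames(x)[!st$keep], 3), collapse = ", "),
      call. = FALSE
    )
  }
  sv <- svd(st$xs)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(k)]
  loadings <- matrix(0, ncol(x), k,
    dimnames = list(colnames(x), paste0("PC", seq_len(k)))
  )
  loadings[st$keep, ] <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  dimnames(scores) <- list(rownames(x), colnames(loadings))

  anchor <- pca_anchor(x)
  model <- structure(
    list(
      loadings = loadings, scores = scores,
      var_explained = sv$d^2 / sum(sv$d^2),
      sdev = d / sqrt(nrow(x) - 1),
      center = st$center, scale = st$scale, kept = st$keep,
      standardize = standardize, n = nrow(x),
      group = NULL, perm_p = NULL, reliability_r = NULL
    ),
    class = "pc_model"
  )
  orient_pc_model(model, anchor)
}

# Anchor for the PC1 sign convention: HRSD total when available.
pca_anchor <- function(x) {
  hrsd <- grepl("^HRSD", colnames(x) %||% character(0))
  if (any(hrsd)) rowSums(x[, hrsd, drop = FALSE]) else rowSums(x)
}

orient_pc_model <- function(model, anchor) {
  k <- ncol(model$loadings)
  if (sd(anchor) > 0 && sd(model$scores[, 1]) > 0) {
    if (cor(model$scores[, 1], anchor) < 0) {
      model$loadings[, 1] <- -model$loadings[, 1]
      model$scores[, 1] <- -model$scores[, 1]
    }
  }
  if (k > 1) {
    for (j in 2:k) {
      peak <- which.max(abs(model$loadings[, j]))
      if (model$loadings[peak, j] < 0) {
        model$loadings[, j] <- -model$loadings[, j]
        model$scores[, j] <- -model$scores[, j]
      }
    }
  }
  model
}

#' @export
print.pc_model <- function(x, ...) {
  cat(
    "<pc_model>", x$n, "subjects,", nrow(x$loadings), "items; PC1 explains",
    sprintf("%.1f%%", 100 * x$var_explained[1]), "\n"
  )
  if (!is.null(x$perm_p)) {
    cat(" perm p (PC1):", format.pval(x$perm_p[1]), "\n")
  }
  if (!is.null(x$reliability_r)) {
    cat(" split-half |r| (PC1):", round(x$reliability_r[1], 3), "\n")
  }
  invisible(x)
}

#' Project new data onto a fitted PC model
#'
#' Applies the model's centering/scaling (from the fitting sample) and the
#' stored loadings.
#'
#' @param model A `pc_model`.
#' @param x Matrix with the same item columns.
#' @param components Which components to return.
#' @return Scores matrix.
#' @export
project_scores <- function(model, x, components = seq_len(ncol(model$loadings))) {
  x <- as_plain_matrix(x)[, names(model$kept)[model$kept] %||% model$kept, drop = FALSE]
  xs <- sweep(x, 2, model$center, "-")
  if (!is.null(model$scale)) xs <- sweep(xs, 2, model$scale, "/")
  xs %*% model$loadings[model$kept, components, drop = FALSE]
}

#' Permutation significance of principal components
#'
#' Builds the null by independently permuting each item column across
#' subjects, refitting the PCA, and comparing variance-explained fractions
#' component-wise. P-values use the add-one convention
#' `p_k = (1 + #[perm >= observed]) / (n_perm + 1)`.
#'
#' @param x Subjects-by-items matrix.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @param standardize As in [fit_pca()].
#' @param n_components Number of leading components to test.
#' @return Numeric vector of per-component permutation p-values.
#' @export
pc_significance <- function(x, n_perm = 1000, seed = 1, standardize = TRUE,
                            n_components = 10) {
  if (n_perm < 1) stop_symgeo("`n_perm` must be at least 1")
  x <- as_plain_matrix(x)
  st <- standardize_columns(x, standardize)
  ve_of <- function(m) {
    d2 <- svd(m, nu = 0, nv = 0)$d^2
    d2 / sum(d2)
  }
  obs <- ve_of(st$xs)
  k <- min(n_components, length(obs))
  n <- nrow(x)
  exceed <- integer(k)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      xp <- apply(st$xs, 2, function(col) col[sample.int(n)])
      vp <- ve_of(scale(xp, center = TRUE, scale = FALSE))
      exceed <- exceed + (vp[seq_len(k)] >= obs[seq_len(k)])
    }
  })
  setNames((1 + exceed) / (n_perm + 1), paste0("PC", seq_len(k)))
}

#' Split-half cross-validation reliability of PC loadings
#'
#' For each random half-split (stratified by group when the matrix carries
#' arm labels) a PCA is fitted in each half; components are matched
#' greedily in rank order by maximal absolute loading correlation, and the
#' absolute correlation is recorded. The summary is the median over
#' splits. A component is conventionally retained when it is significant
#' and its reliability is at least 0.5.
#'
#' @param x Subjects-by-items matrix (>= 8 subjects).
#' @param n_splits Number of random splits (default 1000).
#' @param seed RNG seed.
#' @param n_components Leading components to track (default 5).
#' @param standardize As in [fit_pca()].
#' @param strata Optional stratification labels (defaults to the matrix's
#'   `groups` attribute).
#' @return Named vector of median absolute loading correlations.
#' @export
split_half_reliability <- function(x, n_splits = 1000, seed = 1,
                                   n_components = 5, standardize = TRUE,
                                   strata = NULL) {
  strata <- strata %||% attr(x, "groups")
  x <- as_plain_matrix(x)
  n <- nrow(x)
  if (n < 8) stop_symgeo("need at least 8 subjects to split")
  if (is.null(strata)) strata <- rep("all", n)
  half_loadings <- function(rows) {
    sub <- x[rows, , drop = FALSE]
    sds <- apply(sub, 2, sd)
    keep <- sds > 0
    sv <- svd(scale(sub[, keep, drop = FALSE], center = TRUE, scale = standardize))
    v <- matrix(0, ncol(x), min(n_components, ncol(sv$v)))
    v[keep, ] <- sv$v[, seq_len(ncol(v)), drop = FALSE]
    v
  }
  k <- n_components
  rel <- matrix(NA_real_, n_splits, k)
  with_seed(seed, {
    for (b in seq_len(n_splits)) {
      in_half <- logical(n)
      for (g in unique(strata)) {
        ig <- which(strata == g)
        in_half[sample(ig, length(ig) %/% 2)] <- TRUE
      }
      va <- half_loadings(in_half)
      vb <- half_loadings(!in_half)
      kk <- min(k, ncol(va), ncol(vb))
      cm <- abs(stats::cor(va[, seq_len(kk), drop = FALSE], vb[, seq_len(kk), drop = FALSE]))
      taken <- logical(kk)
      for (j in seq_len(kk)) { # greedy match in rank order
        cand <- which(!taken)
        best <- cand[which.max(cm[j, cand])]
        rel[b, j] <- cm[j, best]
        taken[best] <- TRUE
      }
    }
  })
  setNames(
    apply(rel, 2, median, na.rm = TRUE),
    paste0("PC", seq_len(k))
  )
}

#' Component retention rule
#'
#' A component is retained when its permutation p-value is below `alpha`
#' and its split-half reliability is at least `min_reliability`.
#'
#' @param perm_p Per-component permutation p-values.
#' @param reliability_r Per-component split-half reliabilities.
#' @param alpha Significance level (default 0.05).
#' @param min_reliability Retention threshold (default 0.5).
#' @return Logical vector over the common components.
#' @export
retain_components <- function(perm_p, reliability_r, alpha = 0.05,
                              min_reliability = 0.5) {
  k <- min(length(perm_p), length(reliability_r))
  setNames(
    perm_p[seq_len(k)] < alpha & reliability_r[seq_len(k)] >= min_reliability,
    paste0("PC", seq_len(k))
  )
}
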