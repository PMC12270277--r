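#' Structural degrees-of-freedom check on a complete synthetic cohort
#'
#' Runs the repeated-measures ANOVA, the pooled score t-test and the paired
#' map-strength comparison on a freshly generated complete cohort and
#' returns the design-determined degrees of freedom. With 192 subjects, 12
#' networks, 4 sites, binary gender and continuous age the expected values
#' are 183 (between-subject residual), 2068 (subject-by-network residual),
#' 190 (pooled two-sample t over 192 subjects) and 717 (paired t over 718
#' parcels).
#'
#' @param seed RNG seed.
#' @param n_subjects Cohort size (default 192).
#' @return List of degrees of freedom.
#' @export
study_printed_dfs <- function(seed = 1, n_subjects = 192L) {
  spec <- cohort_spec(
    n_subjects = n_subjects, n_parcels = 60L, n_timepoints = 60L,
    seed = derive_seed(seed, 31L)
  )
  clin <- generate_clinical(spec)
  gbc <- cohort_gbc(spec, clin$truth)
  agg <- aggregate_gbc(gbc, spec$parcellation)

  deltas <- compute_deltas(clin$panel)
  axis <- fit_common(deltas)
  tt <- compare_scores(axis)

  cov_tab <- tibble::tibble(
    subject_id = clin$truth$subject_id, score = axis$scores$score,
    treatment = clin$truth$arm, age = clin$truth$age,
    gender = clin$truth$gender, site = clin$truth$site
  )
  an <- rm_anova(gbc_long(agg$network, cov_tab))
  df_between <- an$df[an$stratum == "subject_id" & an$term == "Residuals"]
  df_within <- an$df[an$stratum == "Within" & an$term == "Residuals"]

  # map-strength df over the default 718-parcel set
  with_seed(derive_seed(seed, 32L), {
    g <- matrix(rnorm(20 * 718), 20, 718)
    s <- rnorm(20)
  })
  m1 <- map_univariate(g, s, n_perm = 19, seed = derive_seed(seed, 33L))
  m2 <- map_univariate(g, rev(s), n_perm = 19, seed = derive_seed(seed, 34L))
  cmp <- compare_map_strength(m1, m2)

  list(
    df_pc1_between = df_between,
    df_pc1_treatment_network = df_within,
    df_score_t = tt$df[tt$group1 != tt$group2][1],
    df_map_strength = cmp$df
  )
}

#' Family-wise error calibration of the max-statistic permutation test
#'
#' Simulates replicate datasets under the global null (independent Gaussian
#' GBC and scores), runs [map_univariate()] on each and reports the
#' fraction of replicates in which any parcel reaches `p_fwe <= alpha`.
#' Under a calibrated procedure this fraction estimates `alpha`.
#'
#' @param n_rep Replicate datasets (default 200).
#' @param n_parcels,n_subjects Dimensions of each replicate.
#' @param n_perm Permutations per replicate (default 199).
#' @param alpha Nominal level.
#' @param seed RNG seed.
#' @return List with `rejections`, `n_rep`, `fwer`.
#' @export
study_fwer <- function(n_rep = 200, n_parcels = 50, n_subjects = 100,
                       n_perm = 199, alpha = 0.05, seed = 1) {
  rejections <- 0L
  for (b in seq_len(n_rep)) {
    with_seed(derive_seed(seed, 41L, b), {
      g <- matrix(rnorm(n_subjects * n_parcels), n_subjects, n_parcels)
      s <- rnorm(n_subjects)
    })
    m <- map_univariate(g, s, n_perm = n_perm, seed = derive_seed(seed, 42L, b))
    rejections <- rejections + any(m$p_fwe <= alpha, na.rm = TRUE)
  }
  list(rejections = rejections, n_rep = n_rep, fwer = rejections / n_rep)
}

#' Recovery of the planted improvement geometry
#'
#' Generates cohorts under the default specification, fits per-arm and
#' pooled change-score PCAs, and measures the absolute cosine between each
#' PC1 loading vector and the planted geometry, plus the cross-arm loading
#' correlation.
#'
#' @param n_seeds Number of replicate cohorts (default 20).
#' @param seed Base seed.
#' @param n_subjects Cohort size.
#' @return Tibble with one row per replicate and columns `cos_pooled`,
#'   `cos_arm1`, `cos_arm2`, `cross_arm_r`.
#' @export
study_geometry_recovery <- function(n_seeds = 20, seed = 1, n_subjects = 192L) {
  rows <- lapply(seq_len(n_seeds), function(k) {
    spec <- cohort_spec(n_subjects = n_subjects, seed = derive_seed(seed, 51L, k))
    w <- spec$loading_geometry
    clin <- generate_clinical(spec)
    deltas <- compute_deltas(clin$panel)
    axis <- fit_common(deltas)
    arms <- names(axis$by_group)
    v1 <- axis$by_group[[arms[1]]]$loadings[, 1]
    v2 <- axis$by_group[[arms[2]]]$loadings[, 1]
    tibble::tibble(
      cos_pooled = abs(sum(axis$pooled$loadings[, 1] * w)),
      cos_arm1 = abs(sum(v1 * w)),
      cos_arm2 = abs(sum(v2 * w)),
      cross_arm_r = abs(cor(v1, v2))
    )
  })
  dplyr::bind_rows(rows)
}

#' Split-half reliability of a planted factor versus isotropic noise
#'
#' Measures the PC1 split-half reliability on a default planted cohort and
#' on a same-sized isotropic Gaussian matrix, demonstrating the behavior
#' of the retain/discard rule (reliable planted factor, unreliable noise
#' component).
#'
#' @param seed RNG seed.
#' @param n_splits Split replicates per dataset (default 200).
#' @param n_subjects,n_items Dimensions.
#' @return List with `planted` and `noise` PC1 reliabilities.
#' @export
study_reliability <- function(seed = 1, n_splits = 200, n_subjects = 192L,
                              n_items = 73L) {
  spec <- cohort_spec(n_subjects = n_subjects, seed = derive_seed(seed, 61L))
  clin <- generate_clinical(spec)
  deltas <- compute_deltas(clin$panel)
  planted <- split_half_reliability(deltas,
    n_splits = n_splits,
    seed = derive_seed(seed, 62L)
  )
  noise <- with_seed(
    derive_seed(seed, 63L),
    matrix(rnorm(n_subjects * n_items), n_subjects, n_items)
  )
  noise_rel <- split_half_reliability(noise,
    n_splits = n_splits,
    seed = derive_seed(seed, 64L)
  )
  list(planted = planted[1], noise = noise_rel[1])
}

#' Recovery of the planted arm-specific whole-brain coupling
#'
#' Generates the default cohort (planted whole-brain GBC-improvement
#' correlation 0.34 in the sertraline arm, 0 in the placebo arm), computes
#' per-subject brain-average GBC from the simulated time series, and
#' correlates it with the latent improvement per arm, with 95% Fisher
#' confidence intervals.
#'
#' @param seed RNG seed.
#' @param use_pc1 Correlate against estimated common-axis PC1 scores
#'   instead of the latent improvement (default FALSE).
#' @return Tibble per arm: `n`, `r`, `ci_lo`, `ci_hi`.
#' @export
study_coupling_recovery <- function(seed = 1, use_pc1 = FALSE) {
  spec <- cohort_spec(seed = derive_seed(seed, 71L))
  clin <- generate_clinical(spec)
  gbc <- cohort_gbc(spec, clin$truth)
  brain <- aggregate_gbc(gbc, spec$parcellation)$brain
  y <- if (use_pc1) {
    axis <- fit_common(compute_deltas(clin$panel))
    setNames(axis$scores$score, axis$scores$subject_id)[clin$truth$subject_id]
  } else {
    clin$truth$u
  }
  rows <- lapply(split(seq_len(nrow(clin$truth)), clin$truth$arm), function(i) {
    r <- cor(brain[i], y[i])
    ci <- fisher_ci(r, length(i))
    tibble::tibble(
      arm = clin$truth$arm[i[1]], n = length(i), r = r,
      ci_lo = ci[1], ci_hi = ci[2]
    )
  })
  dplyr::bind_rows(rows)
}

#' Demo pipeline configuration
#'
#' A small synthetic cohort sized so the full pipeline completes within a
#' few minutes on one CPU, used by determinism checks and examples.
#'
#' @param seed Global seed.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1) {
  run_config(
    cohort = list(n_subjects = 24L, n_parcels = 60L, n_timepoints = 80L),
    n_perm = 49, n_splits = 40, seed = seed
  )
}

#' Pipeline determinism check
#'
#' Runs the demo pipeline twice into separate directories and compares the
#' artifact checksums.
#'
#' @param seed Global seed.
#' @return TRUE when both runs produce identical manifests.
#' @export
study_determinism <- function(seed = 1) {
  d1 <- tempfile("run1_")
  d2 <- tempfile("run2_")
  on.exit(unlink(c(d1, d2), recursive = TRUE), add = TRUE)
  cfg <- demo_config(seed)
  run_pipeline(cfg, d1, quiet = TRUE)
  run_pipeline(cfg, d2, quiet = TRUE)
  m1 <- readr::read_tsv(file.path(d1, "manifest.tsv"), show_col_types = FALSE)
  m2 <- readr::read_tsv(file.path(d2, "manifest.tsv"), show_col_types = FALSE)
  identical(m1$file, m2$file) && identical(m1$md5, m2$md5)
}
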