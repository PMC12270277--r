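#' Generate a synthetic clinical panel with known latent structure
#'
#' Draws the latent improvement (`u`), baseline severity (`s`) and response
#' status of every subject, then builds ordinal item values at baseline,
#' week 8 and week 16 according to the generative model of the
#' [cohort_spec()]. Baseline items are
#' `round/clip(mu + lambda_j * s_i + noise)`; week-8 items subtract the
#' planted change `effect_scale * w_j * u_i + noise`; week-16 items are
#' generated analogously from a second improvement latent drawn after
#' stage-2 treatment reassignment. Every random draw comes from a
#' per-subject stream derived from `(seed, subject index)`, so a subset of
#' subjects is reproduced identically regardless of cohort size.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `panel` (a `clinical_panel` tibble) and
#'   `truth` (tibble of per-subject latents: `u`, `u2`, `s`,
#'   `cgi_responder`, arms, covariates).
#' @export
generate_clinical <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- spec$n_items
  w <- spec$loading_geometry
  rng <- spec$item_range
  arms <- names(spec$arm_fractions)

  effect_reach <- spec$effect_scale * max(abs(w)) *
    (max(abs(spec$arm_improvement_means)) + 2)
  if (effect_reach > diff(rng)) {
    warning("item range [", rng[1], ",", rng[2],
      "] is narrow relative to the planted effect; expect strong floor/ceiling effects",
      call. = FALSE
    )
  }

  # deterministic interleaved arm allocation and round-robin sites
  f1 <- spec$arm_fractions[[1]]
  idx <- seq_len(n)
  arm <- ifelse(floor(idx * f1) - floor((idx - 1) * f1) == 1, arms[1], arms[2])
  site <- sprintf("site%d", 1 + (idx - 1) %% spec$n_sites)

  rho <- spec$baseline_improvement_corr
  lam <- spec$baseline_loadings
  subjects <- sprintf("S%04d", idx)

  truth_rows <- vector("list", n)
  visit_values <- vector("list", n)
  for (i in idx) {
    delta_arm <- spec$arm_improvement_means[[arm[i]]]
    with_seed(derive_seed(spec$seed, 1L, i), {
      age <- round(runif(1, 18, 65))
      gender <- if (runif(1) < 0.6) "F" else "M"
      u <- rnorm(1, delta_arm, 1)
      s <- rho * (u - delta_arm) + sqrt(1 - rho^2) * rnorm(1)
      responder <- (u + rnorm(1, 0, spec$cgi_noise_sd)) > spec$cgi_threshold
      miss_w8 <- runif(1) < spec$missing_rate

      b_cont <- spec$item_mu + lam * s + rnorm(p, 0, spec$baseline_noise_sd)
      base <- if (spec$round_items) clip(round(b_cont), rng[1], rng[2]) else b_cont
      d1 <- spec$effect_scale * w * u + rnorm(p, 0, spec$delta_noise_sd)
      w8 <- if (spec$round_items) clip(round(base - d1), rng[1], rng[2]) else base - d1

      arm2 <- stage2_rule(arm[i], responder)
      u2 <- rnorm(1, spec$stage2_improvement_means[[arm2]], 1)
      d2 <- spec$effect_scale * w * u2 + rnorm(p, 0, spec$delta_noise_sd)
      w16 <- if (spec$round_items) clip(round(w8 - d2), rng[1], rng[2]) else w8 - d2
    })
    truth_rows[[i]] <- tibble::tibble(
      subject_id = subjects[i], arm = arm[i],
      arm_stage2 = if (miss_w8) NA_character_ else arm2,
      u = u, u2 = u2, s = s,
      cgi_responder = if (miss_w8) NA else responder,
      age = age, gender = gender, site = site[i]
    )
    visit_values[[i]] <- list(
      baseline = base,
      week8 = if (miss_w8) NULL else w8,
      week16 = if (miss_w8) NULL else w16
    )
  }
  truth <- dplyr::bind_rows(truth_rows)

  items <- names(w)
  long <- lapply(idx, function(i) {
    vv <- visit_values[[i]]
    vis <- names(vv)[!vapply(vv, is.null, logical(1))]
    tibble::tibble(
      subject_id = subjects[i],
      visit = rep(vis, each = p),
      item_id = rep(items, length(vis)),
      value = unlist(vv[vis], use.names = FALSE)
    )
  })
  panel <- dplyr::bind_rows(long)
  panel <- dplyr::left_join(panel, truth[, c(
    "subject_id", "arm", "arm_stage2",
    "cgi_responder", "age", "gender", "site"
  )], by = "subject_id")
  panel <- as_clinical_panel(panel, item_ranges = item_range_table(spec))
  list(panel = panel, truth = truth)
}

stage2_rule <- function(arm, responder) {
  if (is.na(responder) || responder) {
    arm
  } else if (arm == "sertraline") {
    "bupropion"
  } else if (arm == "placebo") {
    "sertraline"
  } else {
    arm
  }
}

item_range_table <- function(spec) {
  tibble::tibble(
    item_id = names(spec$loading_geometry),
    scale = sub("_.*$", "", names(spec$loading_geometry)),
    min = spec$item_range[1], max = spec$item_range[2]
  )
}

#' Apply the stage-2 treatment reassignment rule
#'
#' Sertraline nonresponders are switched to bupropion, placebo nonresponders
#' to sertraline, and responders continue their stage-1 treatment. Response
#' is the week-8 clinician-rated flag carried by the panel; subjects with a
#' missing flag are left unassigned and their count reported.
#'
#' @param panel A `clinical_panel`.
#' @return The panel with an updated `arm_stage2` column.
#' @export
stage2_assign <- function(panel) {
  stopifnot(inherits(panel, "clinical_panel"))
  subj <- dplyr::distinct(
    tibble::as_tibble(panel)[, c("subject_id", "arm", "cgi_responder")]
  )
  n_missing <- sum(is.na(subj$cgi_responder))
  if (n_missing > 0) {
    message(n_missing, " subject(s) lack a week-8 CGI flag; excluded from stage-2 assignment")
  }
  subj$arm_stage2 <- unname(mapply(stage2_rule, subj$arm, subj$cgi_responder))
  subj$arm_stage2[is.na(subj$cgi_responder)] <- NA_character_
  panel$arm_stage2 <- subj$arm_stage2[match(panel$subject_id, subj$subject_id)]
  panel
}

#' Generate parcellated resting-state time series for a cohort
#'
#' Each subject's parcel-by-timepoint matrix follows an equicorrelated
#' common-signal model `X_p(t) = alpha_i * c_i(t) + noise` with white unit
#' noise. The amplitude `alpha_i` is chosen so the expected pairwise parcel
#' correlation equals `tanh(z_i)` with the subject's coupling target
#' `z_i = coupling_base + slope_arm * u_i + subject deviation` (Fisher-z
#' scale, clipped to a correlation in `[0, 0.98]`). Optional per-network
#' gains rescale the common-signal amplitude of selected networks.
#'
#' @param spec A [cohort_spec()].
#' @param truth Truth table from [generate_clinical()].
#' @param subjects Optional subset of subject ids.
#' @return List with `timeseries` (named list of parcel-by-time matrices)
#'   and `coupling` (tibble of per-subject coupling targets).
#' @export
generate_timeseries <- function(spec, truth, subjects = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_timepoints < 10) {
    stop_symgeo("n_timepoints must be at least 10 for correlations to be meaningful")
  }
  subjects <- subjects %||% truth$subject_id
  rows <- match(subjects, truth$subject_id)
  if (anyNA(rows)) stop_symgeo("unknown subject ids")
  out <- vector("list", length(rows))
  names(out) <- subjects
  coup <- numeric(length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    sim <- simulate_subject_ts(spec, truth$arm[i], truth$u[i], i)
    out[[k]] <- sim$ts
    coup[k] <- sim$z_target
  }
  list(
    timeseries = out,
    coupling = tibble::tibble(
      subject_id = subjects, z_target = coup,
      rho_target = tanh(coup)
    )
  )
}

# One subject's time series from the per-subject stream; index is the
# subject's position in the cohort (stream id), not a row in a subset.
simulate_subject_ts <- function(spec, arm, u, index) {
  P <- spec$n_parcels
  T <- spec$n_timepoints
  slope <- spec$coupling_slope[[arm]] %||% 0
  with_seed(derive_seed(spec$seed, 2L, index), {
    z <- spec$coupling_base + slope * u + rnorm(1, 0, spec$coupling_subject_sd)
    rho <- clip(tanh(z), 0, 0.98)
    alpha <- rep(sqrt(rho / (1 - rho)), P)
    if (!is.null(spec$network_gain)) {
      for (nw in names(spec$network_gain)) {
        alpha[spec$parcellation$network == nw] <-
          alpha[spec$parcellation$network == nw] * spec$network_gain[[nw]]
      }
    }
    common <- rnorm(T)
    ts <- outer(alpha, common) + matrix(rnorm(P * T), P, T)
  })
  rownames(ts) <- spec$parcellation$parcel_id
  list(ts = ts, z_target = z)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_clinical()] and, optionally,
#' [generate_timeseries()]; the returned truth table carries the coupling
#' targets when time series are generated.
#'
#' @param spec A [cohort_spec()].
#' @param timeseries Generate time series too? (default TRUE)
#' @return Object of class `synthetic_cohort`: list with `panel`,
#'   `timeseries` (or NULL), `truth`, `spec`.
#' @export
generate_cohort <- function(spec, timeseries = TRUE) {
  clin <- generate_clinical(spec)
  ts <- NULL
  if (timeseries) {
    gen <- generate_timeseries(spec, clin$truth)
    ts <- gen$timeseries
    clin$truth <- dplyr::left_join(clin$truth, gen$coupling, by = "subject_id")
  }
  structure(
    list(panel = clin$panel, timeseries = ts, truth = clin$truth, spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort>", x$spec$n_subjects, "subjects;",
    if (is.null(x$timeseries)) "no time series" else
      paste(length(x$timeseries), "time-series matrices"), "\n"
  )
  invisible(x)
}

#' Per-subject GBC for a cohort without storing time series
#'
#' Generates each subject's time series from its own stream, reduces it to
#' the parcel-wise GBC vector and discards it, returning the
#' subjects-by-parcels GBC matrix. Equivalent to running [compute_gbc()]
#' on [generate_timeseries()] output, but with O(1) memory in the cohort
#' size.
#'
#' @param spec A [cohort_spec()].
#' @param truth Truth table from [generate_clinical()].
#' @param mode Passed to [compute_gbc()].
#' @return Numeric matrix subjects x parcels.
#' @export
cohort_gbc <- function(spec, truth, mode = "fisherz") {
  n <- nrow(truth)
  out <- matrix(NA_real_, n, spec$n_parcels,
    dimnames = list(truth$subject_id, spec$parcellation$parcel_id)
  )
  for (i in seq_len(n)) {
    idx <- match(truth$subject_id[i], sprintf("S%04d", seq_len(spec$n_subjects)))
    sim <- simulate_subject_ts(spec, truth$arm[i], truth$u[i], idx)
    out[i, ] <- compute_gbc(sim$ts, mode = mode)
  }
  out
}
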