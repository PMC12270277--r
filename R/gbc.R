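#' Global brain connectivity of a parcellated time series
#'
#' For each parcel, correlates its time series with every other parcel and
#' averages: `GBC_i = mean_{j != i} g(r_ij)` where `g` is the Fisher z
#' transform by default (`mode = "fisherz"`, correlations clipped to
#' `+/-(1 - 1e-7)` first) or the identity (`mode = "raw"`). Zero-variance
#' parcels are masked: their GBC is `NA` and they are excluded from every
#' other parcel's mean.
#'
#' @param ts Parcels-by-timepoints matrix.
#' @param mode `"fisherz"` (default) or `"raw"`.
#' @return Numeric vector of length `nrow(ts)` with `NA` at masked
#'   parcels; attributes `mask` (logical, TRUE = masked), `mode`,
#'   `n_timepoints`.
#' @export
compute_gbc <- function(ts, mode = c("fisherz", "raw")) {
  mode <- match.arg(mode)
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  if (ncol(ts) < 10) stop_symgeo("need at least 10 timepoints")
  sds <- apply(ts, 1, sd)
  mask <- !is.finite(sds) | sds == 0
  m <- sum(!mask)
  if (m == 0) stop_symgeo("all parcels are constant")
  if (m == 1) stop_symgeo("only one non-constant parcel; GBC undefined")
  R <- cor(t(ts[!mask, , drop = FALSE]))
  Z <- if (mode == "fisherz") fisher_z(R) else R
  diag(Z) <- 0
  gbc <- rep(NA_real_, nrow(ts))
  gbc[!mask] <- rowSums(Z) / (m - 1)
  names(gbc) <- rownames(ts)
  structure(gbc, mask = mask, mode = mode, n_timepoints = ncol(ts))
}

#' Aggregate parcel GBC to networks, structures and whole brain
#'
#' Unweighted means of parcel GBC per functional network, per subcortical
#' structure, and over all parcels (brain average); masked (`NA`) parcels
#' are excluded. A network with no unmasked parcel yields `NA` with a
#' warning.
#'
#' @param gbc GBC vector (one subject) or subjects-by-parcels matrix.
#' @param parcellation Parcellation table matching the parcel dimension.
#' @return List with `network` (tibble or matrix), `structure`, and
#'   `brain` (numeric).
#' @export
aggregate_gbc <- function(gbc, parcellation) {
  if (is.matrix(gbc)) {
    if (ncol(gbc) != nrow(parcellation)) {
      stop_symgeo("gbc has ", ncol(gbc), " parcels; parcellation declares ", nrow(parcellation))
    }
    group_means <- function(labels, groups) {
      m <- vapply(
        groups,
        function(g) rowMeans(gbc[, labels == g, drop = FALSE], na.rm = TRUE),
        numeric(nrow(gbc))
      )
      if (!is.matrix(m)) m <- matrix(m, nrow(gbc), dimnames = list(NULL, groups))
      rownames(m) <- rownames(gbc)
      m
    }
    nw <- group_means(parcellation$network, levels(parcellation$network))
    if (any(!is.finite(nw))) warning("some network means are undefined", call. = FALSE)
    st <- NULL
    if (!is.null(parcellation$structure)) {
      st <- group_means(parcellation$structure, levels(parcellation$structure))
    }
    list(network = nw, structure = st, brain = rowMeans(gbc, na.rm = TRUE))
  } else {
    res <- aggregate_gbc(matrix(gbc, 1, length(gbc)), parcellation)
    list(
      network = setNames(drop(res$network), colnames(res$network)),
      structure = if (!is.null(res$structure)) setNames(drop(res$structure), colnames(res$structure)),
      brain = unname(res$brain)
    )
  }
}

#' Long-format aggregated GBC table for ANOVA
#'
#' Stacks a subjects-by-levels aggregate matrix into one row per
#' (subject, level) and joins subject-level variables.
#'
#' @param agg Subjects-by-levels matrix (e.g. `aggregate_gbc()$network`).
#' @param covariates Tibble with `subject_id` and subject-level columns
#'   (scores, arm, age, gender, site).
#' @param level_name Name of the within-subject factor column (default
#'   `"network"`).
#' @return Long tibble with columns `subject_id`, `<level_name>`, `gbc`
#'   plus the covariates.
#' @export
gbc_long <- function(agg, covariates, level_name = "network") {
  df <- tibble::as_tibble(agg)
  df$subject_id <- rownames(agg) %||% covariates$subject_id
  long <- tidyr::pivot_longer(df, -"subject_id",
    names_to = level_name, values_to = "gbc"
  )
  long[[level_name]] <- factor(long[[level_name]], levels = colnames(agg))
  dplyr::left_join(long, covariates, by = "subject_id")
}
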