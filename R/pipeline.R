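#' Assemble a pipeline run configuration
#'
#' A run is driven either by a synthetic cohort specification (`cohort`,
#' a list of [cohort_spec()] arguments) or by paths to existing inputs
#' (`clinical` CSV, `timeseries_dir` of per-subject TSVs, `parcellation`
#' TSV). Paths are validated here, before any computation. All stage seeds
#' are derived deterministically from the single `seed`.
#'
#' @param cohort List of [cohort_spec()] arguments (used when no paths are
#'   given).
#' @param clinical,timeseries_dir,parcellation Optional input paths.
#' @param n_perm Permutations for PC significance and brain maps.
#' @param n_splits Split-half replicates for reliability.
#' @param gbc_mode `"fisherz"` or `"raw"`.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = list(), clinical = NULL, timeseries_dir = NULL,
                       parcellation = NULL, n_perm = 200, n_splits = 200,
                       gbc_mode = "fisherz", seed = 1L) {
  if (!is.null(clinical) || !is.null(timeseries_dir) || !is.null(parcellation)) {
    for (p in c(clinical, parcellation)) {
      if (!is.null(p) && !file.exists(p)) stop_symgeo("input path does not exist: ", p)
    }
    if (!is.null(timeseries_dir) && !dir.exists(timeseries_dir)) {
      stop_symgeo("input path does not exist: ", timeseries_dir)
    }
    if (is.null(parcellation) && !is.null(timeseries_dir)) {
      stop_symgeo("a parcellation path is required to read time series")
    }
  }
  structure(
    list(
      cohort = cohort, clinical = clinical, timeseries_dir = timeseries_dir,
      parcellation = parcellation, n_perm = n_perm, n_splits = n_splits,
      gbc_mode = gbc_mode, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_symgeo("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_symgeo("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Sequences the study end to end: synthesize (or load) the cohort;
#' item-level change PCA per arm with permutation significance and
#' split-half reliability; pooled common axis, similarity and score
#' comparisons; baseline-severity PCA and clinical prediction; parcel GBC
#' with network/structure/whole-brain aggregation; per-arm and interaction
#' brain-behavior maps with permutation FWE plus map comparisons; and the
#' repeated-measures / per-arm ANOVA battery. All artifacts are written to
#' `out_dir` together with a checksum manifest; an identical configuration
#' and seed reproduces identical checksums.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the result bundle (named list).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[symgeo] ", ...)
  seed_spec <- derive_seed(config$seed, 10L)
  seed_geom <- derive_seed(config$seed, 11L)
  seed_maps <- derive_seed(config$seed, 12L)

  say("stage: cohort")
  dat <- run_stage("cohort", {
    if (!is.null(config$clinical)) {
      panel <- read_clinical(config$clinical)
      parc <- if (!is.null(config$parcellation)) read_parcellation(config$parcellation)
      gbc <- NULL
      if (!is.null(config$timeseries_dir)) {
        files <- sort(list.files(config$timeseries_dir, full.names = TRUE))
        gbc <- t(vapply(
          files,
          function(f) as.numeric(compute_gbc(read_timeseries(f, parc), mode = config$gbc_mode)),
          numeric(nrow(parc))
        ))
        rownames(gbc) <- sub("\\..*$", "", basename(files))
      }
      list(panel = panel, parc = parc, gbc = gbc, truth = NULL)
    } else {
      spec <- do.call(cohort_spec, c(config$cohort, list(seed = seed_spec)))
      clin <- generate_clinical(spec)
      gbc <- cohort_gbc(spec, clin$truth, mode = config$gbc_mode)
      list(panel = clin$panel, parc = spec$parcellation, gbc = gbc, truth = clin$truth)
    }
  })
  panel <- dat$panel

  say("stage: geometry")
  geom <- run_stage("geometry", {
    deltas <- compute_deltas(panel, "baseline", "week8")
    arms <- attr(deltas, "groups")
    by_arm <- lapply(split(seq_along(arms), arms), function(i) {
      m <- as_plain_matrix(deltas)[i, , drop = FALSE]
      model <- fit_pca(m)
      model$perm_p <- pc_significance(m, n_perm = config$n_perm, seed = seed_geom)
      model$reliability_r <- split_half_reliability(
        m,
        n_splits = config$n_splits, seed = seed_geom
      )
      model
    })
    list(deltas = deltas, by_arm = by_arm)
  })

  say("stage: common axis")
  axis <- run_stage("common_axis", fit_common(geom$deltas))
  ttests <- run_stage("common_axis", compare_scores(axis))

  say("stage: baseline prediction")
  pred <- run_stage("prediction", {
    subjects <- axis$scores$subject_id
    base_model <- baseline_pca(panel, subjects = subjects)
    totals <- scale_totals(panel, "baseline")
    totals <- totals[match(subjects, totals$subject_id), ]
    predictors <- tibble::tibble(
      subject_id = subjects,
      HRSD = totals$HRSD, ASRM = totals$ASRM,
      CHRT = totals$CHRT, CAST = totals$CAST,
      baseline_pc1 = base_model$scores[match(subjects, rownames(base_model$scores)), 1],
      severity = severity_split(totals$HRSD)
    )
    cov <- subject_covariates(panel)
    arm <- setNames(cov$arm, cov$subject_id)[subjects]
    table <- predict_improvement(
      setNames(axis$scores$score, subjects), predictors, arm
    )
    list(base_model = base_model, table = table)
  })

  bundle <- list(
    pc1_loadings = loadings_table(geom$by_arm, axis),
    common_scores = axis$scores,
    similarity = as.data.frame(axis$similarity),
    score_ttests = ttests,
    prediction = pred$table,
    geometry_summary = geometry_summary(geom$by_arm, axis)
  )

  if (!is.null(dat$gbc)) {
    say("stage: gbc")
    neural <- run_stage("gbc", {
      agg <- aggregate_gbc(dat$gbc, dat$parc)
      cov <- subject_covariates(panel)
      ids <- intersect(axis$scores$subject_id, rownames(dat$gbc))
      scores <- setNames(axis$scores$score, axis$scores$subject_id)[ids]
      covs <- cov[match(ids, cov$subject_id), ]
      list(agg = agg, ids = ids, scores = scores, covs = covs)
    })
    say("stage: brain maps")
    maps <- run_stage("maps", {
      g <- dat$gbc[neural$ids, , drop = FALSE]
      arm <- neural$covs$arm
      resp <- as.numeric(neural$covs$cgi_responder)
      per_arm <- lapply(split(seq_along(arm), arm), function(i) {
        map_univariate(g[i, , drop = FALSE], neural$scores[i],
          n_perm = config$n_perm, seed = seed_maps
        )
      })
      cgi_maps <- lapply(split(seq_along(arm), arm), function(i) {
        if (sd(resp[i]) == 0) NULL else {
          map_univariate(g[i, , drop = FALSE], resp[i],
            n_perm = config$n_perm, seed = seed_maps
          )
        }
      })
      inter <- interaction_map(g, neural$scores, arm,
        n_perm = config$n_perm, seed = seed_maps
      )
      list(per_arm = per_arm, cgi = cgi_maps, interaction = inter)
    })
    say("stage: anovas")
    anovas <- run_stage("anova", {
      cov_tab <- tibble::tibble(
        subject_id = neural$ids, score = unname(neural$scores),
        treatment = neural$covs$arm, age = neural$covs$age,
        gender = neural$covs$gender, site = neural$covs$site
      )
      gl <- gbc_long(neural$agg$network[neural$ids, , drop = FALSE], cov_tab)
      network_rm <- rm_anova(gl)
      per_arm <- lapply(split(gl, gl$treatment), per_group_model)
      fw <- network_followups(neural$agg$network[neural$ids, , drop = FALSE],
        unname(neural$scores),
        n_tests = ncol(neural$agg$network)
      )
      list(network_rm = network_rm, per_arm = per_arm, followups = fw)
    })
    arms <- names(maps$per_arm)
    bundle$map_strength <- compare_map_strength(maps$per_arm[[arms[1]]], maps$per_arm[[arms[2]]])
    for (a in arms) {
      bundle[[paste0("map_", a)]] <- tibble::as_tibble(maps$per_arm[[a]])
      if (!is.null(maps$cgi[[a]])) {
        bundle[[paste0("map_cgi_", a)]] <- tibble::as_tibble(maps$cgi[[a]])
        bundle[[paste0("map_similarity_", a)]] <-
          correlate_maps(maps$per_arm[[a]], maps$cgi[[a]])
      }
    }
    bundle$map_interaction <- tibble::as_tibble(maps$interaction)
    bundle$anova_network <- anovas$network_rm
    for (a in names(anovas$per_arm)) {
      bundle[[paste0("anova_", a)]] <- anovas$per_arm[[a]]
    }
    bundle$network_followups <- anovas$followups
  }

  say("stage: write")
  manifest <- run_stage("write", write_tables(bundle, out_dir, config = unclass(config)))
  say("wrote ", nrow(manifest), " artifacts to ", out_dir)
  invisible(bundle)
}

loadings_table <- function(by_arm, axis) {
  out <- tibble::tibble(item_id = rownames(axis$pooled$loadings))
  for (g in names(by_arm)) out[[g]] <- by_arm[[g]]$loadings[, 1]
  out$pooled <- axis$pooled$loadings[, 1]
  out
}

geometry_summary <- function(by_arm, axis) {
  list(
    per_arm = lapply(by_arm, function(m) {
      list(
        var_explained_pc1 = m$var_explained[1],
        perm_p = as.list(m$perm_p[1:min(3, length(m$perm_p))]),
        reliability = as.list(m$reliability_r[1:min(3, length(m$reliability_r))]),
        retained_pc1 = unname(retain_components(m$perm_p, m$reliability_r)[1])
      )
    }),
    pooled_var_explained_pc1 = axis$pooled$var_explained[1],
    similarity = as.list(as.data.frame(axis$similarity))
  )
}
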