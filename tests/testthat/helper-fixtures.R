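# Small cohort spec used across tests: fast to generate, keeps all the
# structure of the default (4 scales, 73 items, 2 arms, 4 sites).
small_spec <- function(n_subjects = 30L, seed = 7L, n_timepoints = 60L, ...) {
  cohort_spec(
    n_subjects = n_subjects, n_parcels = 40L, n_timepoints = n_timepoints,
    seed = seed, ...
  )
}

# A tiny hand-checkable long panel: `values` is a list of per-visit
# item-value matrices (subjects x items).
toy_panel <- function(values, arms = NULL, items = NULL) {
  subjects <- rownames(values[[1]]) %||% sprintf("S%02d", seq_len(nrow(values[[1]])))
  items <- items %||% colnames(values[[1]]) %||% sprintf("HRSD_%02d", seq_len(ncol(values[[1]])))
  rows <- list()
  for (v in names(values)) {
    m <- values[[v]]
    rows[[v]] <- tibble::tibble(
      subject_id = rep(subjects, each = length(items)),
      visit = v,
      item_id = rep(items, length(subjects)),
      value = as.vector(t(m))
    )
  }
  x <- dplyr::bind_rows(rows)
  x$arm <- if (is.null(arms)) "sertraline" else rep(arms[match(x$subject_id, subjects)])
  x$cgi_responder <- TRUE
  x$age <- 40
  x$gender <- "F"
  x$site <- "site1"
  as_clinical_panel(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force GBC oracle: explicit double loop over parcel pairs.
gbc_bruteforce <- function(ts, fisherz = TRUE) {
  P <- nrow(ts)
  out <- numeric(P)
  for (i in seq_len(P)) {
    acc <- 0
    for (j in seq_len(P)) {
      if (i == j) next
      r <- cor(ts[i, ], ts[j, ])
      r <- min(max(r, -1 + 1e-7), 1 - 1e-7)
      acc <- acc + if (fisherz) atanh(r) else r
    }
    out[i] <- acc / (P - 1)
  }
  out
}
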