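#' Construct and validate a clinical panel
#'
#' A clinical panel is a long (tidy) table with one row per
#' (subject, visit, item): columns `subject_id`, `visit`, `item_id`,
#' `value`, plus subject-level `arm`, `cgi_responder`, `age`, `gender`,
#' `site` (and `arm_stage2` once assigned). Validation rejects duplicate
#' (subject, visit, item) triples and out-of-range item values.
#'
#' @param x Data frame in long format.
#' @param item_ranges Optional tibble `item_id`, `min`, `max` declaring
#'   ordinal bounds; when NULL, bounds are not checked.
#' @return A `clinical_panel` tibble.
#' @export
as_clinical_panel <- function(x, item_ranges = NULL) {
  x <- tibble::as_tibble(x)
  needed <- c("subject_id", "visit", "item_id", "value")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop_symgeo("panel lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  dup <- duplicated(x[, c("subject_id", "visit", "item_id")])
  if (any(dup)) {
    ex <- x[dup, ][1, ]
    stop_symgeo(
      "duplicate (subject, visit, item) records, e.g. ",
      ex$subject_id, " / ", ex$visit, " / ", ex$item_id
    )
  }
  if (!is.null(item_ranges)) {
    m <- match(x$item_id, item_ranges$item_id)
    bad <- which(!is.na(m) &
      (x$value < item_ranges$min[m] | x$value > item_ranges$max[m]))
    if (length(bad)) {
      offenders <- unique(x$item_id[bad])
      stop_symgeo(
        "item values outside declared bounds for: ",
        paste(utils::head(offenders, 5), collapse = ", "),
        if (length(offenders) > 5) ", ..." else ""
      )
    }
    attr(x, "item_ranges") <- item_ranges
  }
  if (!is.null(x$arm)) x$arm <- as.character(x$arm)
  class(x) <- unique(c("clinical_panel", class(x)))
  x
}

#' Read a clinical panel from a long-format CSV
#'
#' @param path CSV path with the columns described in [as_clinical_panel()].
#' @param item_ranges Optional bounds table (`item_id`, `min`, `max`), or
#'   path to a CSV/TSV holding one.
#' @return A validated `clinical_panel`.
#' @export
read_clinical <- function(path, item_ranges = NULL) {
  if (!file.exists(path)) stop_symgeo("no such file: ", path)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.character(item_ranges)) {
    item_ranges <- readr::read_csv(item_ranges, show_col_types = FALSE, progress = FALSE)
  }
  as_clinical_panel(x, item_ranges = item_ranges)
}

#' Write a clinical panel to CSV
#'
#' @param panel A `clinical_panel`.
#' @param path Output path; written atomically (temp file + rename).
#' @export
write_clinical <- function(panel, path) {
  atomic_write(path, function(tmp) {
    readr::write_csv(tibble::as_tibble(panel), tmp, progress = FALSE)
  })
  invisible(path)
}

#' Complete-case analysis set for a stage
#'
#' Returns the subjects holding the full item set at every required visit;
#' excluded subjects are reported. Analyses are complete-case per stage (no
#' imputation).
#'
#' @param panel A `clinical_panel`.
#' @param visits Visits that must be complete.
#' @return Character vector of subject ids.
#' @export
analysis_set <- function(panel, visits = c("baseline", "week8")) {
  items <- sort(unique(panel$item_id))
  tab <- dplyr::count(
    dplyr::filter(tibble::as_tibble(panel), .data$visit %in% visits),
    .data$subject_id, .data$visit
  )
  full <- tidyr::pivot_wider(tab, names_from = "visit", values_from = "n")
  ok <- full$subject_id[rowSums(is.na(full[-1])) == 0 &
    apply(full[-1], 1, function(r) all(r == length(items), na.rm = TRUE))]
  ok <- intersect(unique(panel$subject_id), ok)
  dropped <- setdiff(unique(panel$subject_id), ok)
  if (length(dropped)) {
    message(
      length(dropped), " subject(s) lack complete items at ",
      paste(visits, collapse = "/"), "; excluded from this analysis set"
    )
  }
  ok
}

#' Item values of one visit as a subjects-by-items matrix
#'
#' @param panel A `clinical_panel`.
#' @param visit Visit to extract.
#' @param subjects Optional subject subset (defaults to subjects complete at
#'   that visit).
#' @return Numeric matrix with subject ids as row names, item ids as
#'   column names (items in first-appearance order).
#' @export
panel_matrix <- function(panel, visit, subjects = NULL) {
  x <- dplyr::filter(tibble::as_tibble(panel), .data$visit == !!visit)
  if (!nrow(x)) stop_symgeo("no records at visit '", visit, "'")
  items <- unique(panel$item_id)
  subjects <- subjects %||% unique(x$subject_id)
  wide <- tidyr::pivot_wider(
    x[, c("subject_id", "item_id", "value")],
    names_from = "item_id", values_from = "value"
  )
  wide <- wide[match(subjects, wide$subject_id), , drop = FALSE]
  m <- as.matrix(wide[, items, drop = FALSE])
  rownames(m) <- subjects
  if (anyNA(m)) {
    keep <- rowSums(is.na(m)) == 0
    message(sum(!keep), " subject(s) incomplete at ", visit, "; dropped")
    m <- m[keep, , drop = FALSE]
  }
  m
}

#' Subject-level covariates from a panel
#'
#' @param panel A `clinical_panel`.
#' @return Tibble with one row per subject: arm, stage-2 arm (if present),
#'   CGI flag, age, gender, site.
#' @export
subject_covariates <- function(panel) {
  cols <- intersect(
    c(
      "subject_id", "arm", "arm_stage2", "cgi_responder",
      "age", "gender", "site"
    ),
    names(panel)
  )
  dplyr::distinct(tibble::as_tibble(panel)[, cols])
}

#' Per-scale total scores at a visit
#'
#' Plain item sums per scale (scale inferred from the item id prefix), the
#' conventional definition of a total score.
#'
#' @param panel A `clinical_panel`.
#' @param visit Visit to total.
#' @return Tibble subject_id x one column per scale, plus `total`.
#' @export
scale_totals <- function(panel, visit = "baseline") {
  m <- panel_matrix(panel, visit)
  scales <- sub("_.*$", "", colnames(m))
  out <- tibble::tibble(subject_id = rownames(m))
  for (sc in unique(scales)) {
    out[[sc]] <- rowSums(m[, scales == sc, drop = FALSE])
  }
  out$total <- rowSums(m)
  out
}
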