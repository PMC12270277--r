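#' Read a parcellation table
#'
#' @param path TSV with columns `parcel_id`, `network` and optionally
#'   `hemisphere`, `structure`.
#' @return Validated parcellation tibble ordered by `parcel_id`.
#' @export
read_parcellation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_parcellation(x)
}

validate_parcellation <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("parcel_id", "network") %in% names(x))) {
    stop_symgeo("parcellation needs `parcel_id` and `network` columns")
  }
  x <- x[order(x$parcel_id), ]
  if (any(duplicated(x$parcel_id)) ||
    !identical(as.integer(x$parcel_id), seq_len(nrow(x)))) {
    stop_symgeo("parcel ids must be unique and contiguous starting at 1")
  }
  if (anyNA(x$network)) stop_symgeo("every parcel needs a network label")
  if (!is.factor(x$network)) x$network <- factor(x$network)
  if (!is.null(x$structure) && !is.factor(x$structure)) {
    x$structure <- factor(x$structure)
  }
  x
}

#' Write a parcellation table to TSV
#' @param parcellation Parcellation tibble.
#' @param path Output path.
#' @export
write_parcellation <- function(parcellation, path) {
  atomic_write(path, function(tmp) {
    readr::write_tsv(parcellation, tmp, progress = FALSE)
  })
  invisible(path)
}

#' Read a parcellated time-series matrix
#'
#' Canonical format is a TSV matrix, one row per parcel and one column per
#' timepoint, optionally led by a `parcel_id` column permitting arbitrary
#' row order. A `.ptseries.nii` (CIFTI-2) file is read through the RNifti
#' package when available; the TSV dialect is the tested path.
#'
#' @param path File path.
#' @param parcellation Parcellation the rows must match.
#' @return Parcels-by-timepoints matrix ordered by `parcel_id`, with a
#'   logical `zero_variance` attribute flagging constant rows.
#' @export
read_timeseries <- function(path, parcellation) {
  if (grepl("\\.nii$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop_symgeo("reading .nii time series requires the RNifti package")
    }
    vol <- RNifti::readNifti(path)
    m <- t(drop(as.array(vol))) # CIFTI stores timepoints x parcels
  } else {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if ("parcel_id" %in% names(x)) {
      ids <- x$parcel_id
      m <- as.matrix(x[, setdiff(names(x), "parcel_id")])
      m <- m[order(ids), , drop = FALSE]
    } else {
      m <- as.matrix(x)
    }
  }
  P <- nrow(parcellation)
  if (nrow(m) != P) {
    stop_symgeo("time series has ", nrow(m), " rows; parcellation declares ", P)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop_symgeo("time series contains NaN/NA/Inf cells")
  }
  rownames(m) <- parcellation$parcel_id
  zv <- apply(m, 1, function(r) sd(r) == 0)
  if (any(zv)) {
    message(sum(zv), " zero-variance parcel row(s) flagged")
  }
  attr(m, "zero_variance") <- zv
  m
}

#' Write a time-series matrix as TSV with a parcel_id column
#' @param ts Parcels-by-timepoints matrix.
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  df <- tibble::as_tibble(as.data.frame(ts, optional = TRUE), .name_repair = "minimal")
  names(df) <- sprintf("t%d", seq_len(ncol(df)))
  df <- dplyr::bind_cols(tibble::tibble(parcel_id = seq_len(nrow(ts))), df)
  atomic_write(path, function(tmp) readr::write_tsv(df, tmp, progress = FALSE))
  invisible(path)
}
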