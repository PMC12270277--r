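# Write via a temp file in the target directory, then rename, so a partial
# write never leaves a valid-looking file behind.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop_symgeo("could not move temp file onto ", path)
  invisible(path)
}

#' Write a brain-behavior map to TSV
#'
#' Columns: `parcel_id`, `n`, `r`, `beta`, `t`, `p_unc`, `p_fwe`. Values
#' round-trip exactly through [read_map()].
#'
#' @param map A `brain_map` tibble from [map_univariate()] or
#'   [interaction_map()].
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  cols <- c("parcel_id", "n", "r", "beta", "t", "p_unc", "p_fwe")
  stopifnot(all(cols %in% names(map)))
  atomic_write(path, function(tmp) {
    readr::write_tsv(tibble::as_tibble(map)[, cols], tmp, progress = FALSE)
  })
  invisible(path)
}

#' Read a brain-behavior map written by [write_map()]
#' @param path TSV path.
#' @return A `brain_map` tibble.
#' @export
read_map <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(x) <- unique(c("brain_map", class(x)))
  x
}

# Stable hash of a configuration: md5 of its canonical JSON serialization.
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(js, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result bundle and its reproducibility manifest
#'
#' Writes every table of the bundle (TSV for tabular results, JSON for
#' summaries) into `dir`, then a `manifest.tsv` listing each artifact with
#' its md5 checksum, byte size and the config hash that produced it.
#' Re-running the pipeline with an identical configuration and seed must
#' reproduce identical checksums.
#'
#' @param bundle Named list of tibbles/data frames (written as TSV) and
#'   lists (written as JSON).
#' @param dir Output directory.
#' @param config Configuration to hash into the manifest.
#' @return Invisibly, the manifest tibble.
#' @export
write_tables <- function(bundle, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  files <- character(0)
  for (nm in names(bundle)) {
    obj <- bundle[[nm]]
    if (is.data.frame(obj)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      atomic_write(f, function(tmp) readr::write_tsv(tibble::as_tibble(obj), tmp, progress = FALSE))
    } else {
      f <- file.path(dir, paste0(nm, ".json"))
      atomic_write(f, function(tmp) {
        jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
      })
    }
    files <- c(files, f)
  }
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files),
    config_hash = hash
  )
  atomic_write(file.path(dir, "manifest.tsv"), function(tmp) {
    readr::write_tsv(manifest, tmp, progress = FALSE)
  })
  invisible(manifest)
}
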