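# Occurrence records: reading, cleaning, per-cell spatial thinning.

#' Read and clean species occurrence records
#'
#' Reads a CSV of presence records, requiring `longitude` and `latitude`
#' columns (matched case-insensitively). Cleaning drops rows with a missing
#' or unparsable coordinate and collapses exact duplicates; duplicate
#' detection rounds coordinates to 6 decimal places (about 0.11 m) first.
#' The numbers of dropped rows are reported via `message()`.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param species Species name attached to every record.
#' @return A tibble with columns `species`, `longitude`, `latitude`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("longitude,latitude", "80.1,41.2", "80.1,41.2", "79.0,"), f)
#' read_occurrences(f, species = "C. salsa")
#' @export
read_occurrences <- function(path, species = "species") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nms <- tolower(names(df))
  if (!all(c("longitude", "latitude") %in% nms)) {
    stop("CSV must have 'longitude' and 'latitude' columns (case-insensitive): ",
         path)
  }
  lon <- suppressWarnings(as.numeric(df[[which(nms == "longitude")[1]]]))
  lat <- suppressWarnings(as.numeric(df[[which(nms == "latitude")[1]]]))
  occ <- tibble::tibble(species = species, longitude = lon, latitude = lat)
  if (nrow(occ) == 0L) {
    warning("no occurrence rows in ", path)
    return(occ)
  }
  clean_occurrences(occ)
}

#' Clean an occurrence table
#'
#' Drops rows with missing or out-of-world coordinates and collapses exact
#' duplicates after rounding to 6 decimals. Idempotent.
#'
#' @param occ Tibble with `longitude` and `latitude` (and optionally
#'   `species`) columns.
#' @return The cleaned tibble, original row order preserved.
#' @export
clean_occurrences <- function(occ) {
  stopifnot(all(c("longitude", "latitude") %in% names(occ)))
  n0 <- nrow(occ)
  keep <- !is.na(occ$longitude) & !is.na(occ$latitude) &
    occ$longitude >= -180 & occ$longitude <= 180 &
    occ$latitude >= -90 & occ$latitude <= 90
  n_missing <- sum(!keep)
  occ <- occ[keep, , drop = FALSE]
  key <- paste(round(occ$longitude, 6), round(occ$latitude, 6),
               if ("species" %in% names(occ)) occ$species else "")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  out <- tibble::as_tibble(occ[!dup, , drop = FALSE])
  if (n_missing + n_dup > 0) {
    message("cleaned occurrences: dropped ", n_missing,
            " with missing/invalid coordinates, ", n_dup, " duplicates (",
            n0, " -> ", nrow(out), ")")
  }
  out
}

#' Thin occurrences to one record per grid cell
#'
#' Matches the spatial resolution of the records to that of the predictor
#' rasters: of all records falling in one cell, only the first in input
#' order is kept (deterministic). Records outside the grid extent are
#' dropped with a warning.
#'
#' @param occ Occurrence tibble (`longitude`, `latitude`, ...).
#' @param spec A [grid_spec()].
#' @return Thinned tibble with an added integer `cell` column.
#' @export
thin_to_cells <- function(occ, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  loc <- locate_cells(spec, occ$longitude, occ$latitude)
  outside <- is.na(loc$cell)
  if (any(outside)) {
    warning(sum(outside), " record(s) outside the grid extent dropped")
  }
  occ <- occ[!outside, , drop = FALSE]
  cell <- loc$cell[!outside]
  keep <- !duplicated(cell)
  out <- tibble::as_tibble(occ[keep, , drop = FALSE])
  out$cell <- cell[keep]
  out
}
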