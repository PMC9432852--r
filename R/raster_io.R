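# ESRI ASCII grid I/O and on-disk stack manifests.
#
# The ASCII grid is the package's on-disk raster format: plain text, a
# six-line header (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value)
# followed by rows north to south. Values are written with 17 significant
# digits so a write -> read round trip is bit-exact for doubles.

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file with a declared `NODATA_value`.
#' @return An `sdm_layer`; nodata cells have `NA` values.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, " (missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "), ")")
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  spec <- grid_spec(
    origin_lon = hdr$xllcorner,
    origin_lat = hdr$yllcorner + nr * hdr$cellsize,
    cell_size = hdr$cellsize, n_rows = nr, n_cols = nc
  )
  new_layer(spec, m)
}

#' Write an ESRI ASCII grid
#'
#' @param layer An `sdm_layer`.
#' @param path Output path.
#' @param nodata Sentinel written for invalid cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "sdm_layer"))
  sp <- layer$spec
  m <- layer$values
  if (any(m[!is.na(m)] == nodata)) stop("a valid cell equals the nodata sentinel")
  m[is.na(m)] <- nodata
  hdr <- c(
    paste("ncols", sp$n_cols),
    paste("nrows", sp$n_rows),
    paste("xllcorner", format(sp$origin_lon, digits = 17)),
    paste("yllcorner", format(sp$origin_lat - sp$n_rows * sp$cell_size, digits = 17)),
    paste("cellsize", format(sp$cell_size, digits = 17)),
    paste("NODATA_value", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a stack to a directory with a manifest
#'
#' Each layer goes to `<name>.asc`; `manifest.json` records layer order and
#' an optional scenario key.
#'
#' @param stack An `sdm_stack`.
#' @param dir Output directory (created if needed).
#' @param scenario Optional scenario label (e.g. `"current"`, `"SSP585"`).
#' @param period Optional period label (e.g. `"2080-2100"`).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir, scenario = NULL, period = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$layers)) {
    write_ascii_grid(get_layer(stack, nm), file.path(dir, paste0(nm, ".asc")))
  }
  manifest <- list(layers = as.list(names(stack$layers)))
  if (!is.null(scenario)) manifest$scenario <- scenario
  if (!is.null(period)) manifest$period <- period
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a stack written by [write_stack()]
#'
#' @param dir Directory containing `manifest.json` and `.asc` layers.
#' @return An `sdm_stack` with the manifest's scenario attached as attributes
#'   `scenario` / `period` when present.
#' @export
read_stack <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  layers <- lapply(manifest$layers, function(nm) {
    read_ascii_grid(file.path(dir, paste0(nm, ".asc")))
  })
  names(layers) <- manifest$layers
  spec <- layers[[1]]$spec
  st <- new_stack(spec, layers)
  attr(st, "scenario") <- manifest$scenario
  attr(st, "period") <- manifest$period
  st
}
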