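# Grid geometry and raster containers.
#
# Conventions (fixed throughout the package):
#   * coordinates are WGS84 lon/lat decimal degrees;
#   * rasters use a top-left origin, row index increasing southward;
#   * a point belongs to a cell by the half-open rule [west, east) x (south, north].

EARTH_RADIUS_KM <- 6371.0088 # IUGG mean radius

#' Define a regular lon/lat grid
#'
#' A grid is anchored at its north-west corner and uses square cells of
#' `cell_size` decimal degrees, rows increasing southward.
#'
#' @param origin_lon Longitude of the west edge (degrees).
#' @param origin_lat Latitude of the north edge (degrees).
#' @param cell_size Cell edge length in degrees (> 0).
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(80, 50, 0.5, 10, 20)
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size, n_rows, n_cols) {
  stopifnot(is.numeric(origin_lon), is.numeric(origin_lat), is.numeric(cell_size))
  if (cell_size <= 0) stop("cell_size must be > 0")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  if (origin_lon < -180 || origin_lon + n_cols * cell_size > 180 + 1e-9 ||
      origin_lat > 90 || origin_lat - n_rows * cell_size < -90 - 1e-9) {
    stop("grid extends outside [-180,180] x [-90,90]")
  }
  structure(
    list(origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Construct a raster layer
#'
#' A layer is a matrix of cell values on a [grid_spec()]; `NA` marks nodata
#' cells (the valid mask is `!is.na`).
#'
#' @param spec A `grid_spec`.
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = northernmost).
#' @return An `sdm_layer`.
#' @export
new_layer <- function(spec, values) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols) {
    stop("values must be a ", spec$n_rows, " x ", spec$n_cols, " matrix")
  }
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) stop("layer values must be finite or NA")
  structure(list(spec = spec, values = values), class = "sdm_layer")
}

#' @export
print.sdm_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<sdm_layer> %d x %d, %d valid cells, range [%g, %g]\n",
              x$spec$n_rows, x$spec$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Construct a named raster stack
#'
#' All layers share one grid; names must be unique.
#'
#' @param spec A `grid_spec`.
#' @param layers Named list of value matrices (or `sdm_layer`s).
#' @return An `sdm_stack`.
#' @export
new_stack <- function(spec, layers) {
  stopifnot(inherits(spec, "grid_spec"), is.list(layers))
  nms <- names(layers)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("layers must be uniquely named")
  }
  layers <- lapply(layers, function(l) {
    if (inherits(l, "sdm_layer")) {
      if (!same_spec(l$spec, spec)) stop("layer grid does not match stack grid")
      l$values
    } else {
      new_layer(spec, l)$values
    }
  })
  structure(list(spec = spec, layers = layers), class = "sdm_stack")
}

#' @export
print.sdm_stack <- function(x, ...) {
  cat(sprintf("<sdm_stack> %d layer(s) on %d x %d grid: %s\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

stack_names <- function(stack) names(stack$layers)

#' Extract one layer from a stack
#'
#' @param stack An `sdm_stack`.
#' @param name Layer name.
#' @return An `sdm_layer`.
#' @export
get_layer <- function(stack, name) {
  if (!name %in% names(stack$layers)) stop("no layer named '", name, "'")
  new_layer(stack$spec, stack$layers[[name]])
}

#' Joint valid mask of a stack
#'
#' @param stack An `sdm_stack`.
#' @return Logical matrix, `TRUE` where every layer is valid.
#' @export
stack_valid_mask <- function(stack) {
  Reduce(`&`, lapply(stack$layers, function(v) !is.na(v)))
}

# Cells x layers matrix over the joint valid mask; attribute "cells" holds
# the linear (column-major) cell indices so values can be written back.
stack_as_matrix <- function(stack, mask = stack_valid_mask(stack)) {
  idx <- which(mask)
  m <- vapply(stack$layers, function(v) v[idx], numeric(length(idx)))
  if (length(idx) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(stack$layers)))
  attr(m, "cells") <- idx
  m
}

#' Convert a layer to a tidy tibble
#'
#' One row per cell with cell-centre coordinates; invalid cells are dropped
#' unless `drop_na = FALSE`.
#'
#' @param layer An `sdm_layer`.
#' @param drop_na Drop nodata cells?
#' @return A tibble with `longitude`, `latitude`, `row`, `col`, `value`.
#' @export
layer_to_tibble <- function(layer, drop_na = TRUE) {
  sp <- layer$spec
  rows <- rep(seq_len(sp$n_rows), times = sp$n_cols)
  cols <- rep(seq_len(sp$n_cols), each = sp$n_rows)
  out <- tibble::tibble(
    longitude = sp$origin_lon + (cols - 0.5) * sp$cell_size,
    latitude = sp$origin_lat - (rows - 0.5) * sp$cell_size,
    row = rows, col = cols,
    value = as.vector(layer$values)
  )
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Locate points on a grid
#'
#' Maps lon/lat points to 1-based (row, col) cell indices under the half-open
#' membership rule `[west, east) x (south, north]`. Points outside the grid
#' extent get `NA` indices.
#'
#' @param spec A `grid_spec`.
#' @param longitude,latitude Numeric vectors (degrees).
#' @return A tibble with `row`, `col`, and linear `cell` index (column-major).
#' @export
locate_cells <- function(spec, longitude, latitude) {
  col <- floor((longitude - spec$origin_lon) / spec$cell_size) + 1
  row <- floor((spec$origin_lat - latitude) / spec$cell_size) + 1
  # north edge of the grid belongs to row 1; west edge to col 1 (half-open rule)
  row[latitude == spec$origin_lat] <- 1
  inside <- !is.na(row) & !is.na(col) &
    row >= 1 & row <= spec$n_rows & col >= 1 & col <= spec$n_cols
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  tibble::tibble(
    row = as.integer(row), col = as.integer(col),
    cell = as.integer(ifelse(inside, (col - 1) * spec$n_rows + row, NA))
  )
}

#' Cell-centre coordinates
#'
#' @param spec A `grid_spec`.
#' @param row,col Cell indices.
#' @return A tibble with `longitude`, `latitude`.
#' @export
cell_centers <- function(spec, row, col) {
  tibble::tibble(
    longitude = spec$origin_lon + (col - 0.5) * spec$cell_size,
    latitude = spec$origin_lat - (row - 0.5) * spec$cell_size
  )
}

#' Spherical cell areas
#'
#' Per-cell area on a sphere of radius 6371.0088 km (IUGG mean):
#' `A = R^2 * d_lambda * (sin(phi_top) - sin(phi_bottom))`. Constant along
#' each row.
#'
#' @param spec A `grid_spec`.
#' @return An `sdm_layer` of areas in km^2.
#' @export
cell_area_km2 <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  deg <- pi / 180
  phi_top <- (spec$origin_lat - (seq_len(spec$n_rows) - 1) * spec$cell_size) * deg
  phi_bot <- phi_top - spec$cell_size * deg
  band <- EARTH_RADIUS_KM^2 * (spec$cell_size * deg) * (sin(phi_top) - sin(phi_bot))
  new_layer(spec, matrix(band, nrow = spec$n_rows, ncol = spec$n_cols))
}

#' Cellwise mean over an ensemble of climate-model stacks
#'
#' Averages two or more stacks (e.g. GCM variants of one future scenario)
#' layer by layer. Nodata propagates strictly: a cell is valid in the output
#' only where it is valid in every input, so scenario masks stay comparable.
#'
#' @param stacks List of `sdm_stack`s with identical grids and layer names.
#' @return An `sdm_stack` of cellwise means.
#' @export
average_gcms <- function(stacks) {
  if (!is.list(stacks) || length(stacks) < 2L) stop("need at least 2 stacks")
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!same_spec(s$spec, ref$spec)) stop("stacks have mismatched grids")
    if (!identical(sort(names(s$layers)), sort(names(ref$layers)))) {
      stop("stacks have mismatched layer names")
    }
  }
  out <- lapply(names(ref$layers), function(nm) {
    Reduce(`+`, lapply(stacks, function(s) s$layers[[nm]])) / length(stacks)
  })
  names(out) <- names(ref$layers)
  new_stack(ref$spec, out)
}
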