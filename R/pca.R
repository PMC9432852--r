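# Correlation-matrix PCA over raster stacks.
#
# The transform is fitted on the current-scenario stack only; its means,
# standard deviations and loadings are frozen and applied unchanged to all
# future stacks, so principal-component space is comparable across scenarios.

#' Fit a PCA on the jointly valid cells of a stack
#'
#' Standardizes each layer (correlation-matrix PCA: the layers mix units)
#' and computes principal components over all cells valid in every layer.
#' The number of retained components is the smallest k whose cumulative
#' explained variance reaches `variance_target`. Loadings use a fixed sign
#' convention: each component's largest-magnitude loading is positive.
#'
#' @param stack An `sdm_stack` with at least two layers.
#' @param variance_target Cumulative explained-variance fraction in (0, 1].
#' @return A `pca_transform`: layer names, means, sds, full loading matrix,
#'   per-component explained fractions, and `n_kept`.
#' @export
fit_pca <- function(stack, variance_target = 0.95) {
  stopifnot(inherits(stack, "sdm_stack"))
  if (length(stack$layers) < 2L) stop("need at least 2 layers")
  if (variance_target <= 0 || variance_target > 1) {
    stop("variance_target must be in (0, 1]")
  }
  X <- stack_as_matrix(stack)
  if (nrow(X) < ncol(X)) stop("fewer jointly valid cells than layers")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant layer(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  loadings <- fit$rotation
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  n_kept <- which(cumsum(explained) >= variance_target - 1e-12)[1]
  structure(
    list(layer_names = colnames(X), means = fit$center, sds = fit$scale,
         loadings = loadings, explained_fraction = explained,
         eigenvalues = fit$sdev^2, n_kept = as.integer(n_kept),
         variance_target = variance_target),
    class = "pca_transform"
  )
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf(
    "<pca_transform> %d layers -> %d components (%.1f%% of variance at target %.0f%%)\n",
    length(x$layer_names), x$n_kept,
    100 * sum(x$explained_fraction[seq_len(x$n_kept)]), 100 * x$variance_target))
  invisible(x)
}

#' Tidy a PCA transform
#'
#' @param x A `pca_transform`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `eigenvalue`,
#'   `explained_fraction`, `cumulative_fraction`, `kept`.
#' @method tidy pca_transform
#' @export
tidy.pca_transform <- function(x, ...) {
  k <- length(x$explained_fraction)
  tibble::tibble(
    component = paste0("PC", seq_len(k)),
    eigenvalue = x$eigenvalues,
    explained_fraction = x$explained_fraction,
    cumulative_fraction = cumsum(x$explained_fraction),
    kept = seq_len(k) <= x$n_kept
  )
}

#' Project a stack into a fitted PC space
#'
#' Applies the frozen standardization and loadings to any scenario's stack.
#' Output layers are named `PC1..PCk` (kept components only); the output
#' mask is the intersection of the input layer masks.
#'
#' @param stack An `sdm_stack` providing exactly the fitted layer names.
#' @param transform A `pca_transform` from [fit_pca()].
#' @return An `sdm_stack` of PC score layers.
#' @export
project_pca <- function(stack, transform) {
  stopifnot(inherits(stack, "sdm_stack"), inherits(transform, "pca_transform"))
  missing <- setdiff(transform$layer_names, names(stack$layers))
  if (length(missing)) stop("stack lacks layer(s): ", paste(missing, collapse = ", "))
  mask <- Reduce(`&`, lapply(transform$layer_names,
                             function(nm) !is.na(stack$layers[[nm]])))
  idx <- which(mask)
  X <- vapply(transform$layer_names, function(nm) stack$layers[[nm]][idx],
              numeric(length(idx)))
  if (length(idx) == 1L) X <- matrix(X, nrow = 1)
  Z <- sweep(sweep(X, 2, transform$means, "-"), 2, transform$sds, "/")
  scores <- Z %*% transform$loadings[, seq_len(transform$n_kept), drop = FALSE]
  sp <- stack$spec
  out <- lapply(seq_len(transform$n_kept), function(k) {
    m <- matrix(NA_real_, sp$n_rows, sp$n_cols)
    m[idx] <- scores[, k]
    m
  })
  names(out) <- paste0("PC", seq_len(transform$n_kept))
  new_stack(sp, out)
}

#' Serialize / restore a PCA transform as JSON
#'
#' @param transform A `pca_transform`.
#' @param path JSON file path.
#' @return `path` invisibly; `pca_from_json` returns the transform.
#' @export
pca_to_json <- function(transform, path) {
  jsonlite::write_json(
    list(layer_names = transform$layer_names,
         means = unname(transform$means), sds = unname(transform$sds),
         loadings = unname(transform$loadings),
         explained_fraction = transform$explained_fraction,
         eigenvalues = transform$eigenvalues,
         n_kept = transform$n_kept, variance_target = transform$variance_target),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pca_to_json
#' @export
pca_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- x$loadings
  rownames(loadings) <- x$layer_names
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  structure(
    list(layer_names = x$layer_names,
         means = stats::setNames(x$means, x$layer_names),
         sds = stats::setNames(x$sds, x$layer_names),
         loadings = loadings, explained_fraction = x$explained_fraction,
         eigenvalues = x$eigenvalues, n_kept = as.integer(x$n_kept),
         variance_target = x$variance_target),
    class = "pca_transform")
}
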