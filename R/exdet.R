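# Extrapolation diagnostics for model transfer: ExDet (NT1 univariate
# range exceedance, NT2 Mahalanobis combinatorial novelty), the most
# influential covariate (MIC), the percentage of data nearby (%N), and
# niche-overlap statistics between suitability surfaces.

#' Extrapolation detection (ExDet)
#'
#' Compares each projection cell with the reference sample in covariate
#' space. Per covariate with reference range `[min, max]` the univariate
#' exceedance is `(x - min)/(max - min)` below the range, `(max - x)/(max
#' - min)` above it, else 0; NT1 is their sum (<= 0). Where NT1 = 0, NT2 is
#' the squared Mahalanobis distance to the reference mean scaled by the
#' reference maximum, so NT2 > 1 flags novel covariate combinations within
#' univariate ranges. Cells are classed `univariate` (NT1 < 0),
#' `combinatorial` (NT1 = 0, NT2 > 1) or `analogue` (NT1 = 0, NT2 <= 1).
#'
#' @param reference Matrix/data frame of reference rows (model training
#'   sites), columns = covariates.
#' @param projection An `sdm_stack` providing the reference covariates, or
#'   a covariate matrix.
#' @return An `exdet_result` with layers (or vectors) `nt1`, `nt2`,
#'   `exdet`, `novelty_class`, plus the reference statistics needed by
#'   [mic()].
#' @export
exdet <- function(reference, projection) {
  R <- as.matrix(reference)
  if (is.null(colnames(R))) colnames(R) <- paste0("x", seq_len(ncol(R)))
  if (nrow(R) < ncol(R) + 1L) stop("reference needs >= n_covariates + 1 rows")
  is_stack <- inherits(projection, "sdm_stack")
  if (is_stack) {
    missing <- setdiff(colnames(R), names(projection$layers))
    if (length(missing)) stop("projection lacks covariate(s): ",
                              paste(missing, collapse = ", "))
    Xm <- stack_as_matrix(projection)
    P <- Xm[, colnames(R), drop = FALSE]
    cells <- attr(Xm, "cells")
  } else {
    P <- as.matrix(projection)[, colnames(R), drop = FALSE]
    cells <- NULL
  }

  lo <- apply(R, 2, min); hi <- apply(R, 2, max)
  rng <- hi - lo
  if (any(rng == 0)) stop("zero-range reference covariate(s): ",
                          paste(colnames(R)[rng == 0], collapse = ", "))
  UD <- matrix(0, nrow(P), ncol(P), dimnames = list(NULL, colnames(P)))
  for (j in seq_len(ncol(P))) {
    x <- P[, j]
    UD[, j] <- ifelse(x < lo[j], (x - lo[j]) / rng[j],
                      ifelse(x > hi[j], (hi[j] - x) / rng[j], 0))
  }
  nt1 <- rowSums(UD)

  mu <- colMeans(R)
  S <- stats::cov(R)
  S <- ridge_if_singular(S)
  d2_ref <- stats::mahalanobis(R, mu, S)
  d2_max <- max(d2_ref)
  nt2 <- rep(NA_real_, nrow(P))
  inr <- nt1 == 0
  if (any(inr)) {
    nt2[inr] <- stats::mahalanobis(P[inr, , drop = FALSE], mu, S) / d2_max
  }
  ex <- ifelse(nt1 < 0, nt1, nt2)
  cls <- ifelse(nt1 < 0, "univariate",
                ifelse(nt2 > 1, "combinatorial", "analogue"))

  out <- list(nt1 = nt1, nt2 = nt2, exdet = ex, novelty_class = cls,
              ud = UD, reference_mean = mu, reference_cov = S,
              reference_lower = lo, reference_upper = hi,
              d2_max = d2_max, covariate_names = colnames(R),
              reference = R, proj_rows = P, cells = cells,
              spec = if (is_stack) projection$spec else NULL)
  class(out) <- "exdet_result"
  out
}

# add a small ridge when the reference covariance is near-singular
ridge_if_singular <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("near-singular reference covariance; adding ridge")
    S <- S + diag(1e-8 * sum(diag(S)) / nrow(S), nrow(S))
  }
  S
}

#' @export
print.exdet_result <- function(x, ...) {
  tab <- table(factor(x$novelty_class,
                      levels = c("univariate", "combinatorial", "analogue")))
  cat("<exdet_result>", length(x$nt1), "cells:",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

# exdet layers as sdm_layers when computed from a stack
exdet_layer <- function(result, what = c("exdet", "nt1", "nt2")) {
  what <- match.arg(what)
  if (is.null(result$spec)) stop("exdet was computed from a matrix, not a stack")
  m <- matrix(NA_real_, result$spec$n_rows, result$spec$n_cols)
  m[result$cells] <- result[[what]]
  new_layer(result$spec, m)
}

#' Most influential covariate per projection cell
#'
#' For univariate-novel cells: the covariate with the most negative
#' exceedance (ties to the first in covariate order). For combinatorial
#' cells: the covariate whose omission most reduces NT2, by exhaustive
#' leave-one-out Mahalanobis recomputation. Analogue cells get `NA`.
#'
#' @param result An `exdet_result`.
#' @return Character vector (per projection row) of covariate names.
#' @export
mic <- function(result) {
  stopifnot(inherits(result, "exdet_result"))
  n <- length(result$nt1)
  out <- rep(NA_character_, n)
  covs <- result$covariate_names

  uni <- result$novelty_class == "univariate"
  if (any(uni)) {
    out[uni] <- covs[apply(result$ud[uni, , drop = FALSE], 1, which.min)]
  }

  comb <- result$novelty_class == "combinatorial"
  if (any(comb)) {
    R <- result$reference
    # leave-one-out NT2 for every covariate
    nt2_full <- result$nt2[comb]
    drop_pct <- matrix(NA_real_, sum(comb), length(covs))
    for (j in seq_along(covs)) {
      keep <- setdiff(seq_along(covs), j)
      Rj <- R[, keep, drop = FALSE]
      Sj <- ridge_if_singular(stats::cov(Rj))
      muj <- colMeans(Rj)
      d2maxj <- max(stats::mahalanobis(Rj, muj, Sj))
      nt2_j <- stats::mahalanobis(result$proj_rows[comb, keep, drop = FALSE],
                                  muj, Sj) / d2maxj
      drop_pct[, j] <- 100 * (nt2_full - nt2_j) / nt2_full
    }
    out[comb] <- covs[apply(drop_pct, 1, which.max)]
  }
  out
}

#' Summarize extrapolation classes and most influential covariates
#'
#' Counts projection cells per novelty class (and per MIC covariate within
#' the novel classes) and reports percentages of the valid total at two
#' decimals, half-up rounding.
#'
#' @param result An `exdet_result`, or a named integer vector of class
#'   counts (names `univariate`, `combinatorial`, `analogue`).
#' @return List of two tibbles: `classes` (with sub-total and total rows)
#'   and, when `result` is an `exdet_result`, `mic` (counts by type and
#'   covariate).
#' @export
summarize_exdet <- function(result) {
  if (inherits(result, "exdet_result")) {
    counts <- table(factor(result$novelty_class,
                           levels = c("univariate", "combinatorial", "analogue")))
    counts <- stats::setNames(as.integer(counts), names(counts))
    mic_cov <- mic(result)
    mic_tab <- tibble::tibble(type = result$novelty_class, covariate = mic_cov) |>
      dplyr::filter(!is.na(.data$covariate)) |>
      dplyr::count(.data$type, .data$covariate, name = "count") |>
      dplyr::arrange(.data$type, dplyr::desc(.data$count)) |>
      dplyr::mutate(percentage = round_half_up(
        100 * .data$count / sum(counts), 2))
  } else {
    counts <- result
    if (!all(c("univariate", "combinatorial", "analogue") %in% names(counts))) {
      stop("counts must be named univariate/combinatorial/analogue")
    }
    mic_tab <- NULL
  }
  total <- sum(counts)
  pct <- function(n) round_half_up(100 * n / total, 2)
  classes <- tibble::tibble(
    type = c("univariate", "combinatorial", "sub-total", "analogue", "total"),
    count = c(counts[["univariate"]], counts[["combinatorial"]],
              counts[["univariate"]] + counts[["combinatorial"]],
              counts[["analogue"]], total),
    percentage = c(pct(counts[["univariate"]]), pct(counts[["combinatorial"]]),
                   pct(counts[["univariate"]] + counts[["combinatorial"]]),
                   pct(counts[["analogue"]]), pct(total))
  )
  out <- list(classes = classes)
  if (!is.null(mic_tab)) out$mic <- mic_tab
  out
}

# round-half-up at d decimals (R's round() is round-half-even)
round_half_up <- function(x, d = 0) {
  s <- 10^d
  floor(x * s + 0.5 + 1e-12) / s
}

#' Percentage of reference data nearby (%N)
#'
#' For each projection row, the share of reference rows lying within an
#' axis-aligned box of half-width `radius_sd` reference standard
#' deviations on every covariate. High %N means the projection point sits
#' in a well-sampled part of covariate space.
#'
#' @param reference Reference covariate matrix.
#' @param projection An `sdm_stack` or covariate matrix.
#' @param radius_sd Box half-width in reference SDs.
#' @return An `sdm_layer` (stack input) or numeric vector, values in
#'   [0, 100].
#' @export
percent_nearby <- function(reference, projection, radius_sd = 1) {
  if (radius_sd <= 0) stop("radius_sd must be > 0")
  R <- as.matrix(reference)
  if (is.null(colnames(R))) colnames(R) <- paste0("x", seq_len(ncol(R)))
  if (nrow(R) == 0L) stop("reference is empty")
  is_stack <- inherits(projection, "sdm_stack")
  if (is_stack) {
    Xm <- stack_as_matrix(projection)
    cells <- attr(Xm, "cells")
    P <- Xm[, colnames(R), drop = FALSE]
  } else {
    P <- as.matrix(projection)[, colnames(R), drop = FALSE]
  }
  sds <- apply(R, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance reference covariate(s); SD floored")
    sds <- pmax(sds, 1e-12)
  }
  half <- radius_sd * sds
  out <- vapply(seq_len(nrow(P)), function(i) {
    inside <- rep(TRUE, nrow(R))
    for (j in seq_len(ncol(R))) {
      inside <- inside & abs(R[, j] - P[i, j]) <= half[j]
      if (!any(inside)) break
    }
    100 * sum(inside) / nrow(R)
  }, 0)
  if (is_stack) {
    m <- matrix(NA_real_, projection$spec$n_rows, projection$spec$n_cols)
    m[cells] <- out
    new_layer(projection$spec, m)
  } else out
}

#' Niche overlap between two suitability surfaces
#'
#' Normalizes both layers to probability distributions over the joint
#' valid mask and reports Schoener's D = `1 - 0.5 * sum|p - q|` and
#' Warren's I = `1 - 0.5 * sum (sqrt(p) - sqrt(q))^2`. Both lie in [0, 1]
#' and equal 1 exactly when the normalized surfaces coincide.
#'
#' @param s1,s2 `sdm_layer`s on the same grid (or equal-length numeric
#'   vectors), non-negative with positive sums.
#' @return Tibble with columns `d` and `i`.
#' @export
niche_overlap <- function(s1, s2) {
  if (inherits(s1, "sdm_layer")) {
    if (!same_spec(s1$spec, s2$spec)) stop("layers on different grids")
    v1 <- as.vector(s1$values); v2 <- as.vector(s2$values)
  } else {
    v1 <- as.numeric(s1); v2 <- as.numeric(s2)
    if (length(v1) != length(v2)) stop("vectors of different lengths")
  }
  ok <- !is.na(v1) & !is.na(v2)
  if (!any(ok)) stop("empty joint valid mask")
  v1 <- v1[ok]; v2 <- v2[ok]
  if (any(v1 < 0) || any(v2 < 0)) stop("suitability surfaces must be non-negative")
  if (sum(v1) <= 0 || sum(v2) <= 0) stop("surfaces must have positive sums")
  p <- v1 / sum(v1); q <- v2 / sum(v2)
  tibble::tibble(
    d = 1 - 0.5 * sum(abs(p - q)),
    i = 1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)
  )
}
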