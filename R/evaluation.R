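# Model evaluation: hierarchical-checkerboard spatial cross-validation,
# AUC, omission rate, the Continuous Boyce Index, and CBI-maximizing model
# selection.

#' Hierarchical checkerboard fold assignment
#'
#' Two nested checkerboards at aggregation factors `a1` and `a1 * a2`
#' partition the grid into 4 spatial folds. With native cell indices
#' `(cx, cy)` (0-based):
#' `g1 = (floor(cx/a1) + floor(cy/a1)) mod 2`,
#' `g2 = (floor(cx/(a1*a2)) + floor(cy/(a1*a2))) mod 2`,
#' `fold = 1 + g1 + 2*g2`. Presences and background are partitioned by the
#' same rule, so train/test splits are spatially blocked.
#'
#' @param occ Occurrence tibble (`longitude`, `latitude`).
#' @param background Integer linear cell indices of background sites.
#' @param spec A [grid_spec()].
#' @param a1 First-level aggregation factor (>= 1).
#' @param a2 Second-level factor (>= 2); the coarse board uses `a1 * a2`.
#' @return List with `presence_fold` and `background_fold` (integers 1-4).
#' @export
checkerboard_partition <- function(occ, background, spec, a1 = 2L, a2 = 2L) {
  a1 <- as.integer(a1); a2 <- as.integer(a2)
  if (a1 < 1L || a2 < 2L) stop("need a1 >= 1 and a2 >= 2")
  loc <- locate_cells(spec, occ$longitude, occ$latitude)
  if (anyNA(loc$cell)) stop("all occurrences must fall inside the grid")
  pf <- checkerboard_fold(loc$col - 1L, loc$row - 1L, a1, a2)
  brow <- (background - 1L) %% spec$n_rows
  bcol <- (background - 1L) %/% spec$n_rows
  bf <- checkerboard_fold(bcol, brow, a1, a2)
  missing_pres <- setdiff(1:4, unique(pf))
  if (length(missing_pres)) {
    warning("fold(s) without presences: ", paste(missing_pres, collapse = ", "))
  }
  list(presence_fold = pf, background_fold = bf, a1 = a1, a2 = a2)
}

checkerboard_fold <- function(cx, cy, a1, a2) {
  g1 <- (cx %/% a1 + cy %/% a1) %% 2L
  g2 <- (cx %/% (a1 * a2) + cy %/% (a1 * a2)) %% 2L
  as.integer(1L + g1 + 2L * g2)
}

#' Area under the ROC curve for presence vs background predictions
#'
#' Mann-Whitney statistic `U / (n_p * n_b)` with ties counted one half.
#'
#' @param pred_presence,pred_background Numeric prediction vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(pred_presence, pred_background) {
  np <- length(pred_presence); nb <- length(pred_background)
  if (np == 0L || nb == 0L) stop("auc needs non-empty presence and background")
  r <- rank(c(pred_presence, pred_background), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Continuous Boyce Index
#'
#' Slides `n_windows` overlapping windows of width `window_frac` across
#' the landscape's habitat-rank scale: predictions are first mapped
#' through the landscape's empirical CDF, so windows hold (near-)equal
#' numbers of landscape cells and the index is an exact rank statistic
#' (invariant under any strictly increasing transform of the
#' predictions). In each window, P = fraction of evaluation presences and
#' E = fraction of landscape cells; the index is the Spearman rank
#' correlation (average ranks for ties) between P/E and the window
#' midpoints. +1 means presence density increases with predicted
#' suitability (good calibration), 0 chance, -1 inverted.
#'
#' The defaults (201 narrow windows of 0.5% of the rank range) keep the
#' windows close to independent, which concentrates the index near zero
#' for uninformative predictions; see the methods vignette for the
#' calibration behind this choice.
#'
#' @param pred_presence Predictions at evaluation presences.
#' @param pred_landscape An `sdm_layer` or numeric vector of landscape
#'   predictions.
#' @param n_windows Number of sliding windows.
#' @param window_frac Window width as a fraction of the rank range.
#' @return A `boyce_curve`: tibble of retained windows (`midpoint`, `P`,
#'   `E`, `F`) with the index in `$cbi`.
#' @export
cbi <- function(pred_presence, pred_landscape, n_windows = 201L,
                window_frac = 0.005) {
  land <- if (inherits(pred_landscape, "sdm_layer")) {
    as.vector(pred_landscape$values)
  } else as.numeric(pred_landscape)
  land <- land[!is.na(land)]
  if (length(unique(land)) < 2L) stop("landscape needs >= 2 distinct values")
  if (length(pred_presence) == 0L) stop("no evaluation presences")
  to_rank <- stats::ecdf(land)
  land <- to_rank(land)
  pred_presence <- to_rank(pred_presence)
  lo <- min(land); hi <- max(land)
  W <- window_frac * (hi - lo)
  starts <- seq(lo, hi - W, length.out = n_windows)
  P <- E <- mid <- numeric(n_windows)
  for (k in seq_len(n_windows)) {
    a <- starts[k]; b <- a + W
    P[k] <- mean(pred_presence >= a & pred_presence <= b)
    E[k] <- mean(land >= a & land <= b)
    mid[k] <- a + W / 2
  }
  keep <- E > 0
  if (sum(keep) < 3L) stop("fewer than 3 windows contain landscape cells")
  Fr <- P[keep] / E[keep]
  index <- stats::cor(rank(Fr), rank(mid[keep]))
  structure(
    list(windows = tibble::tibble(midpoint = mid[keep], P = P[keep],
                                  E = E[keep], F = Fr),
         cbi = index, n_windows = n_windows, window_frac = window_frac),
    class = "boyce_curve"
  )
}

#' @export
print.boyce_curve <- function(x, ...) {
  cat(sprintf("<boyce_curve> CBI = %.3f over %d retained windows\n",
              x$cbi, nrow(x$windows)))
  invisible(x)
}

#' Omission rate at a training-percentile threshold
#'
#' The threshold is the given percentile of the training presence
#' predictions under the linear-interpolation ("type 7") quantile rule;
#' the omission rate is the fraction of test presences strictly below it.
#'
#' @param pred_train Training presence predictions.
#' @param pred_test Test presence predictions.
#' @param percentile Percentile in (0, 100).
#' @return Omission rate in [0, 1].
#' @export
omission_rate <- function(pred_train, pred_test, percentile = 10) {
  if (length(pred_train) == 0L || length(pred_test) == 0L) {
    stop("omission_rate needs non-empty train and test predictions")
  }
  if (percentile <= 0 || percentile >= 100) stop("percentile must be in (0, 100)")
  thr <- stats::quantile(pred_train, percentile / 100, type = 7, names = FALSE)
  mean(pred_test < thr)
}

#' Select the best candidate model settings
#'
#' Argmax of mean CBI; ties broken by lower mean omission rate, then
#' higher mean AUC, then first in candidate order.
#'
#' @param candidates Tibble with one row per candidate and columns
#'   `cbi_mean`, `or_mean`, `auc_mean` (others, e.g. `classes`, `rm`, are
#'   carried through).
#' @return The winning row of `candidates`.
#' @export
select_model <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  ok <- is.finite(candidates$cbi_mean)
  if (!any(ok)) stop("no candidate has a valid mean CBI")
  cand <- candidates[ok, , drop = FALSE]
  ord <- order(-cand$cbi_mean, cand$or_mean, -cand$auc_mean,
               seq_len(nrow(cand)))
  cand[ord[1], , drop = FALSE]
}

#' Cross-validate one maxent settings choice
#'
#' Fits the model on three folds and evaluates on the held-out fold, for
#' each of the 4 checkerboard folds; folds without presences are skipped
#' with a warning.
#'
#' @param X Covariate matrix over presence + background rows.
#' @param presence Logical row roles.
#' @param folds Integer fold labels per row (1-4).
#' @param pred_landscape Numeric vector of landscape predictions used as
#'   the CBI reference distribution (recomputed per fold model).
#' @param land_X Covariate matrix of landscape cells for per-fold CBI.
#' @param classes,rm,k_h Maxent settings.
#' @param or_percentile Omission-rate training percentile.
#' @param cbi_windows,cbi_window_frac CBI parameters.
#' @param tol,max_iter Optimizer controls.
#' @return Tibble with one row per evaluated fold: `fold`, `auc`, `cbi`,
#'   `or`.
#' @export
cv_maxent <- function(X, presence, folds, land_X, classes, rm, k_h = 20,
                      or_percentile = 10, cbi_windows = 101L,
                      cbi_window_frac = 0.1, tol = 1e-8, max_iter = 5000L) {
  res <- list()
  for (f in 1:4) {
    test <- folds == f
    if (sum(presence & test) == 0L || sum(presence & !test) == 0L) {
      warning("fold ", f, " lacks presences; skipped")
      next
    }
    if (sum(!presence & !test) < 2L) {
      warning("fold ", f, " lacks training background; skipped")
      next
    }
    model <- fit_maxent(X[!test, , drop = FALSE], presence[!test],
                        classes = classes, rm = rm, k_h = k_h,
                        tol = tol, max_iter = max_iter)
    land_pred <- predict(model, land_X, type = "cloglog")
    p_test <- predict(model, X[presence & test, , drop = FALSE], type = "cloglog")
    p_train <- predict(model, X[presence & !test, , drop = FALSE], type = "cloglog")
    b_test <- if (sum(!presence & test) > 0L) {
      predict(model, X[!presence & test, , drop = FALSE], type = "cloglog")
    } else land_pred
    res[[length(res) + 1L]] <- tibble::tibble(
      fold = f,
      auc = auc(p_test, b_test),
      cbi = tryCatch(cbi(p_test, land_pred, cbi_windows, cbi_window_frac)$cbi,
                     error = function(e) NA_real_),
      or = omission_rate(p_train, p_test, or_percentile)
    )
  }
  dplyr::bind_rows(res)
}

#' Aggregate per-fold metrics to mean and SD
#'
#' @param fold_metrics Tibble from [cv_maxent()].
#' @return One-row tibble with `auc_mean`, `auc_sd`, `cbi_mean`, `cbi_sd`,
#'   `or_mean`, `or_sd`, `n_folds`.
#' @export
aggregate_metrics <- function(fold_metrics) {
  tibble::tibble(
    auc_mean = mean(fold_metrics$auc),
    auc_sd = stats::sd(fold_metrics$auc),
    cbi_mean = mean(fold_metrics$cbi, na.rm = TRUE),
    cbi_sd = stats::sd(fold_metrics$cbi, na.rm = TRUE),
    or_mean = mean(fold_metrics$or),
    or_sd = stats::sd(fold_metrics$or),
    n_folds = nrow(fold_metrics)
  )
}
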