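# Feature construction for the maximum-entropy model.
#
# Covariates are rescaled by their training bounds; the basis holds linear
# (L), quadratic (Q) and hinge (H) transforms, all mapped into [0, 1].
# Hinge knots are equally spaced strictly inside the bounds, k_h per
# direction per covariate.

#' Define a feature set from training covariates
#'
#' Bounds come from the union of presence and background training rows.
#' Constant covariates are dropped with a warning.
#'
#' @param data Data frame or matrix of training covariate values.
#' @param classes Character vector, subset of `c("L", "Q", "H")`, or a
#'   compact string like `"LQH"`.
#' @param k_h Hinge knots per direction per covariate.
#' @return A `feature_set`.
#' @export
feature_set <- function(data, classes = c("L", "Q", "H"), k_h = 20) {
  classes <- parse_classes(classes)
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  const <- hi <= lo
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    lo <- lo[!const]; hi <- hi[!const]
  }
  if (ncol(X) == 0L) stop("no non-constant covariates")
  knots <- lapply(seq_len(ncol(X)), function(j) {
    lo[j] + seq_len(k_h) * (hi[j] - lo[j]) / (k_h + 1)
  })
  names(knots) <- colnames(X)
  structure(
    list(classes = classes, covariate_names = colnames(X),
         lower = lo, upper = hi, k_h = as.integer(k_h), knots = knots),
    class = "feature_set"
  )
}

parse_classes <- function(classes) {
  if (length(classes) == 1L && nchar(classes) > 1L) {
    classes <- strsplit(classes, "")[[1]]
  }
  classes <- toupper(classes)
  bad <- setdiff(classes, c("L", "Q", "H"))
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  if (length(classes) == 0L) stop("at least one feature class required")
  unique(classes)
}

#' Evaluate a feature set on covariate values
#'
#' Covariates are clamped to the training bounds before evaluation, so
#' features stay in [0, 1] under projection; extrapolation is reported
#' separately by the ExDet diagnostics rather than extrapolated here.
#'
#' @param fs A `feature_set`.
#' @param data Data frame or matrix providing the fitted covariates.
#' @return Numeric matrix, one column per feature. Column names encode the
#'   feature: `L:cov`, `Q:cov`, `HF:cov:k` (forward hinge), `HR:cov:k`
#'   (reverse hinge).
#' @export
build_features <- function(fs, data) {
  stopifnot(inherits(fs, "feature_set"))
  X <- as.matrix(data)
  missing <- setdiff(fs$covariate_names, colnames(X))
  if (length(missing)) stop("missing covariate(s): ", paste(missing, collapse = ", "))
  X <- X[, fs$covariate_names, drop = FALSE]
  cols <- list()
  for (j in seq_along(fs$covariate_names)) {
    nm <- fs$covariate_names[j]
    lo <- fs$lower[j]; hi <- fs$upper[j]
    x <- pmin(pmax(X[, j], lo), hi)
    lin <- (x - lo) / (hi - lo)
    if ("L" %in% fs$classes) cols[[paste0("L:", nm)]] <- lin
    if ("Q" %in% fs$classes) cols[[paste0("Q:", nm)]] <- lin^2
    if ("H" %in% fs$classes) {
      for (k in seq_along(fs$knots[[nm]])) {
        t <- fs$knots[[nm]][k]
        cols[[paste0("HF:", nm, ":", k)]] <- pmax(0, (x - t) / (hi - t))
        cols[[paste0("HR:", nm, ":", k)]] <- pmax(0, (t - x) / (t - lo))
      }
    }
  }
  do.call(cbind, cols)
}

# class of each feature column ("L", "Q" or "H"), from the encoded name
feature_class_of <- function(feature_names) {
  ifelse(startsWith(feature_names, "L:"), "L",
         ifelse(startsWith(feature_names, "Q:"), "Q", "H"))
}

# covariate owning each feature column
feature_covariate_of <- function(feature_names) {
  vapply(strsplit(feature_names, ":", fixed = TRUE), `[`, "", 2)
}
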