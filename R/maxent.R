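# Maximum-entropy presence-background model.
#
# The model estimates the Gibbs distribution over background sites that
# maximizes entropy subject to (soft) feature-mean constraints. Fitting
# maximizes the L1-penalized log likelihood
#
#   L(lambda) = mean_presence(lambda . f) - log sum_background exp(lambda . f)
#               - sum_j beta_j |lambda_j|
#
# which is concave; the optimizer is an active-set scheme: coordinates
# violating the KKT conditions enter the working set, the fixed-sign smooth
# subproblem is solved by projected quasi-Newton (L-BFGS-B on a
# non-negative reparametrization), and the loop repeats until the
# projected-subgradient norm meets the tolerance. Each subproblem solve can
# only lower the penalized objective, so the outer objective trace is
# monotone.

# Published default regularization table: per-class base value as a function
# of presence sample size m, linearly interpolated and clamped at the ends
# (hinge features use a constant 0.5).
maxent_base_beta <- function(class, m) {
  lq_m <- c(0, 10, 30, 100)
  lq_b <- c(1.0, 1.0, 0.2, 0.05)
  switch(class,
    L = ,
    Q = stats::approx(lq_m, lq_b, xout = min(max(m, 0), 100), rule = 2)$y,
    H = 0.5,
    stop("unknown feature class: ", class)
  )
}

#' Fit a maximum-entropy presence-background model
#'
#' @param data Data frame or matrix of covariate values, presences and
#'   background together.
#' @param presence Logical vector: `TRUE` for presence rows.
#' @param classes Feature classes, e.g. `"LQH"` or `c("L","Q")`.
#' @param rm Regularization multiplier (> 0).
#' @param k_h Hinge knots per direction per covariate.
#' @param tol Convergence tolerance on the infinity norm of the minimal
#'   projected subgradient.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   final gradient norm.
#' @param output Default prediction transform: `"cloglog"`, `"logistic"`
#'   or `"raw"`.
#' @return A `maxent_model` holding the feature set, coefficients,
#'   per-feature penalties, `log_partition` (log Z over the training
#'   background) and `entropy` of the fitted background distribution.
#' @export
fit_maxent <- function(data, presence, classes = "LQH", rm = 1, k_h = 20,
                       tol = 1e-8, max_iter = 5000L, output = "cloglog") {
  presence <- as.logical(presence)
  X <- as.matrix(data)
  if (nrow(X) != length(presence)) stop("presence must match data rows")
  if (anyNA(X)) stop("covariate values must not be missing")
  m <- sum(presence)
  if (m < 1L) stop("need at least 1 presence row")
  if (sum(!presence) < 2L) stop("need at least 2 background rows")
  if (rm <= 0) stop("rm must be > 0")
  output <- match.arg(output, c("cloglog", "logistic", "raw"))

  fs <- feature_set(X, classes = classes, k_h = k_h)
  Fm <- build_features(fs, X)
  Fp <- Fm[presence, , drop = FALSE]
  Fb <- Fm[!presence, , drop = FALSE]

  cls <- feature_class_of(colnames(Fm))
  s <- pmax(apply(Fp, 2, stats::sd), 1e-4)
  if (m == 1L) s <- rep(1e-4, ncol(Fm)) # SD undefined for a single presence
  beta <- rm * vapply(cls, maxent_base_beta, 0, m = m) * s / sqrt(m)

  opt <- maxent_optimize(a = colMeans(Fp), B = Fb, beta = beta,
                         tol = tol, max_iter = max_iter)

  eta_b <- drop(Fb %*% opt$lambda)
  logZ <- logsumexp(eta_b)
  q <- exp(eta_b - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))

  structure(
    list(feature_set = fs, coefficients = stats::setNames(opt$lambda, colnames(Fm)),
         penalties = stats::setNames(beta, colnames(Fm)), rm = rm,
         classes = fs$classes, log_partition = logZ, entropy = H,
         output = output, n_presence = m, n_background = nrow(Fb),
         converged = opt$converged, iterations = opt$iterations,
         grad_norm = opt$grad_norm, objective = opt$objective,
         objective_trace = opt$trace),
    class = "maxent_model"
  )
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Minimize g(l) + sum(beta |l|), g(l) = -a.l + logsumexp(B l).
# Active-set outer loop over sign-fixed smooth subproblems; errors if the
# projected-subgradient tolerance is not met within max_iter total inner
# iterations.
maxent_optimize <- function(a, B, beta, tol, max_iter) {
  p <- length(a)
  g_val <- function(l) -sum(a * l) + logsumexp(drop(B %*% l))
  g_grad <- function(l) {
    eta <- drop(B %*% l)
    q <- exp(eta - logsumexp(eta))
    drop(crossprod(B, q)) - a
  }
  obj <- function(l) g_val(l) + sum(beta * abs(l))
  # minimal-norm subgradient (projected gradient) in the infinity norm
  pg_norm <- function(l, g) {
    at0 <- l == 0
    r <- numeric(length(l))
    r[!at0] <- g[!at0] + beta[!at0] * sign(l[!at0])
    r[at0] <- pmax(abs(g[at0]) - beta[at0], 0)
    max(abs(r))
  }

  x <- numeric(p)
  sgn <- integer(p) # working signs; 0 = out of the active set
  it_total <- 0L
  trace <- numeric(0)
  gnorm <- pg_norm(x, g_grad(x))
  outer <- 0L
  while (gnorm > tol) {
    outer <- outer + 1L
    g <- g_grad(x)
    # KKT screening: zero coordinates whose gradient exceeds the penalty
    # enter with the descent sign; active coordinates keep their sign
    viol <- x == 0 & abs(g) > beta
    sgn[x != 0] <- sign(x[x != 0])
    sgn[viol] <- -sign(g[viol])
    active <- which(sgn != 0L)
    if (length(active) == 0L) break # fully shrunk solution is optimal
    s <- sgn[active]
    # subproblem in u = s * l_active >= 0: smooth + linear penalty.
    # Only active columns of B enter, and the forward pass is shared
    # between objective and gradient calls at the same point.
    Ba <- B[, active, drop = FALSE]
    aa <- a[active]
    ba <- beta[active]
    memo_u <- NULL; memo_q <- NULL; memo_lse <- NULL
    forward <- function(u) {
      if (is.null(memo_u) || !identical(u, memo_u)) {
        eta <- drop(Ba %*% (s * u))
        lse <- logsumexp(eta)
        memo_q <<- exp(eta - lse); memo_lse <<- lse; memo_u <<- u
      }
    }
    fn <- function(u) {
      forward(u)
      -sum(aa * s * u) + memo_lse + sum(ba * u)
    }
    gr <- function(u) {
      forward(u)
      s * (drop(crossprod(Ba, memo_q)) - aa) + ba
    }
    fit <- stats::optim(pmax(s * x[active], 0), fn, gr, method = "L-BFGS-B",
                        lower = 0,
                        control = list(maxit = max_iter, factr = 1,
                                       pgtol = tol / 2, lmm = 20))
    if (fit$value < -1e10) {
      stop("maxent likelihood is unbounded: some feature's presence mean ",
           "lies outside the background hull (a presence site missing from ",
           "the background). Include the presence sites in the background.")
    }
    it_total <- it_total + fit$counts[["gradient"]]
    # clamp numerically-zero solutions to exact zero so the working sign
    # cannot wedge on a rounding residual at the bound
    u_new <- pmax(fit$par, 0)
    u_new[u_new < 1e-12] <- 0
    x_new <- numeric(p); x_new[active] <- s * u_new
    if (obj(x_new) <= obj(x) + 1e-12) x <- x_new
    sgn[x == 0] <- 0L
    trace <- c(trace, obj(x))
    gnorm <- pg_norm(x, g_grad(x))
    if (outer > 100L) break
  }
  if (gnorm > tol) {
    stop(sprintf(
      "maxent optimizer did not converge in %d iterations (projected gradient norm %.3e > %.1e)",
      it_total, gnorm, tol))
  }
  list(lambda = x, converged = TRUE, iterations = it_total,
       grad_norm = gnorm, objective = -obj(x), trace = -trace)
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %s features over %d covariate(s); %d/%d nonzero coefficients\n",
    paste(x$classes, collapse = ""), length(x$feature_set$covariate_names),
    sum(x$coefficients != 0), length(x$coefficients)))
  cat(sprintf("  rm = %g, logZ = %.4f, entropy = %.4f, output = %s\n",
              x$rm, x$log_partition, x$entropy, x$output))
  invisible(x)
}

#' Tidy a fitted maximum-entropy model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `feature`, `class`, `covariate`,
#'   `estimate`, `penalty`.
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  nms <- names(x$coefficients)
  tibble::tibble(
    feature = nms,
    class = feature_class_of(nms),
    covariate = feature_covariate_of(nms),
    estimate = unname(x$coefficients),
    penalty = unname(x$penalties)
  )
}

#' One-row summary of a fitted maximum-entropy model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with fit-level quantities (entropy, log partition,
#'   penalized objective, iteration count, sparsity).
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$n_presence, n_background = x$n_background,
    n_features = length(x$coefficients),
    n_nonzero = sum(x$coefficients != 0),
    entropy = x$entropy, log_partition = x$log_partition,
    objective = x$objective, iterations = x$iterations,
    rm = x$rm
  )
}

# linear predictor + raw density for a covariate matrix
maxent_raw <- function(model, X) {
  Fm <- build_features(model$feature_set, X)
  exp(drop(Fm %*% model$coefficients) - model$log_partition)
}

maxent_transform <- function(raw, entropy, type) {
  switch(type,
    raw = raw,
    cloglog = 1 - exp(-exp(entropy) * raw),
    logistic = {
      er <- exp(entropy) * raw
      er / (1 + er)
    },
    stop("unknown output type: ", type)
  )
}

#' Predict habitat suitability from a fitted model
#'
#' Covariates are clamped to the training bounds before feature evaluation.
#' The raw output is the Gibbs density normalized over the training
#' background (it sums to 1 there); `cloglog` maps it to (0,1) via
#' `1 - exp(-e^H * raw)` with H the fitted entropy.
#'
#' @param object A `maxent_model`.
#' @param newdata An `sdm_stack` (returns an `sdm_layer`) or a data
#'   frame/matrix of covariates (returns a numeric vector).
#' @param type `"cloglog"`, `"logistic"` or `"raw"`; defaults to the
#'   model's `output` setting.
#' @param ... Unused.
#' @return An `sdm_layer` or numeric vector of suitabilities.
#' @export
predict.maxent_model <- function(object, newdata, type = NULL, ...) {
  type <- if (is.null(type)) object$output else
    match.arg(type, c("cloglog", "logistic", "raw"))
  if (inherits(newdata, "sdm_stack")) {
    missing <- setdiff(object$feature_set$covariate_names, names(newdata$layers))
    if (length(missing)) stop("stack lacks covariate(s): ",
                              paste(missing, collapse = ", "))
    X <- stack_as_matrix(newdata)
    raw <- maxent_raw(object, X)
    out <- maxent_transform(raw, object$entropy, type)
    sp <- newdata$spec
    m <- matrix(NA_real_, sp$n_rows, sp$n_cols)
    m[attr(X, "cells")] <- out
    new_layer(sp, m)
  } else {
    raw <- maxent_raw(object, as.matrix(newdata))
    maxent_transform(raw, object$entropy, type)
  }
}

#' Sample background cells from a stack
#'
#' Uniform, without replacement, over jointly valid cells (all of them if
#' fewer than `n`).
#'
#' @param stack An `sdm_stack`.
#' @param n Background size.
#' @param seed RNG seed.
#' @return Integer vector of linear cell indices.
#' @export
sample_background <- function(stack, n = 10000L, seed = 1L) {
  cells <- which(stack_valid_mask(stack))
  if (length(cells) <= n) return(cells)
  withr_seed(seed, sample(cells, n))
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Permutation importance of each covariate
#'
#' Shuffles one covariate at a time across the valid cells of `stack`
#' (seeded), recomputes the AUC of presence vs background predictions, and
#' reports the AUC drop, floored at zero and normalized to sum to 100.
#'
#' @param model A `maxent_model`.
#' @param stack Covariate stack the model predicts from.
#' @param occ Occurrence tibble (`longitude`, `latitude`).
#' @param n_perm Permutations per covariate (averaged).
#' @param seed RNG seed.
#' @param background Optional integer cell indices; defaults to a seeded
#'   10,000-cell sample.
#' @return Tibble with `covariate`, `auc_drop`, `importance` (percent).
#' @export
permutation_importance <- function(model, stack, occ, n_perm = 10L, seed = 1L,
                                   background = NULL) {
  stopifnot(inherits(model, "maxent_model"), inherits(stack, "sdm_stack"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- stack_as_matrix(stack)
  cells <- attr(X, "cells")
  loc <- locate_cells(stack$spec, occ$longitude, occ$latitude)
  pres_idx <- match(loc$cell, cells)
  pres_idx <- pres_idx[!is.na(pres_idx)]
  if (length(pres_idx) == 0L) stop("no presences fall on valid cells")
  if (is.null(background)) background <- sample_background(stack, seed = seed)
  bg_idx <- match(background, cells)
  bg_idx <- bg_idx[!is.na(bg_idx)]

  pred <- maxent_raw(model, X)
  auc0 <- auc(pred[pres_idx], pred[bg_idx])

  covs <- model$feature_set$covariate_names
  drops <- withr_seed(seed, vapply(covs, function(cv) {
    mean(vapply(seq_len(n_perm), function(k) {
      Xp <- X
      Xp[, cv] <- X[sample.int(nrow(X)), cv]
      predp <- maxent_raw(model, Xp)
      auc0 - auc(predp[pres_idx], predp[bg_idx])
    }, 0))
  }, 0))
  drops <- pmax(drops, 0)
  total <- sum(drops)
  imp <- if (total > 0) 100 * drops / total else {
    warning("all permutation AUC drops are zero; importances undefined, returning 0")
    drops
  }
  tibble::tibble(covariate = covs, auc_drop = unname(drops),
                 importance = unname(imp))
}

#' Serialize / restore a maxent model as JSON
#'
#' @param model A `maxent_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `maxent_from_json` returns the model.
#' @export
maxent_to_json <- function(model, path) {
  fs <- model$feature_set
  jsonlite::write_json(
    list(classes = fs$classes, covariate_names = fs$covariate_names,
         lower = unname(fs$lower), upper = unname(fs$upper), k_h = fs$k_h,
         coefficients = as.list(model$coefficients),
         penalties = as.list(model$penalties), rm = model$rm,
         log_partition = model$log_partition, entropy = model$entropy,
         output = model$output, n_presence = model$n_presence,
         n_background = model$n_background),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname maxent_to_json
#' @export
maxent_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  knots <- lapply(seq_along(x$covariate_names), function(j) {
    x$lower[j] + seq_len(x$k_h) * (x$upper[j] - x$lower[j]) / (x$k_h + 1)
  })
  names(knots) <- x$covariate_names
  fs <- structure(
    list(classes = x$classes, covariate_names = x$covariate_names,
         lower = stats::setNames(x$lower, x$covariate_names),
         upper = stats::setNames(x$upper, x$covariate_names),
         k_h = as.integer(x$k_h), knots = knots),
    class = "feature_set")
  structure(
    list(feature_set = fs, coefficients = unlist(x$coefficients),
         penalties = unlist(x$penalties), rm = x$rm, classes = fs$classes,
         log_partition = x$log_partition, entropy = x$entropy,
         output = x$output, n_presence = x$n_presence,
         n_background = x$n_background, converged = TRUE),
    class = "maxent_model")
}
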