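# Feature construction and the L1-penalized maximum-entropy fit.

test_that("features respect their boundary values", {
  X <- cbind(v = c(0, 1, 0.75, 0.3))
  fs <- feature_set(X, classes = "LQH", k_h = 1) # single knot at 0.5
  Fm <- build_features(fs, X)
  # x = min: L = Q = 0, forward hinge 0, reverse hinge positive
  expect_equal(unname(Fm[1, c("L:v", "Q:v", "HF:v:1")]), c(0, 0, 0))
  expect_gt(Fm[1, "HR:v:1"], 0)
  # x = max: L = Q = 1
  expect_equal(unname(Fm[2, c("L:v", "Q:v")]), c(1, 1))
  # hand evaluation at x = 0.75 with knot 0.5 on [0, 1]
  expect_equal(unname(Fm[3, "HF:v:1"]), 0.5)
  expect_equal(unname(Fm[3, "HR:v:1"]), 0)
  expect_true(all(Fm >= 0 & Fm <= 1))

  # constant covariates are dropped with a warning
  X2 <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(fs2 <- feature_set(X2, "L"), "b")
  expect_equal(fs2$covariate_names, "a")
})

test_that("infinite regularization shrinks every coefficient to zero", {
  prob <- toy_problem(seed = 2)
  m <- fit_maxent(prob$X, prob$presence, classes = "LQH", rm = 1e8, k_h = 5)
  expect_true(all(m$coefficients == 0))
  n_bg <- sum(!prob$presence)
  raw <- predict(m, prob$X[!prob$presence, , drop = FALSE], type = "raw")
  expect_equal(raw, rep(1 / n_bg, n_bg), tolerance = 1e-12)
  # cloglog of the uniform model is 1 - exp(-1)
  expect_equal(predict(m, prob$X[1:3, , drop = FALSE], type = "cloglog"),
               rep(1 - exp(-1), 3), tolerance = 1e-9)
})

test_that("a single-feature fit matches a golden-section oracle", {
  # one binary L feature: presences mostly at 1, background half and half
  x <- c(rep(1, 38), rep(0, 2), rep(0, 100), rep(1, 100))
  presence <- c(rep(TRUE, 40), rep(FALSE, 200))
  m <- fit_maxent(cbind(v = x), presence, classes = "L", rm = 1)
  beta <- unname(m$penalties)
  f_p <- x[presence]; f_b <- x[!presence]
  neg_obj <- function(l) {
    -(mean(f_p * l) - log(sum(exp(f_b * l))) - beta * abs(l))
  }
  gold <- optimize(neg_obj, c(-20, 20), tol = 1e-10)
  expect_equal(unname(m$coefficients), gold$minimum, tolerance = 1e-5)
})

test_that("the fitted distribution satisfies the L1 KKT moment conditions", {
  for (seed in 1:10) {
    prob <- toy_problem(n_pres = 40, n_bg = 200, n_cov = 2, seed = seed)
    m <- fit_maxent(prob$X, prob$presence, classes = "LQH", rm = 1, k_h = 4)
    Fm <- build_features(m$feature_set, prob$X)
    q <- predict(m, prob$X[!prob$presence, , drop = FALSE], type = "raw")
    model_mean <- drop(crossprod(Fm[!prob$presence, , drop = FALSE], q))
    pres_mean <- colMeans(Fm[prob$presence, , drop = FALSE])
    expect_true(all(abs(model_mean - pres_mean) <= m$penalties + 1e-6),
                label = paste("KKT moment match, seed", seed))
  }
})

test_that("the optimum matches an exhaustively refined grid search (<= 2 features)", {
  prob <- toy_problem(n_pres = 30, n_bg = 150, n_cov = 2, seed = 3)
  m <- fit_maxent(prob$X, prob$presence, classes = "L", rm = 1)
  Fm <- build_features(m$feature_set, prob$X)
  Fp <- Fm[prob$presence, , drop = FALSE]
  Fb <- Fm[!prob$presence, , drop = FALSE]
  beta <- m$penalties
  obj <- function(l1, l2) {
    eta <- Fb %*% c(l1, l2)
    mean(Fp %*% c(l1, l2)) - log(sum(exp(eta))) - sum(beta * abs(c(l1, l2)))
  }
  # multi-resolution exhaustive grid: 41 x 41, zooming 6 times
  ctr <- c(0, 0); half <- 10
  for (round in 1:6) {
    g1 <- seq(ctr[1] - half, ctr[1] + half, length.out = 41)
    g2 <- seq(ctr[2] - half, ctr[2] + half, length.out = 41)
    vals <- outer(g1, g2, Vectorize(obj))
    best <- arrayInd(which.max(vals), dim(vals))
    ctr <- c(g1[best[1]], g2[best[2]])
    half <- half / 8
  }
  expect_equal(m$objective, obj(ctr[1], ctr[2]), tolerance = 1e-6)
  expect_gte(m$objective + 1e-12, obj(ctr[1], ctr[2]))
})

test_that("the penalized objective trace is monotone and gain grows with nesting", {
  prob <- toy_problem(n_pres = 50, n_bg = 250, n_cov = 2, seed = 4)
  m <- fit_maxent(prob$X, prob$presence, classes = "LQH", rm = 1, k_h = 5)
  expect_true(all(diff(m$objective_trace) >= -1e-12))

  # nested classes can only increase the optimal penalized objective
  objs <- vapply(c("L", "LQ", "LQH"), function(cl) {
    fit_maxent(prob$X, prob$presence, classes = cl, rm = 1, k_h = 5)$objective
  }, 0)
  expect_true(all(diff(objs) >= -1e-8))
})

test_that("raw predictions conserve probability over the training background", {
  for (cl in c("L", "LQ", "LQH")) {
    prob <- toy_problem(n_pres = 40, n_bg = 300, n_cov = 2, seed = 5)
    m <- fit_maxent(prob$X, prob$presence, classes = cl, rm = 1, k_h = 5)
    raw <- predict(m, prob$X[!prob$presence, , drop = FALSE], type = "raw")
    expect_equal(sum(raw), 1, tolerance = 1e-6)
    expect_true(m$entropy >= 0 && m$entropy <= log(m$n_background) + 1e-9)
  }
})

test_that("prediction clamps covariates to the training bounds", {
  prob <- toy_problem(seed = 6)
  m <- fit_maxent(prob$X, prob$presence, classes = "LQH", rm = 1, k_h = 5)
  hi <- max(prob$X[, 1])
  inside <- predict(m, cbind(v1 = hi), type = "raw")
  beyond <- predict(m, cbind(v1 = hi + 50), type = "raw")
  expect_equal(beyond, inside, tolerance = 1e-12)
})

test_that("a maxent model survives the JSON round trip", {
  prob <- toy_problem(seed = 7)
  m <- fit_maxent(prob$X, prob$presence, classes = "LQH", rm = 2, k_h = 5)
  f <- withr::local_tempfile(fileext = ".json")
  maxent_to_json(m, f)
  back <- maxent_from_json(f)
  new_pts <- cbind(v1 = seq(-2, 2, length.out = 7))
  expect_equal(predict(back, new_pts), predict(m, new_pts), tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in broom shape", {
  prob <- toy_problem(seed = 8)
  m <- fit_maxent(prob$X, prob$presence, classes = "LQ", rm = 1)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("feature", "class", "covariate", "estimate", "penalty"))
  expect_equal(nrow(td), length(m$coefficients))
  gl <- glance(m)
  expect_equal(gl$n_nonzero, sum(m$coefficients != 0))
})

test_that("permutation importance attributes signal to the informative covariate", {
  # a one-covariate model concentrates all importance
  sp <- toy_spec(20, 20)
  set.seed(9)
  grad <- matrix(rep(seq(0, 1, length.out = 20), each = 20), 20, 20)
  noise <- matrix(runif(400), 20, 20)
  st <- new_stack(sp, list(sig = grad, noi = noise))
  occ <- tibble::tibble(longitude = runif(40, 82, 84.9),
                        latitude = runif(40, 40.1, 44.9)) # high-sig half
  occ <- thin_to_cells(occ, sp)
  X <- stack_as_matrix_for_test(st)
  pres <- match(occ$cell, attr(X, "cells"))
  Xfit <- rbind(X[pres, ], X)
  presence <- c(rep(TRUE, length(pres)), rep(FALSE, nrow(X)))
  m1 <- fit_maxent(Xfit[, "sig", drop = FALSE], presence, classes = "LQ", rm = 1)
  imp1 <- permutation_importance(m1, new_stack(sp, list(sig = grad)), occ,
                                 n_perm = 3, seed = 1)
  expect_equal(imp1$importance, 100)

  # a covariate whose every coefficient is zero gets importance 0
  m2 <- fit_maxent(Xfit, presence, classes = "LQ", rm = 1)
  if (all(tidy(m2)$estimate[tidy(m2)$covariate == "noi"] == 0)) {
    imp2 <- permutation_importance(m2, st, occ, n_perm = 3, seed = 1)
    expect_equal(imp2$importance[imp2$covariate == "noi"], 0)
    expect_equal(imp2$importance[imp2$covariate == "sig"], 100)
  }
})
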