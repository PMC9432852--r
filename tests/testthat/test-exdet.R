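# Extrapolation detection, covariate attribution, %N, niche overlap.

ref_2cov <- function(n = 60, seed = 1, rho = 0) {
  set.seed(seed)
  a <- rnorm(n); b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  cbind(a = a, b = b)
}

test_that("NT1 follows the univariate exceedance formula", {
  R <- cbind(a = seq(0, 10, length.out = 20))
  # below the range by 1 unit on range 10: UD = -0.1
  res <- exdet(R, cbind(a = c(-1, 5, 12)))
  expect_equal(res$nt1, c(-0.1, 0, -0.2))
  expect_equal(res$novelty_class, c("univariate", "analogue", "univariate"))

  # at the reference mean: NT1 = 0, NT2 = 0, analogue
  R2 <- ref_2cov()
  res2 <- exdet(R2, rbind(colMeans(R2)))
  expect_equal(res2$nt1, 0)
  expect_equal(res2$nt2, 0)
  expect_equal(res2$novelty_class, "analogue")
})

test_that("NT2 equals an independent Mahalanobis computation", {
  R <- ref_2cov(n = 80, seed = 2, rho = 0.6)
  set.seed(3)
  P <- cbind(a = runif(30, min(R[, "a"]), max(R[, "a"])),
             b = runif(30, min(R[, "b"]), max(R[, "b"])))
  res <- exdet(R, P)
  # oracle: explicit quadratic form with solve()
  mu <- colMeans(R); Si <- solve(cov(R))
  d2 <- apply(P, 1, function(x) drop(t(x - mu) %*% Si %*% (x - mu)))
  d2max <- max(apply(R, 1, function(x) drop(t(x - mu) %*% Si %*% (x - mu))))
  expect_lt(max(abs(res$nt2 - d2 / d2max)), 1e-10)
  # combinatorial iff scaled distance exceeds 1 within the ranges
  expect_equal(res$novelty_class == "combinatorial", res$nt2 > 1)
})

test_that("novelty classes partition the projection cells", {
  R <- ref_2cov(n = 100, seed = 4, rho = 0.8)
  set.seed(5)
  P <- cbind(a = rnorm(200, 0, 2), b = rnorm(200, 0, 2))
  res <- exdet(R, P)
  counts <- table(factor(res$novelty_class,
                         c("univariate", "combinatorial", "analogue")))
  expect_equal(sum(counts), 200)
  expect_true(all(res$nt1 <= 0))
  expect_true(all(res$nt2[res$novelty_class != "univariate"] >= 0))
  # exdet layer is NT1 where negative, NT2 otherwise
  expect_equal(res$exdet, ifelse(res$nt1 < 0, res$nt1, res$nt2))
})

test_that("exdet is invariant to consistent affine covariate rescaling", {
  R <- ref_2cov(n = 60, seed = 6, rho = 0.5)
  set.seed(7)
  P <- cbind(a = rnorm(50, 0, 2), b = rnorm(50, 0, 2))
  res0 <- exdet(R, P)
  Rs <- R; Ps <- P
  Rs[, "a"] <- 100 * Rs[, "a"] - 7; Ps[, "a"] <- 100 * Ps[, "a"] - 7
  Rs[, "b"] <- -0.5 * Rs[, "b"] + 3; Ps[, "b"] <- -0.5 * Ps[, "b"] + 3
  res1 <- exdet(Rs, Ps)
  expect_equal(res1$nt1, res0$nt1, tolerance = 1e-10)
  ok <- res0$novelty_class != "univariate"
  expect_equal(res1$nt2[ok], res0$nt2[ok], tolerance = 1e-8)
})

test_that("MIC picks the worst exceedance / largest leave-one-out NT2 drop", {
  R <- ref_2cov(n = 60, seed = 8)
  lo <- apply(R, 2, min)
  # exactly one covariate out of range
  res1 <- exdet(R, cbind(a = lo[1] - 1, b = 0))
  expect_equal(mic(res1), "a")
  # most negative exceedance wins; ties go to the first covariate
  rng <- apply(R, 2, function(x) diff(range(x)))
  res2 <- exdet(R, cbind(a = lo[1] - 0.3 * rng[1], b = lo[2] - 0.1 * rng[2]))
  expect_equal(mic(res2), "a")

  # combinatorial attribution matches exhaustive leave-one-out recomputation
  set.seed(9)
  R3 <- cbind(ref_2cov(n = 120, seed = 10, rho = 0.9),
              c = rnorm(120))
  P3 <- cbind(a = c(1.5, -1, 0.5), b = c(-1.5, 1, -0.5), c = c(0, 0, 2))
  P3 <- P3 * 0.9 # keep inside univariate ranges
  res3 <- exdet(R3, P3)
  m <- mic(res3)
  expect_true(any(res3$novelty_class == "combinatorial"))
  for (i in which(res3$novelty_class == "combinatorial")) {
    drops <- vapply(1:3, function(j) {
      keep <- setdiff(1:3, j)
      Rj <- R3[, keep]; muj <- colMeans(Rj); Sij <- solve(cov(Rj))
      d2 <- drop(t(P3[i, keep] - muj) %*% Sij %*% (P3[i, keep] - muj))
      d2m <- max(apply(Rj, 1, function(x)
        drop(t(x - muj) %*% Sij %*% (x - muj))))
      100 * (res3$nt2[i] - d2 / d2m) / res3$nt2[i]
    }, 0)
    expect_equal(m[i], colnames(R3)[which.max(drops)])
  }
  expect_true(all(is.na(m[res3$novelty_class == "analogue"])))
})

test_that("shifting one covariate makes it the modal MIC among novel cells", {
  R <- ref_2cov(n = 100, seed = 11, rho = 0.3)
  set.seed(12)
  P <- cbind(a = rnorm(200, 0, 0.5), b = rnorm(200, 0, 0.5))
  base_cls <- exdet(R, P)$novelty_class
  P2 <- P; P2[, "b"] <- P2[, "b"] + 2 * sd(R[, "b"])
  res <- exdet(R, P2)
  newly <- base_cls == "analogue" & res$novelty_class != "analogue"
  modal <- names(which.max(table(mic(res)[newly])))
  expect_equal(modal, "b")
})

test_that("class-count summaries reproduce half-up two-decimal percentages", {
  counts <- c(univariate = 73980L, combinatorial = 6696L, analogue = 19612L)
  s <- summarize_exdet(counts)$classes
  expect_equal(s$percentage[s$type == "univariate"], 73.77)
  expect_equal(s$percentage[s$type == "combinatorial"], 6.68)
  expect_equal(s$percentage[s$type == "sub-total"], 80.44)
  expect_equal(s$percentage[s$type == "analogue"], 19.56)
  expect_equal(s$count[s$type == "total"], 100288L)

  # degenerate world: everything analogue
  s2 <- summarize_exdet(c(univariate = 0L, combinatorial = 0L,
                          analogue = 50L))$classes
  expect_equal(s2$percentage[s2$type == "analogue"], 100)
})

test_that("percent nearby counts reference rows in the SD box", {
  R <- ref_2cov(n = 40, seed = 13)
  # a projection point equal to a reference row sees all rows within reach
  # only if they are close; identical reference rows give 100
  Rsame <- matrix(rep(c(0.3, -0.2), each = 25), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  expect_warning(pn <- percent_nearby(Rsame, rbind(c(a = 0.3, b = -0.2))),
                 "zero-variance")
  expect_equal(pn, 100)
  # a point 1e6 SDs away sees nothing
  far <- rbind(c(a = 1e6 * sd(R[, "a"]), b = 0))
  expect_equal(percent_nearby(R, far), 0)
  # constructed half-split: half the rows inside the box on one axis
  Rh <- cbind(a = c(rep(0, 10), rep(10, 10)), b = rep(0, 20))
  expect_warning(ph <- percent_nearby(Rh, rbind(c(a = 0, b = 0)),
                                      radius_sd = 1), "zero-variance")
  expect_equal(ph, 50)
  # direct enumeration oracle on random data
  set.seed(14)
  P <- cbind(a = rnorm(20), b = rnorm(20))
  got <- percent_nearby(R, P, radius_sd = 1.5)
  sds <- apply(R, 2, sd)
  oracle <- sapply(seq_len(nrow(P)), function(i) {
    100 * mean(abs(R[, 1] - P[i, 1]) <= 1.5 * sds[1] &
               abs(R[, 2] - P[i, 2]) <= 1.5 * sds[2])
  })
  expect_equal(got, oracle)
})

test_that("niche overlap statistics behave like D and I should", {
  sp <- grid_spec(0, 2, 1, 1, 2)
  # proportional surfaces are identical after normalization
  s1 <- new_layer(sp, matrix(c(0.2, 0.6), 1, 2))
  s2 <- new_layer(sp, matrix(c(0.1, 0.3), 1, 2))
  ov <- niche_overlap(s1, s2)
  expect_equal(ov$d, 1)
  expect_equal(ov$i, 1)
  # disjoint supports share nothing
  ov0 <- niche_overlap(new_layer(sp, matrix(c(1, 0), 1, 2)),
                       new_layer(sp, matrix(c(0, 1), 1, 2)))
  expect_equal(ov0$d, 0)
  expect_equal(ov0$i, 0)
  # hand-computed two-cell case: p = (1,0), q = (0.5,0.5)
  ovh <- niche_overlap(new_layer(sp, matrix(c(1, 0), 1, 2)),
                       new_layer(sp, matrix(c(0.5, 0.5), 1, 2)))
  expect_equal(ovh$d, 0.5)
  expect_equal(ovh$i, 1 - 0.5 * (2 - sqrt(2)), tolerance = 1e-12)
  # D = I = 1 iff the normalized surfaces coincide (both directions)
  set.seed(15)
  for (k in 1:5) {
    v <- runif(10); w <- runif(10)
    ovr <- niche_overlap(v, w)
    expect_lt(ovr$d, 1); expect_lt(ovr$i, 1)
    ovp <- niche_overlap(v, 3.7 * v)
    expect_equal(ovp$d, 1); expect_equal(ovp$i, 1)
  }
  expect_error(niche_overlap(c(NA, NA), c(1, 2)), "empty joint")
})
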