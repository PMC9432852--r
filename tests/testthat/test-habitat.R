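# Jenks breaks, habitat classification, change accounting, reserve rules.

# exhaustive Fisher-Jenks oracle: try every placement of k-1 boundaries
jenks_oracle_ssd <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- sum(vapply(seq_len(k), function(c) {
      ssd(x[(cuts[c] + 1):cuts[c + 1]])
    }, 0))
    if (tot < best) best <- tot
  }
  best
}

classes_ssd <- function(x, breaks) {
  cls <- findInterval(x, breaks, left.open = TRUE) + 1
  sum(vapply(unique(cls), function(c) {
    v <- x[cls == c]; sum((v - mean(v))^2)
  }, 0))
}

test_that("jenks breaks separate obvious groups and reject degenerate input", {
  br <- jenks_breaks(c(1, 1, 1, 9, 9, 9), k = 2)
  expect_length(br, 1)
  expect_gte(br, 1); expect_lt(br, 9)
  expect_equal(classes_ssd(c(1, 1, 1, 9, 9, 9), br), 0)
  expect_error(jenks_breaks(rep(3, 10), k = 2), "distinct")
  expect_error(jenks_breaks(c(1, 2, 3), k = 5), "distinct")
})

test_that("the dynamic program equals exhaustive enumeration (n <= 15, k <= 4)", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 10), 2)
    if (length(unique(x)) < k) next
    br <- jenks_breaks(x, k)
    expect_equal(classes_ssd(x, br), jenks_oracle_ssd(x, k), tolerance = 1e-9,
                 label = paste("rep", rep))
  }
})

test_that("large inputs are subsampled deterministically", {
  set.seed(21)
  x <- runif(2e5)
  b1 <- jenks_breaks(x, 4, max_exact = 1e5, subsample = 2000, seed = 9)
  b2 <- jenks_breaks(x, 4, max_exact = 1e5, subsample = 2000, seed = 9)
  expect_identical(b1, b2)
  expect_length(b1, 3)
})

test_that("classification is right-closed and matches a histogram oracle", {
  sp <- toy_spec()
  set.seed(22)
  m <- matrix(runif(100), 10, 10)
  m[1:5] <- NA
  lay <- new_layer(sp, m)
  breaks <- c(0.25, 0.5, 0.75)
  hc <- classify_habitat(lay, breaks)
  # value exactly on a break falls in the lower class
  lay2 <- new_layer(sp, matrix(0.5, 10, 10))
  hc2 <- classify_habitat(lay2, breaks)
  expect_true(all(hc2$class_layer$values == 2))
  # all below the first break -> all ISH
  hc3 <- classify_habitat(new_layer(sp, matrix(0.1, 10, 10)), breaks)
  expect_equal(hc3$class_areas$n_cells, c(100L, 0L, 0L, 0L))
  # per-class counts match hist() with the same edges
  counts <- hist(m[!is.na(m)], breaks = c(-Inf, breaks, Inf),
                 plot = FALSE, right = TRUE)$counts
  expect_equal(hc$class_areas$n_cells, as.integer(counts))
  # total classified area equals total valid area
  areas <- cell_area_km2(sp)$values
  expect_equal(sum(hc$class_areas$area_km2), sum(areas[!is.na(m)]),
               tolerance = 1e-6)
})

test_that("reclassifying representative class values is idempotent", {
  set.seed(23)
  x <- runif(500)
  br <- jenks_breaks(x, 4)
  cls <- findInterval(x, br, left.open = TRUE) + 1
  reps <- tapply(x, cls, mean) # class representatives
  again <- findInterval(reps, br, left.open = TRUE) + 1
  expect_equal(unname(again), as.integer(names(reps)))
})

test_that("change ratios and categories follow the class bookkeeping", {
  sp <- toy_spec()
  set.seed(24)
  cur_vals <- matrix(runif(100), 10, 10)
  br <- jenks_breaks(as.vector(cur_vals), 4)
  cur <- classify_habitat(new_layer(sp, cur_vals), br)
  # identical layers: all ratios 0, all cells constant
  same <- change_ratio(cur, cur)
  expect_equal(same$r, rep(0, 4))
  cc <- change_category(cur, cur)
  expect_equal(cc$counts$n_cells, c(100L, 0L, 0L))

  # manual 10x10 tally against hand-computed areas
  fut_vals <- pmin(cur_vals + 0.15, 1) # push values upward
  fut <- classify_habitat(new_layer(sp, fut_vals), br)
  cr <- change_ratio(cur, fut)
  areas <- cell_area_km2(sp)$values
  for (c in 1:4) {
    cls_cur <- cur$class_layer$values == c
    cls_fut <- fut$class_layer$values == c
    expect_equal(cr$r[c],
                 (sum(areas[cls_fut]) - sum(areas[cls_cur])) / sum(areas[cls_cur]))
  }
  # category counts partition the valid cells
  cc2 <- change_category(cur, fut)
  expect_equal(sum(cc2$counts$n_cells), 100L)
  # an HSH -> MSH cell is a decrease
  dec <- which(cur$class_layer$values == 4 & fut$class_layer$values == 3)
  if (length(dec)) expect_true(all(cc2$category[dec] == "decreased"))
})

test_that("trend extremes on the bundled change table match its printed extrema", {
  trends <- example_change_trends()
  ext <- trend_extremes(trends)
  as_hsh <- ext[ext$species == "A. splendens" & ext$class == "HSH", ]
  expect_equal(as_hsh$mgr, 3.82)
  expect_equal(as_hsh$mgr_scenario, "SSP585")
  expect_equal(as_hsh$mgr_period, "2080-2100")
  kc_hsh <- ext[ext$species == "K. ceratoides" & ext$class == "HSH", ]
  expect_equal(kc_hsh$mrr, -0.18)
  expect_equal(kc_hsh$mrr_scenario, "SSP126")
  expect_equal(kc_hsh$mrr_period, "2060-2080")
  ns_msh <- ext[ext$species == "N. sibirica" & ext$class == "MSH", ]
  expect_equal(ns_msh$mrr, -0.26)
  # a single-entry trend has mgr = mrr
  single <- tibble::tibble(species = "x", scenario = "SSP126",
                           period = "2020-2040", class = "HSH", r = 0.4)
  ext1 <- trend_extremes(single)
  expect_equal(ext1$mgr, ext1$mrr)
})

test_that("influential hosts are screened by mean I and ranked by MIC share", {
  i_values <- tibble::tibble(
    host = c("K. cuspidatum", "N. sibirica", "K. ceratoides", "A. splendens",
             "K. gracile"),
    i = c(0.977, 0.973, 0.972, 0.938, 0.684))
  mic_summary <- tibble::tibble(
    host = c("N. sibirica", "K. ceratoides", "K. cuspidatum"),
    share = c(33, 19, 17))
  sel <- select_influential_hosts(i_values, mic_summary, i_threshold = 0.9)
  expect_equal(nrow(sel), 4L)
  expect_equal(sel$host[1:3], c("N. sibirica", "K. ceratoides", "K. cuspidatum"))
  # below-threshold hosts produce an empty result with a warning
  low <- dplyr::mutate(i_values, i = i / 2)
  expect_warning(none <- select_influential_hosts(low, i_threshold = 0.9),
                 "threshold")
  expect_equal(nrow(none), 0L)
})

test_that("shrinking classes follow the majority-negative rule on the bundled table", {
  trends <- example_change_trends()
  shr <- shrinking_classes(trends)
  key <- paste(shr$species, shr$class)
  expect_true("K. ceratoides HSH" %in% key)
  expect_true("N. sibirica MSH" %in% key)
  expect_false("A. splendens HSH" %in% key)
  # all-negative is always in; all-positive never
  allneg <- tibble::tibble(species = "s", scenario = "a", period = "p",
                           class = "HSH", r = c(-0.1, -0.2))
  expect_equal(nrow(shrinking_classes(allneg)), 1L)
  expect_equal(nrow(shrinking_classes(dplyr::mutate(allneg, r = -r))), 0L)
})

test_that("reserve delineation matches direct mask arithmetic", {
  sp <- toy_spec()
  set.seed(25)
  para_vals <- matrix(runif(100), 10, 10)
  host_vals <- list(h1 = matrix(runif(100), 10, 10),
                    h2 = matrix(runif(100), 10, 10))
  br <- c(0.25, 0.5, 0.75)
  para <- classify_habitat(new_layer(sp, para_vals), br)
  hosts <- lapply(host_vals, function(v) classify_habitat(new_layer(sp, v), br))
  shrink <- tibble::tibble(species = c("h1", "h2"), class = c("HSH", "MSH"))
  res <- delineate_reserve(para, hosts, shrink)
  # cell-by-cell boolean oracle
  pmask <- para$class_layer$values %in% c(3, 4)
  hmask <- hosts$h1$class_layer$values == 4 | hosts$h2$class_layer$values == 3
  oracle <- matrix(pmask & hmask, 10, 10)
  expect_equal(res$core, oracle)
  areas <- cell_area_km2(sp)$values
  expect_equal(res$area_km2, sum(areas[oracle]))

  # union rule covers both components
  res_u <- delineate_reserve(para, hosts, shrink, rule = "union")
  expect_equal(res_u$core, matrix(pmask | hmask, 10, 10))

  # no overlap -> empty core; full host cover -> parasite habitat exactly
  lo_host <- list(h1 = classify_habitat(new_layer(sp, matrix(0.05, 10, 10)), br))
  res0 <- delineate_reserve(para, lo_host,
                            tibble::tibble(species = "h1", class = "HSH"))
  expect_equal(res0$area_km2, 0)
  all_host <- list(h1 = classify_habitat(new_layer(sp, matrix(0.99, 10, 10)), br))
  res1 <- delineate_reserve(para, all_host,
                            tibble::tibble(species = "h1", class = "HSH"))
  expect_equal(res1$core, matrix(pmask, 10, 10))

  # empty shrink set falls back to parasite habitat with a warning
  expect_warning(resf <- delineate_reserve(para, hosts,
                                           shrink[0, ]), "empty shrink")
  expect_equal(resf$core, matrix(pmask, 10, 10))

  # reserve area grows monotonically with the shrink set
  a1 <- delineate_reserve(para, hosts, shrink[1, ])$area_km2
  a2 <- delineate_reserve(para, hosts, shrink)$area_km2
  expect_gte(a2, a1)
})
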