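# Habitat classification (Jenks natural breaks), climate-scenario change
# accounting, influential-host screening, and core-reserve delineation.

HABITAT_LABELS <- c("ISH", "LSH", "MSH", "HSH")

#' Jenks (Fisher) natural breaks
#'
#' Exact dynamic program minimizing the total within-class sum of squared
#' deviations over k classes of the sorted values. Returns the k - 1
#' upper-boundary thresholds (the maximum of each class but the last).
#' For very large inputs (> `max_exact` values) the breaks are fitted on a
#' seeded uniform subsample, since the exact DP is O(k n^2).
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes (>= 2).
#' @param max_exact Subsampling threshold.
#' @param subsample Subsample size when above the threshold.
#' @param seed Seed for the subsample.
#' @return Numeric vector of k - 1 ascending break values.
#' @export
jenks_breaks <- function(values, k = 4L, max_exact = 1e5, subsample = 10000L,
                         seed = 1L) {
  values <- values[!is.na(values)]
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (length(unique(values)) < k) stop("need at least k distinct values")
  if (length(values) > max_exact) {
    values <- withr_seed(seed, sample(values, subsample))
    if (length(unique(values)) < k) stop("subsample has fewer than k distinct values")
  }
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  # SSD of x[i..j], vectorized over i
  ssd_vec <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    s2 <- cs2[j + 1] - cs2[i]
    s2 - s^2 / (j - i + 1)
  }
  # D[c, j]: minimal cost of splitting x[1..j] into c classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n) # start index of the last class
  D[1, ] <- cs2[2:(n + 1)] - cs[2:(n + 1)]^2 / (1:n) # ssd of x[1..j]
  B[1, ] <- 1L
  for (c in 2:k) {
    for (j in c:n) {
      i <- c:j
      v <- D[c - 1, i - 1] + ssd_vec(i, j)
      bi <- which.min(v)
      D[c, j] <- v[bi]; B[c, j] <- as.integer(i[bi])
    }
  }
  # backtrack class boundaries
  breaks <- numeric(k - 1)
  j <- n
  for (c in k:2) {
    i <- B[c, j]
    breaks[c - 1] <- x[i - 1] # upper bound of class c-1
    j <- i - 1L
  }
  breaks
}

#' Classify a suitability layer into habitat levels
#'
#' Four levels by default: ISH (inappropriate), LSH (low), MSH (medium),
#' HSH (highly suitable). Intervals are right-closed: a value equal to a
#' break falls in the lower class. Future layers must be classified with
#' the breaks fitted on the current scenario so classes stay comparable.
#'
#' @param suitability An `sdm_layer`.
#' @param breaks Ascending break values (typically from [jenks_breaks()]).
#' @return A `habitat_classification`: the breaks, a class-code layer
#'   (1..k), and a tibble of per-class cell counts and areas (km^2).
#' @export
classify_habitat <- function(suitability, breaks) {
  stopifnot(inherits(suitability, "sdm_layer"))
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly ascending")
  k <- length(breaks) + 1L
  v <- suitability$values
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok] <- findInterval(v[ok], breaks, left.open = TRUE) + 1
  class_layer <- new_layer(suitability$spec, cls)
  areas <- cell_area_km2(suitability$spec)$values
  labels <- if (k == 4L) HABITAT_LABELS else paste0("class", seq_len(k))
  tab <- tibble::tibble(
    class = seq_len(k),
    label = labels,
    n_cells = vapply(seq_len(k), function(c) sum(cls[ok] == c), 0L),
    area_km2 = vapply(seq_len(k), function(c) sum(areas[ok & cls == c]), 0)
  )
  structure(list(breaks = breaks, class_layer = class_layer,
                 class_areas = tab),
            class = "habitat_classification")
}

#' @export
print.habitat_classification <- function(x, ...) {
  cat("<habitat_classification> breaks:",
      paste(signif(x$breaks, 4), collapse = ", "), "\n")
  print(x$class_areas)
  invisible(x)
}

#' Per-class relative area change between two classifications
#'
#' `r = (A_future - A_current) / A_current` per habitat class; classes
#' with zero current area get `NA` with a warning.
#'
#' @param current,future `habitat_classification`s on the same grid with
#'   the same breaks.
#' @return Tibble with `class`, `label`, `area_current`, `area_future`,
#'   `r`.
#' @export
change_ratio <- function(current, future) {
  stopifnot(inherits(current, "habitat_classification"),
            inherits(future, "habitat_classification"))
  a <- current$class_areas; b <- future$class_areas
  if (any(a$area_km2 == 0)) {
    warning("class(es) with zero current area: change ratio undefined")
  }
  tibble::tibble(
    class = a$class, label = a$label,
    area_current = a$area_km2, area_future = b$area_km2,
    r = ifelse(a$area_km2 > 0, (b$area_km2 - a$area_km2) / a$area_km2, NA_real_)
  )
}

#' Per-cell habitat change category
#'
#' Compares class codes cell by cell: `constant`, `decreased` or
#' `increased` habitat level.
#'
#' @param current,future `habitat_classification`s on the same grid.
#' @return List with a character-coded `category` matrix layer and a
#'   tibble of `counts`.
#' @export
change_category <- function(current, future) {
  cv <- current$class_layer$values
  fv <- future$class_layer$values
  if (!same_spec(current$class_layer$spec, future$class_layer$spec)) {
    stop("classifications on different grids")
  }
  cat_m <- matrix(NA_character_, nrow(cv), ncol(cv))
  ok <- !is.na(cv) & !is.na(fv)
  cat_m[ok] <- ifelse(fv[ok] == cv[ok], "constant",
                      ifelse(fv[ok] < cv[ok], "decreased", "increased"))
  counts <- tibble::tibble(
    category = c("constant", "decreased", "increased"),
    n_cells = unname(vapply(c("constant", "decreased", "increased"),
                            function(x) sum(cat_m[ok] == x), 0L))
  )
  list(category = cat_m, counts = counts, spec = current$class_layer$spec)
}

#' Reference host change-ratio table bundled with the package
#'
#' Per-scenario, per-period relative habitat-area change ratios for four
#' Central-Asian host plants of *Cistanche salsa* (ISH/LSH/MSH/HSH
#' columns), shipped as a plain-text example input for the trend
#' statistics.
#'
#' @return Long tibble: `species`, `scenario`, `period`, `class`, `r`.
#' @export
example_change_trends <- function() {
  path <- system.file("extdata", "host_change_trends.csv", package = "parasdm")
  wide <- utils::read.csv(path, check.names = FALSE)
  tidyr::pivot_longer(tibble::as_tibble(wide), cols = dplyr::all_of(HABITAT_LABELS),
                      names_to = "class", values_to = "r")
}

#' Maximum growth and reduction ratios across scenarios
#'
#' For each species x habitat class, the largest (MGR) and smallest (MRR)
#' change ratio over all scenario/period keys, with the key where each
#' occurs (first occurrence on ties).
#'
#' @param trend Tibble with columns `species`, `scenario`, `period`,
#'   `class` (label or code), `r`.
#' @return Tibble with one row per species x class: `mgr`, `mgr_scenario`,
#'   `mgr_period`, `mrr`, `mrr_scenario`, `mrr_period`.
#' @export
trend_extremes <- function(trend) {
  stopifnot(all(c("species", "scenario", "period", "class", "r") %in% names(trend)))
  if (nrow(trend) == 0L) stop("empty trend table")
  trend |>
    dplyr::group_by(.data$species, .data$class) |>
    dplyr::summarise(
      mgr = max(.data$r, na.rm = TRUE),
      mgr_scenario = .data$scenario[which.max(.data$r)],
      mgr_period = .data$period[which.max(.data$r)],
      mrr = min(.data$r, na.rm = TRUE),
      mrr_scenario = .data$scenario[which.min(.data$r)],
      mrr_period = .data$period[which.min(.data$r)],
      .groups = "drop"
    )
}

#' Screen hosts by mean niche similarity and novelty attribution
#'
#' Hosts whose mean niche-similarity statistic I across scenarios reaches
#' `i_threshold` are retained, ranked by their share of univariate-novelty
#' MIC attributions (descending), then by mean I (descending).
#'
#' @param i_values Tibble with `host` and `i` (one row per host x
#'   scenario, or already aggregated).
#' @param mic_summary Optional tibble with `host` and `share` (percent of
#'   univariate MIC attributions); hosts absent from it get share 0.
#' @param i_threshold Minimum mean I.
#' @return Tibble of selected hosts: `host`, `mean_i`, `mic_share`,
#'   ranked.
#' @export
select_influential_hosts <- function(i_values, mic_summary = NULL,
                                     i_threshold = 0.9) {
  stopifnot(all(c("host", "i") %in% names(i_values)))
  means <- i_values |>
    dplyr::group_by(.data$host) |>
    dplyr::summarise(mean_i = mean(.data$i), .groups = "drop")
  sel <- means[means$mean_i >= i_threshold, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no host reaches the similarity threshold")
    return(tibble::tibble(host = character(), mean_i = numeric(),
                          mic_share = numeric()))
  }
  share <- if (is.null(mic_summary)) 0 else {
    s <- mic_summary$share[match(sel$host, mic_summary$host)]
    ifelse(is.na(s), 0, s)
  }
  sel$mic_share <- share
  sel[order(-sel$mic_share, -sel$mean_i), , drop = FALSE]
}

#' Identify shrinking habitat classes
#'
#' A (species, class) pair is shrinking when its change ratio is negative
#' in at least `frac_negative` of the scenario x period keys AND its mean
#' ratio is negative.
#'
#' @param trend Tibble as in [trend_extremes()].
#' @param frac_negative Minimum fraction of negative keys.
#' @return Tibble of shrinking pairs with `n_negative`, `n_keys`,
#'   `mean_r`.
#' @export
shrinking_classes <- function(trend, frac_negative = 0.5) {
  trend |>
    dplyr::group_by(.data$species, .data$class) |>
    dplyr::summarise(
      n_negative = sum(.data$r < 0, na.rm = TRUE),
      n_keys = sum(!is.na(.data$r)),
      mean_r = mean(.data$r, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_negative >= frac_negative * .data$n_keys,
                  .data$mean_r < 0)
}

#' Delineate the core conservation reserve
#'
#' Default (intersection) rule: a cell is core when the parasite's current
#' habitat class is MSH or HSH *and* at least one shrinking (host, class)
#' pair matches the host's current class at that cell. The union rule
#' instead includes any cell in the parasite MSH/HSH or in a shrinking
#' host class.
#'
#' @param parasite A `habitat_classification` of the parasite (current
#'   scenario).
#' @param host_classes Named list of `habitat_classification`s per host.
#' @param shrink_set Tibble with `species` and `class` columns (e.g. from
#'   [shrinking_classes()]); class may be a label ("HSH") or code.
#' @param rule `"intersection"` (default) or `"union"`.
#' @param parasite_classes Parasite classes counted as habitat (codes).
#' @return A `reserve_map`: boolean core layer, total `area_km2`, and a
#'   `rule_trace` tibble of per-component cell counts.
#' @export
delineate_reserve <- function(parasite, host_classes, shrink_set,
                              rule = c("intersection", "union"),
                              parasite_classes = c(3L, 4L)) {
  rule <- match.arg(rule)
  stopifnot(inherits(parasite, "habitat_classification"))
  sp <- parasite$class_layer$spec
  pv <- parasite$class_layer$values
  para_mask <- !is.na(pv) & pv %in% parasite_classes

  label_to_code <- function(cl) {
    if (is.numeric(cl)) return(as.integer(cl))
    match(cl, HABITAT_LABELS)
  }

  host_mask <- matrix(FALSE, sp$n_rows, sp$n_cols)
  trace <- list(tibble::tibble(component = "parasite_habitat",
                               n_cells = sum(para_mask)))
  if (nrow(shrink_set) > 0L) {
    for (i in seq_len(nrow(shrink_set))) {
      h <- shrink_set$species[i]
      code <- label_to_code(shrink_set$class[i])
      if (!h %in% names(host_classes)) {
        warning("no host classification for '", h, "'; skipped")
        next
      }
      hv <- host_classes[[h]]$class_layer$values
      if (!same_spec(host_classes[[h]]$class_layer$spec, sp)) {
        stop("host classification grid mismatch for '", h, "'")
      }
      m <- !is.na(hv) & hv == code
      host_mask <- host_mask | m
      trace[[length(trace) + 1L]] <- tibble::tibble(
        component = paste0(h, ":", shrink_set$class[i]), n_cells = sum(m))
    }
    core <- if (rule == "intersection") para_mask & host_mask
            else para_mask | host_mask
  } else {
    warning("empty shrink set; core = parasite habitat alone")
    core <- para_mask
  }
  areas <- cell_area_km2(sp)$values
  structure(
    list(core_layer = new_layer(sp, ifelse(core, 1, 0)),
         core = core, area_km2 = sum(areas[core]), rule = rule,
         rule_trace = dplyr::bind_rows(trace)),
    class = "reserve_map"
  )
}

#' @export
print.reserve_map <- function(x, ...) {
  cat(sprintf("<reserve_map> %s rule: %d core cells, %.1f km^2\n",
              x$rule, sum(x$core), x$area_km2))
  invisible(x)
}
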