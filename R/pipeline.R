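# End-to-end workflow over a (synthetic or user-supplied) world:
# prepare -> fit hosts -> fit parasite -> project futures -> diagnose ->
# classify -> trends -> reserve -> report.

#' Run the full host-conditioned SDM workflow
#'
#' Takes a world (the output of [simulate_world()], or any list with the
#' same shape built from real rasters and occurrence files), reduces the
#' current environmental stack by PCA, fits host models, fits the parasite
#' on host suitabilities, transfers the frozen models to every future
#' scenario, computes extrapolation and niche-similarity diagnostics,
#' classifies habitat with current-scenario Jenks breaks, accumulates
#' change trends, and delineates the core reserve.
#'
#' @param world List with `config` (a [world_config()] or compatible),
#'   `covariates` (`current` stack + `future` tibble with
#'   scenario/period/gcm/stack columns), and `occurrences` (named list of
#'   tibbles; the parasite's name comes from `world$config$parasite`).
#' @param config A [run_config()].
#' @return A `parasdm_run` list with elements `pca`, `hosts`, `parasite`,
#'   `projections` (tibble: scenario, period, parasite_suitability,
#'   host_suitability), `metrics` (Table-1 shaped), `exdet_summary`
#'   (Table-2 shaped), `overlap` (per host x scenario I and D), `trends`
#'   (Table-3 shaped long), `extremes`, `shrinking`, `influential_hosts`,
#'   `habitat` (classifications) and `reserve`.
#' @export
run_pipeline <- function(world, config = run_config()) {
  hosts <- setdiff(names(world$occurrences), world$config$parasite)
  parasite_name <- world$config$parasite

  # --- prepare: PCA on the current scenario, frozen thereafter
  transform <- fit_pca(world$covariates$current, config$pca$variance_target)
  pc_current <- project_pca(world$covariates$current, transform)

  # --- stage 1 and 2 fits on current data
  host_fits <- fit_hosts(world$occurrences[hosts], pc_current, config)
  parasite_fit <- fit_parasite(world$occurrences[[parasite_name]],
                               host_fits$suitability, config)

  # --- transfer to futures (GCM mean -> frozen PCs -> frozen models)
  fut <- world$covariates$future
  keys <- dplyr::distinct(fut, .data$scenario, .data$period)
  projections <- purrr::pmap(keys, function(scenario, period) {
    stacks <- fut$stack[fut$scenario == scenario & fut$period == period]
    proj <- project_scenario(host_fits, parasite_fit, stacks, transform)
    tibble::tibble(scenario = scenario, period = period,
                   projection = list(proj))
  }) |> dplyr::bind_rows()

  # --- diagnostics in host-suitability space: reference = parasite
  #     training rows, projection = each future host-suitability stack
  X_hs <- stack_as_matrix(host_fits$suitability)
  cells <- attr(X_hs, "cells")
  ref_rows <- c(match(parasite_fit$occurrences$cell, cells),
                match(parasite_fit$background, cells))
  reference <- X_hs[ref_rows[!is.na(ref_rows)], , drop = FALSE]
  diagnostics <- purrr::pmap(projections, function(scenario, period, projection) {
    ex <- exdet(reference, projection$host_suitability)
    tibble::tibble(scenario = scenario, period = period,
                   exdet = list(ex),
                   class_counts = list(table(factor(ex$novelty_class,
                     levels = c("univariate", "combinatorial", "analogue")))),
                   mic = list(mic(ex)))
  }) |> dplyr::bind_rows()
  total_counts <- Reduce(`+`, diagnostics$class_counts)
  exdet_summary <- summarize_exdet(stats::setNames(as.integer(total_counts),
                                                   names(total_counts)))
  mic_all <- unlist(diagnostics$mic)
  n_diag_cells <- sum(vapply(diagnostics$class_counts, sum, 0))
  mic_share <- tibble::tibble(host = mic_all[!is.na(mic_all)]) |>
    dplyr::count(.data$host, name = "count") |>
    dplyr::mutate(share = 100 * .data$count / n_diag_cells)

  # --- niche similarity host vs parasite, current and futures
  overlap <- list()
  for (h in names(host_fits$fits)) {
    ov <- niche_overlap(get_layer(host_fits$suitability, h),
                        parasite_fit$suitability)
    overlap[[length(overlap) + 1L]] <- tibble::tibble(
      host = h, scenario = "current", period = NA_character_,
      d = ov$d, i = ov$i)
  }
  for (r in seq_len(nrow(projections))) {
    proj <- projections$projection[[r]]
    for (h in names(host_fits$fits)) {
      ov <- niche_overlap(get_layer(proj$host_suitability, h),
                          proj$parasite_suitability)
      overlap[[length(overlap) + 1L]] <- tibble::tibble(
        host = h, scenario = projections$scenario[r],
        period = projections$period[r], d = ov$d, i = ov$i)
    }
  }
  overlap <- dplyr::bind_rows(overlap)

  # --- habitat classification: breaks on current, frozen for futures
  class_current <- list()
  suit_current <- c(stats::setNames(
    lapply(names(host_fits$fits),
           function(h) get_layer(host_fits$suitability, h)),
    names(host_fits$fits)),
    stats::setNames(list(parasite_fit$suitability), parasite_name))
  breaks <- lapply(suit_current, function(l) {
    jenks_breaks(as.vector(l$values), k = config$habitat$k,
                 subsample = config$habitat$subsample, seed = config$seed)
  })
  for (s in names(suit_current)) {
    class_current[[s]] <- classify_habitat(suit_current[[s]], breaks[[s]])
  }

  trends <- list()
  for (r in seq_len(nrow(projections))) {
    proj <- projections$projection[[r]]
    fut_suits <- c(stats::setNames(
      lapply(names(host_fits$fits),
             function(h) get_layer(proj$host_suitability, h)),
      names(host_fits$fits)),
      stats::setNames(list(proj$parasite_suitability), parasite_name))
    for (s in names(fut_suits)) {
      cls_f <- classify_habitat(fut_suits[[s]], breaks[[s]])
      cr <- change_ratio(class_current[[s]], cls_f)
      trends[[length(trends) + 1L]] <- tibble::tibble(
        species = s, scenario = projections$scenario[r],
        period = projections$period[r], class = cr$label, r = cr$r)
    }
  }
  trends <- dplyr::bind_rows(trends)

  extremes <- trend_extremes(trends)
  shrinking <- shrinking_classes(
    dplyr::filter(trends, .data$species != parasite_name),
    config$reserve$frac_negative)
  influential <- select_influential_hosts(
    dplyr::rename(overlap, host = "host"), mic_share,
    i_threshold = config$reserve$i_threshold)
  shrink_core <- dplyr::filter(shrinking, .data$species %in% influential$host)

  reserve <- delineate_reserve(class_current[[parasite_name]],
                               class_current[names(host_fits$fits)],
                               shrink_core, rule = config$reserve$rule)

  metrics <- dplyr::bind_rows(
    host_fits$metrics,
    dplyr::mutate(parasite_fit$selected, species = parasite_name)
  ) |> dplyr::relocate("species")

  structure(
    list(pca = transform, hosts = host_fits, parasite = parasite_fit,
         projections = projections, metrics = metrics,
         exdet_summary = exdet_summary, mic_share = mic_share,
         overlap = overlap, habitat = class_current, breaks = breaks,
         trends = trends, extremes = extremes, shrinking = shrinking,
         influential_hosts = influential, reserve = reserve,
         config = config),
    class = "parasdm_run"
  )
}

#' @export
print.parasdm_run <- function(x, ...) {
  cat("<parasdm_run>\n")
  cat("  PCA:", length(x$pca$layer_names), "layers ->", x$pca$n_kept,
      "components\n")
  cat("  hosts fitted:", paste(names(x$hosts$fits), collapse = ", "), "\n")
  cat(sprintf("  parasite: CBI %.3f, AUC %.3f, OR %.3f (fold means)\n",
              x$parasite$selected$cbi_mean, x$parasite$selected$auc_mean,
              x$parasite$selected$or_mean))
  cat(sprintf("  reserve: %.1f km^2 (%s rule)\n", x$reserve$area_km2,
              x$reserve$rule))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `parasdm_run`.
#' @param ... Unused.
#' @return Tibble with headline quantities of the run.
#' @method glance parasdm_run
#' @export
glance.parasdm_run <- function(x, ...) {
  tibble::tibble(
    n_components = x$pca$n_kept,
    n_hosts = length(x$hosts$fits),
    parasite_cbi = x$parasite$selected$cbi_mean,
    parasite_auc = x$parasite$selected$auc_mean,
    parasite_or = x$parasite$selected$or_mean,
    n_influential_hosts = nrow(x$influential_hosts),
    reserve_area_km2 = x$reserve$area_km2
  )
}
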