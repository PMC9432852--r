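# Two-stage host -> parasite inference.
#
# Stage 1 fits one maxent model per host plant on the PC layers; stage 2
# fits the parasite on the hosts' predicted suitability layers (biotic
# factors treated as ordinary covariates). Candidate settings are tuned by
# spatially blocked cross-validation and selected by maximum CBI; the
# selected settings are refit on all presences, and the frozen models are
# transferred to future scenarios without refitting (future occurrences do
# not exist, so per-scenario reselection is not possible).

#' Default run configuration
#'
#' All tunable parameters of the workflow with their package defaults.
#' Unknown keys in `...` are rejected.
#'
#' @param ... Named overrides of any default (nested lists are replaced
#'   whole-key by whole-key, e.g. `maxent = list(rms = 1)` keeps other
#'   maxent defaults).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 42L,
    pca = list(variance_target = 0.95),
    maxent = list(
      classes = c("L", "Q", "H", "LQ", "LH", "QH", "LQH"),
      rms = c(0.5, 1, 2, 4),
      background_n = 10000L, k_h = 20L, tol = 1e-8, max_iter = 5000L
    ),
    # fold-level CBI uses the classic wide-window convention: with a few
    # dozen evaluation presences per fold, narrow windows are mostly empty
    # and the index loses ranking power (see the methods vignette)
    evaluation = list(a1 = 2L, a2 = 2L, cbi_windows = 101L,
                      cbi_window_frac = 0.1, or_percentile = 10),
    exdet = list(radius_sd = 1, reference_space = "host"),
    habitat = list(k = 4L, subsample = 10000L),
    reserve = list(rule = "intersection", i_threshold = 0.9,
                   frac_negative = 0.5),
    min_presences = 10L
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      for (sub in names(dots[[nm]])) {
        if (!sub %in% names(cfg[[nm]])) {
          stop("unknown config key: ", nm, "$", sub)
        }
        cfg[[nm]][[sub]] <- dots[[nm]][[sub]]
      }
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [run_config()]; unknown keys are rejected with the
#' offending name.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  # YAML flow sequences of mixed int/real parse as lists; flatten scalars
  simplify <- function(v) {
    if (is.list(v)) {
      unnamed <- is.null(names(v))
      if (unnamed &&
          all(vapply(v, function(e) is.atomic(e) && length(e) == 1L, TRUE))) {
        return(unlist(v))
      }
      return(lapply(v, simplify))
    }
    v
  }
  do.call(run_config, lapply(x, simplify))
}

# candidate settings grid
candidate_grid <- function(config) {
  tidyr::expand_grid(classes = config$maxent$classes, rm = config$maxent$rms)
}

#' Tune, select and fit a maxent model for one species
#'
#' Cleans and thins the occurrences to the covariate grid, samples a
#' seeded background, assigns hierarchical-checkerboard folds, evaluates
#' every candidate (feature classes x regularization multiplier) by 4-fold
#' spatial CV, selects the maximum-CBI candidate (ties: lower omission,
#' higher AUC), and refits it on all presences.
#'
#' @param occ Occurrence tibble.
#' @param stack Covariate `sdm_stack`.
#' @param config A [run_config()].
#' @param seed Seed for this species' background sampling.
#' @return List: `model` (refit `maxent_model`), `selected` (winning
#'   candidate row), `candidates` (all candidate metrics), `fold_metrics`
#'   (per fold of the winner), `suitability` (cloglog `sdm_layer`),
#'   `occurrences` (thinned), `background` (cell indices), `seed`.
#' @export
fit_species_sdm <- function(occ, stack, config = run_config(), seed = config$seed) {
  occ <- clean_occurrences(occ)
  occ <- thin_to_cells(occ, stack$spec)
  if (nrow(occ) < config$min_presences) {
    warning("only ", nrow(occ), " thinned presences (< ",
            config$min_presences, "); species skipped")
    return(NULL)
  }
  X_all <- stack_as_matrix(stack)
  cells <- attr(X_all, "cells")
  pres_rows <- match(occ$cell, cells)
  drop_pres <- is.na(pres_rows)
  if (any(drop_pres)) {
    warning(sum(drop_pres), " presence(s) on nodata cells dropped")
    occ <- occ[!drop_pres, , drop = FALSE]
    pres_rows <- pres_rows[!drop_pres]
  }
  # presence cells join the background (standard maxent practice: keeps the
  # likelihood bounded by ensuring presence feature values lie in the
  # background hull)
  background <- sort(unique(c(
    sample_background(stack, config$maxent$background_n, seed = seed),
    occ$cell)))
  bg_rows <- match(background, cells)

  X <- rbind(X_all[pres_rows, , drop = FALSE], X_all[bg_rows, , drop = FALSE])
  presence <- c(rep(TRUE, length(pres_rows)), rep(FALSE, length(bg_rows)))
  part <- checkerboard_partition(occ, background, stack$spec,
                                 config$evaluation$a1, config$evaluation$a2)
  folds <- c(part$presence_fold, part$background_fold)
  land_X <- X_all[bg_rows, , drop = FALSE] # landscape reference for CBI

  grid <- candidate_grid(config)
  results <- purrr::pmap(grid, function(classes, rm) {
    fm <- cv_maxent(X, presence, folds, land_X, classes = classes, rm = rm,
                    k_h = config$maxent$k_h,
                    or_percentile = config$evaluation$or_percentile,
                    cbi_windows = config$evaluation$cbi_windows,
                    cbi_window_frac = config$evaluation$cbi_window_frac,
                    tol = config$maxent$tol,
                    max_iter = config$maxent$max_iter)
    dplyr::bind_cols(tibble::tibble(classes = classes, rm = rm),
                     aggregate_metrics(fm),
                     tibble::tibble(folds = list(fm)))
  })
  candidates <- dplyr::bind_rows(results)
  selected <- select_model(candidates)
  model <- fit_maxent(X, presence, classes = selected$classes,
                      rm = selected$rm, k_h = config$maxent$k_h,
                      tol = config$maxent$tol,
                      max_iter = config$maxent$max_iter)
  list(model = model, selected = dplyr::select(selected, -"folds"),
       candidates = dplyr::select(candidates, -"folds"),
       fold_metrics = selected$folds[[1]],
       suitability = predict(model, stack, type = "cloglog"),
       occurrences = occ, background = background, seed = seed)
}

#' Fit all host models on the PC stack
#'
#' Each host is modelled independently; hosts with too few thinned
#' presences are skipped with a warning.
#'
#' @param host_occs Named list of occurrence tibbles.
#' @param pc_stack PC-score `sdm_stack` from [project_pca()].
#' @param config A [run_config()].
#' @return List: `fits` (per host, as [fit_species_sdm()]),
#'   `suitability` (an `sdm_stack`, one cloglog layer per host),
#'   `metrics` (tidy tibble of selected-candidate metrics per host).
#' @export
fit_hosts <- function(host_occs, pc_stack, config = run_config()) {
  if (length(host_occs) == 0L) stop("empty host list")
  if (is.null(names(host_occs))) stop("host_occs must be named")
  fits <- list()
  for (i in seq_along(host_occs)) {
    h <- names(host_occs)[i]
    fit <- fit_species_sdm(host_occs[[i]], pc_stack, config,
                           seed = config$seed + i)
    if (!is.null(fit)) fits[[h]] <- fit
  }
  if (length(fits) == 0L) stop("no host had enough presences")
  layers <- lapply(fits, function(f) f$suitability$values)
  list(
    fits = fits,
    suitability = new_stack(pc_stack$spec, layers),
    metrics = dplyr::bind_rows(lapply(fits, function(f) f$selected),
                               .id = "species")
  )
}

#' Fit the parasite model on host suitability layers
#'
#' Identical tuning/selection machinery to the hosts, with the hosts'
#' cloglog suitability layers as the covariates.
#'
#' @param parasite_occ Occurrence tibble for the parasite.
#' @param host_suitability `sdm_stack` of host suitability layers.
#' @param config A [run_config()].
#' @return As [fit_species_sdm()].
#' @export
fit_parasite <- function(parasite_occ, host_suitability, config = run_config()) {
  if (length(host_suitability$layers) == 0L) stop("no host suitability layers")
  fit <- fit_species_sdm(parasite_occ, host_suitability, config,
                         seed = config$seed + 1000L)
  if (is.null(fit)) stop("parasite has too few presences after thinning")
  fit
}

#' Transfer frozen models to a future scenario
#'
#' GCM variants are averaged cellwise, projected into the frozen PC space,
#' host predictions made with the frozen host models, and the parasite
#' predicted from those host layers with the frozen parasite model. No
#' refitting on future data.
#'
#' @param host_fits Result of [fit_hosts()].
#' @param parasite_fit Result of [fit_parasite()].
#' @param future_env List of `sdm_stack`s (one per GCM) for one scenario x
#'   period.
#' @param transform The frozen `pca_transform`.
#' @return List: `pc_stack`, `host_suitability` (stack), and
#'   `parasite_suitability` (layer).
#' @export
project_scenario <- function(host_fits, parasite_fit, future_env, transform) {
  env <- if (length(future_env) > 1L) average_gcms(future_env) else future_env[[1]]
  pc <- project_pca(env, transform)
  layers <- lapply(host_fits$fits, function(f) {
    predict(f$model, pc, type = "cloglog")$values
  })
  host_suit <- new_stack(pc$spec, layers)
  list(pc_stack = pc, host_suitability = host_suit,
       parasite_suitability = predict(parasite_fit$model, host_suit,
                                      type = "cloglog"))
}
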