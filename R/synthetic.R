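# Synthetic-world generator: spatially autocorrelated, mutually correlated
# covariate rasters for a current scenario and multi-GCM futures, host and
# parasite ground-truth suitabilities, and presence records sampled
# proportionally to truth. Everything is a deterministic function of the
# configuration, so every pipeline stage can be tested against known truth.

SSP_SCENARIOS <- c("SSP126", "SSP245", "SSP370", "SSP585")
SSP_PERIODS <- c("2020-2040", "2040-2060", "2060-2080", "2080-2100")

#' Configure a synthetic world
#'
#' The default world mirrors the structure of a 30-variable environmental
#' stack driven by 8 independent latent fields (so correlation-matrix PCA
#' recovers 8 components), five host plants whose true suitability is
#' logistic in the latents, and a parasite whose true suitability is
#' logistic in the host suitabilities with weights `parasite_weights`.
#' Future scenarios shift the latents along a fixed trend field with a
#' per-scenario magnitude and add GCM-specific noise.
#'
#' The latent-to-covariate `mixing` matrix and the host coefficient matrix
#' are drawn once from `seed`, so an identical config always produces an
#' identical world.
#'
#' @param seed Master seed.
#' @param n_rows,n_cols Grid dimensions.
#' @param n_latent Independent latent fields.
#' @param n_covariates Covariate layers (>= `n_latent`).
#' @param smoothing_length Gaussian smoothing length (cells).
#' @param covariate_noise_sd SD of independent per-covariate noise.
#' @param n_gcm GCM variants per future scenario.
#' @param gcm_noise_sd SD of GCM-specific latent noise.
#' @param trend_magnitude Named per-scenario latent shift per period step.
#' @param n_hosts Number of host species.
#' @param parasite_weights Host weights in the parasite truth
#'   (length `n_hosts`).
#' @param n_presence Presence records sampled per species.
#' @param origin_lon,origin_lat,cell_size Grid placement (degrees).
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 42L, n_rows = 120L, n_cols = 100L,
                         n_latent = 8L, n_covariates = 30L,
                         smoothing_length = 5, covariate_noise_sd = 0.1,
                         n_gcm = 2L, gcm_noise_sd = 0.1,
                         trend_magnitude = c(SSP126 = 0.2, SSP245 = 0.4,
                                             SSP370 = 0.6, SSP585 = 0.8),
                         n_hosts = 5L,
                         parasite_weights = c(3, 3, 1, 0, 0),
                         n_presence = 200L,
                         origin_lon = 75, origin_lat = 49, cell_size = 0.05) {
  if (n_covariates < n_latent) stop("n_covariates must be >= n_latent")
  if (length(parasite_weights) != n_hosts) {
    stop("parasite_weights must have one entry per host")
  }
  spec <- grid_spec(origin_lon, origin_lat, cell_size, n_rows, n_cols)
  params <- withr_seed(seed, {
    # each covariate loads mainly on one latent driver (assigned cyclically,
    # mirroring how real environmental variables cluster into temperature /
    # precipitation / soil groups) plus random cross-talk, so every latent
    # carries a comparable share of the total variance and the latent rank
    # is visible in a scree plot
    primary <- rep_len(seq_len(n_latent), n_covariates)
    base <- matrix(0, n_covariates, n_latent)
    base[cbind(seq_len(n_covariates), primary)] <- 1
    cross <- matrix(stats::rnorm(n_covariates * n_latent), n_covariates, n_latent)
    cross <- cross / sqrt(rowSums(cross^2))
    mixing <- sqrt(1 - 0.4^2) * base + 0.4 * cross
    mixing <- mixing / sqrt(rowSums(mixing^2)) # unit rows: unit-variance signal
    # each host is driven primarily by its own latent field (hosts would
    # otherwise correlate through shared drivers and their niches could
    # not be told apart), plus a weaker secondary from the remaining pool
    if (n_hosts > n_latent) stop("n_hosts must be <= n_latent")
    host_coef <- matrix(0, n_hosts, n_latent)
    for (h in seq_len(n_hosts)) {
      host_coef[h, h] <- sample(c(-1, 1), 1) * stats::runif(1, 1.5, 2.5)
      sec <- if (n_latent > n_hosts) {
        n_hosts + 1L + (h - 1L) %% (n_latent - n_hosts)
      } else 1L + h %% n_latent
      host_coef[h, sec] <- sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1)
    }
    list(mixing = mixing, host_coef = host_coef)
  })
  hosts <- paste0("host", seq_len(n_hosts))
  rownames(params$host_coef) <- hosts
  structure(
    list(seed = as.integer(seed), spec = spec, n_latent = as.integer(n_latent),
         n_covariates = as.integer(n_covariates),
         smoothing_length = smoothing_length,
         covariate_noise_sd = covariate_noise_sd,
         n_gcm = as.integer(n_gcm), gcm_noise_sd = gcm_noise_sd,
         trend_magnitude = trend_magnitude,
         mixing = params$mixing, host_coef = params$host_coef,
         host_intercepts = stats::setNames(rep(-0.5, n_hosts), hosts),
         parasite_weights = stats::setNames(parasite_weights, hosts),
         parasite_intercept = -0.5 * sum(parasite_weights),
         hosts = hosts, parasite = "parasite",
         n_presence = as.integer(n_presence)),
    class = "world_config"
  )
}

# Gaussian-smoothed, standardized random field (matrix)
smooth_field <- function(n_rows, n_cols, sigma) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma > 0) {
    kern <- function(n) {
      K <- outer(seq_len(n), seq_len(n),
                 function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
      K / rowSums(K)
    }
    w <- kern(n_rows) %*% w %*% t(kern(n_cols))
  }
  w
}

# n_cells x n_latent matrix of smoothed fields, centred and orthogonalized
# (QR) then scaled to unit SD, so latent fields are exactly uncorrelated
# over cells and covariate correlations follow the mixing geometry.
make_latents <- function(cfg) {
  sp <- cfg$spec
  L <- vapply(seq_len(cfg$n_latent),
              function(i) as.vector(smooth_field(sp$n_rows, sp$n_cols,
                                                 cfg$smoothing_length)),
              numeric(sp$n_rows * sp$n_cols))
  L <- scale(L, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(L))
  scale(Q, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

latents_to_stack_values <- function(cfg, latents, eps) {
  X <- latents %*% t(cfg$mixing) + eps
  sp <- cfg$spec
  out <- lapply(seq_len(cfg$n_covariates), function(j) {
    matrix(X[, j], sp$n_rows, sp$n_cols)
  })
  names(out) <- paste0("env", sprintf("%02d", seq_len(cfg$n_covariates)))
  out
}

#' Generate covariate stacks for all scenarios and GCMs
#'
#' The current stack is `mixing %*% latents + noise`. A future stack for
#' scenario s, period index p and GCM g uses latents shifted by
#' `trend_magnitude[s] * p * trend_field` plus GCM-specific noise of SD
#' `gcm_noise_sd`; the per-covariate measurement noise is shared, so with
#' `gcm_noise_sd = 0` all GCM variants are identical.
#'
#' @param cfg A [world_config()].
#' @return List with `latents` (cells x n_latent matrix), `trend_field`,
#'   `current` (an `sdm_stack`), and `future`: a tibble with columns
#'   `scenario`, `period`, `gcm`, `stack` (list column), plus the shifted
#'   latents per scenario/period in `future_latents`.
#' @export
make_covariates <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  sp <- cfg$spec
  n_cells <- sp$n_rows * sp$n_cols
  withr_seed(cfg$seed + 1L, {
    latents <- make_latents(cfg)
    trend_field <- as.vector(smooth_field(sp$n_rows, sp$n_cols,
                                          cfg$smoothing_length))
    trend_field <- (trend_field - mean(trend_field)) / stats::sd(trend_field)
    eps <- matrix(stats::rnorm(n_cells * cfg$n_covariates,
                               sd = cfg$covariate_noise_sd),
                  n_cells, cfg$n_covariates)
    current <- new_stack(sp, latents_to_stack_values(cfg, latents, eps))
    fut <- list()
    fut_lat <- list()
    for (s in names(cfg$trend_magnitude)) {
      for (p in seq_along(SSP_PERIODS)) {
        shifted <- latents + cfg$trend_magnitude[[s]] * p * trend_field
        fut_lat[[paste(s, SSP_PERIODS[p])]] <- shifted
        for (g in seq_len(cfg$n_gcm)) {
          gnoise <- matrix(stats::rnorm(n_cells * cfg$n_latent,
                                        sd = cfg$gcm_noise_sd),
                           n_cells, cfg$n_latent)
          st <- new_stack(sp, latents_to_stack_values(cfg, shifted + gnoise, eps))
          fut[[length(fut) + 1L]] <- tibble::tibble(
            scenario = s, period = SSP_PERIODS[p], gcm = paste0("GCM", g),
            stack = list(st))
        }
      }
    }
    list(latents = latents, trend_field = trend_field, current = current,
         future = dplyr::bind_rows(fut), future_latents = fut_lat)
  })
}

#' Ground-truth suitabilities for hosts and parasite
#'
#' Host h truth is `plogis(alpha_h + w_h . latents)`; parasite truth is
#' `plogis(a + sum_h v_h * host_truth_h)`. All values lie in (0, 1).
#'
#' @param cfg A [world_config()].
#' @param latents Cells x n_latent matrix (e.g. from [make_covariates()]).
#' @return List with `hosts` (an `sdm_stack`, one layer per host) and
#'   `parasite` (an `sdm_layer`).
#' @export
make_truth <- function(cfg, latents) {
  sp <- cfg$spec
  eta <- sweep(latents %*% t(cfg$host_coef), 2, cfg$host_intercepts, "+")
  host_truth <- stats::plogis(eta)
  layers <- lapply(seq_len(ncol(host_truth)), function(h) {
    matrix(host_truth[, h], sp$n_rows, sp$n_cols)
  })
  names(layers) <- cfg$hosts
  para <- stats::plogis(cfg$parasite_intercept +
                          drop(host_truth %*% cfg$parasite_weights))
  list(
    hosts = new_stack(sp, layers),
    parasite = new_layer(sp, matrix(para, sp$n_rows, sp$n_cols))
  )
}

#' Sample presence records proportional to true suitability
#'
#' Draws `n` distinct cells with probability proportional to the truth
#' layer and jitters each record uniformly within its cell, so per-cell
#' thinning is exercised by downstream code.
#'
#' @param truth An `sdm_layer` with values in [0, 1].
#' @param n Number of records.
#' @param seed RNG seed.
#' @param species Species label.
#' @return Occurrence tibble (`species`, `longitude`, `latitude`).
#' @export
sample_occurrences <- function(truth, n, seed = 1L, species = "species") {
  stopifnot(inherits(truth, "sdm_layer"))
  v <- as.vector(truth$values)
  cells <- which(!is.na(v) & v > 0)
  if (length(cells) == 0L) stop("truth layer is zero everywhere")
  if (n > length(cells)) stop("n exceeds the number of positive cells")
  sp <- truth$spec
  withr_seed(seed, {
    pick <- sample(cells, n, prob = v[cells])
    row <- (pick - 1L) %% sp$n_rows + 1L
    col <- (pick - 1L) %/% sp$n_rows + 1L
    ctr <- cell_centers(sp, row, col)
    jit <- sp$cell_size * 0.499
    tibble::tibble(
      species = species,
      longitude = ctr$longitude + stats::runif(n, -jit, jit),
      latitude = ctr$latitude + stats::runif(n, -jit, jit)
    )
  })
}

#' Generate the full synthetic world
#'
#' Covariates for every scenario/GCM, ground truth, and presence records
#' for each host and the parasite, all from one config.
#'
#' @param cfg A [world_config()].
#' @return List: `config`, `covariates` (see [make_covariates()]),
#'   `truth`, and `occurrences` (named list of tibbles, hosts then
#'   parasite).
#' @export
simulate_world <- function(cfg = world_config()) {
  cov <- make_covariates(cfg)
  truth <- make_truth(cfg, cov$latents)
  occ <- list()
  for (h in seq_along(cfg$hosts)) {
    occ[[cfg$hosts[h]]] <- sample_occurrences(
      get_layer(truth$hosts, cfg$hosts[h]), cfg$n_presence,
      seed = cfg$seed + 100L + h, species = cfg$hosts[h])
  }
  occ[[cfg$parasite]] <- sample_occurrences(
    truth$parasite, cfg$n_presence, seed = cfg$seed + 200L,
    species = cfg$parasite)
  list(config = cfg, covariates = cov, truth = truth, occurrences = occ)
}
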