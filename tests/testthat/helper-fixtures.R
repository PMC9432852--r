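# Shared fixture builders: everything is generated in code at test time.

# small grid for geometry tests
toy_spec <- function(n_rows = 10L, n_cols = 10L, cell_size = 0.5,
                     origin_lon = 80, origin_lat = 45) {
  grid_spec(origin_lon, origin_lat, cell_size, n_rows, n_cols)
}

# stack of named random layers with optional NA holes
toy_stack <- function(spec = toy_spec(), n_layers = 3L, seed = 1L,
                      na_frac = 0) {
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(i) {
    m <- matrix(rnorm(spec$n_rows * spec$n_cols), spec$n_rows, spec$n_cols)
    if (na_frac > 0) m[sample(length(m), round(na_frac * length(m)))] <- NA
    m
  })
  names(layers) <- paste0("env", seq_len(n_layers))
  new_stack(spec, layers)
}

# bounded presence-background covariate problem: presences shifted up on the
# first covariate, presence rows included in the background so the maxent
# likelihood is bounded
toy_problem <- function(n_pres = 60L, n_bg = 300L, n_cov = 1L, seed = 1L,
                        shift = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_pres + n_bg) * n_cov), ncol = n_cov,
              dimnames = list(NULL, paste0("v", seq_len(n_cov))))
  X[seq_len(n_pres), 1] <- X[seq_len(n_pres), 1] + shift
  presence <- c(rep(TRUE, n_pres), rep(FALSE, n_bg))
  X <- rbind(X, X[presence, , drop = FALSE])
  presence <- c(presence, rep(FALSE, n_pres))
  list(X = X, presence = presence)
}

# cells x layers matrix over the joint valid mask (internal helper)
stack_as_matrix_for_test <- function(st) parasdm:::stack_as_matrix(st)

# small synthetic world shared across cascade/pipeline tests
tiny_world <- function(seed = 7L) {
  cfg <- world_config(seed = seed, n_rows = 50L, n_cols = 40L, n_latent = 4L,
                      n_covariates = 12L, n_hosts = 3L,
                      parasite_weights = c(3, 2, 0), n_presence = 120L,
                      trend_magnitude = c(SSP126 = 0.2, SSP585 = 0.8),
                      n_gcm = 2L)
  simulate_world(cfg)
}

tiny_config <- function(...) {
  run_config(maxent = list(classes = c("L", "LQ"), rms = c(1, 2),
                           background_n = 1000L, k_h = 5L),
             habitat = list(subsample = 2000L), ...)
}
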