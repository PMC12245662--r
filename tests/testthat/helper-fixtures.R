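# Shared fixtures: tiny datasets and mock backends built in code.

separable_dataset <- function(n_pairs = 10, n_features = 8,
                              n_informative = 4, seed = 1) {
  simulate_expression(n_pairs = n_pairs, n_features = n_features,
                      n_informative = n_informative, effect_size = 6,
                      seed = seed)
}

noise_dataset <- function(n_pairs = 10, n_features = 8, seed = 1) {
  simulate_expression(n_pairs = n_pairs, n_features = n_features,
                      n_informative = 0, effect_size = 0, seed = seed)
}

# Scores validation samples by their first signature column (an "oracle"
# score when that column separates the classes). Optionally adds seeded
# noise so replicate AUCs differ; optionally serves a canned OOB curve.
mock_backend <- function(backend_id = "mock", noise_sd = 0,
                         oob_fun = NULL, counter = NULL,
                         deterministic = FALSE) {
  forest_backend(
    backend_id = backend_id, algorithm = "mock",
    supports_oob = !is.null(oob_fun),
    fit_fun = function(x_train, y_train, x_valid, ntree, mtry, seed) {
      if (!is.null(counter)) counter$n <- counter$n + 1L
      set.seed(seed)
      score <- x_valid[, 1L]
      score <- (score - min(score)) / max(diff(range(score)), 1e-12)
      if (noise_sd > 0) score <- score + stats::rnorm(length(score),
                                                      sd = noise_sd)
      list(score = score,
           oob_error = if (is.null(oob_fun)) NA_real_ else oob_fun(ntree))
    },
    deterministic = deterministic)
}

new_counter <- function() {
  env <- new.env()
  env$n <- 0L
  env
}

# A grid built directly from a tensor, bypassing model fits.
grid_from_tensor <- function(auc, backend_id = "mock", ntree = 50L) {
  auc_grid(auc, array(0, dim = dim(auc)), backend_id, ntree)
}

random_auc_tensor <- function(S, k, q, seed) {
  set.seed(seed)
  array(stats::runif(S * k * q), dim = c(S, k, q))
}
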