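#' Simulate a paired two-class RPKM-like expression dataset
#'
#' Generates `2 * n_pairs` samples (one case plus one matched control per
#' pair) over `n_features` features. Values are drawn on the log scale as
#' Gaussians with block-diagonal correlation (consecutive blocks of
#' `block_size` features sharing correlation `within_block_corr`), a shared
#' per-pair random intercept of standard deviation `pair_sd` modelling the
#' matched design, and a case-vs-control mean shift of
#' `effect_size * noise_sd` on the first `n_informative` features. The log
#' values are exponentiated, giving positive right-skewed values in the
#' spirit of RPKM-normalised RNA-seq.
#'
#' @param n_pairs number of case/control pairs (total samples = 2 * n_pairs).
#' @param n_features total feature count.
#' @param n_informative number of class-separating features (the first
#'   `n_informative` feature columns).
#' @param effect_size class mean shift on informative features, in units of
#'   `noise_sd` on the log scale. 0 gives a pure-noise dataset.
#' @param block_size features per correlation block; 1 disables block
#'   structure.
#' @param within_block_corr common correlation inside a block, in `[0, 1)`.
#' @param noise_sd residual standard deviation on the log scale.
#' @param pair_sd standard deviation of the shared per-pair intercept.
#' @param base_log_mean grand mean on the log scale (exp(4) ~ 55 "RPKM").
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments.
#' @return a valid `ExpressionDataset` with labels `"tumor"` / `"healthy"`,
#'   positive class `"tumor"`, and pair ids `p1 ... p<n_pairs>`.
#' @examples
#' ds <- simulate_expression(n_pairs = 10, n_features = 20,
#'                           n_informative = 4, effect_size = 2, seed = 1)
#' validate_dataset(ds)
#' @export
simulate_expression <- function(n_pairs, n_features, n_informative = 0,
                                effect_size = 1, block_size = 1,
                                within_block_corr = 0, noise_sd = 1,
                                pair_sd = 0.25, base_log_mean = 4,
                                seed = 1) {
  assert_scalar_count(n_pairs, "n_pairs")
  assert_scalar_count(n_features, "n_features")
  assert_scalar_count(n_informative, "n_informative", min = 0L)
  assert_scalar_count(block_size, "block_size")
  if (n_informative > n_features) {
    stop("`n_informative` must not exceed `n_features`")
  }
  if (within_block_corr < 0 || within_block_corr >= 1) {
    stop("`within_block_corr` must be in [0, 1)")
  }
  if (effect_size < 0) stop("`effect_size` must be non-negative")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")

  n <- 2L * n_pairs
  set.seed(seed)
  # block-equicorrelated Gaussians: x = sqrt(rho) * u_block + sqrt(1-rho) * e
  blocks <- rep(seq_len(ceiling(n_features / block_size)),
                each = block_size)[seq_len(n_features)]
  u <- matrix(stats::rnorm(n * max(blocks)), n, max(blocks))
  e <- matrix(stats::rnorm(n * n_features), n, n_features)
  latent <- sqrt(within_block_corr) * u[, blocks, drop = FALSE] +
    sqrt(1 - within_block_corr) * e
  latent <- noise_sd * latent

  pair_ids <- rep(paste0("p", seq_len(n_pairs)), each = 2L)
  labels <- rep(c("tumor", "healthy"), times = n_pairs)
  intercepts <- stats::rnorm(n_pairs, sd = pair_sd)
  latent <- latent + intercepts[rep(seq_len(n_pairs), each = 2L)]

  if (n_informative > 0 && effect_size > 0) {
    shift <- matrix(0, n, n_features)
    shift[labels == "tumor", seq_len(n_informative)] <-
      effect_size * noise_sd
    latent <- latent + shift
  }
  values <- exp(base_log_mean + latent)
  expression_dataset(
    values, labels, positive_class = "tumor",
    sample_ids = paste0(pair_ids, "_", labels),
    feature_ids = paste0("g", seq_len(n_features)),
    pair_ids = pair_ids)
}

#' Benchmark-scale configuration presets
#'
#' Named presets mirroring the shapes of the three TCGA cohorts commonly
#' used for paired tumor/healthy benchmarking: infiltrating ductal breast
#' carcinoma (182 samples, 28 selected features), lung squamous cell
#' carcinoma (96 samples, 9 selected features), and papillary thyroid
#' carcinoma (98 samples, 38 selected features). The post-feature-selection
#' counts feed the signature planner directly, reproducing plan sizes 78,
#' 21 and 108.
#'
#' @return a named list of preset lists with elements `n_pairs`,
#'   `n_features`, `n_selected`, `n_informative`, `effect_size`.
#' @examples
#' p <- benchmark_profiles()$lusc_like
#' planned_signature_count(p$n_selected)  # 21
#' @export
benchmark_profiles <- function() {
  list(
    brca_like = list(n_pairs = 91L, n_features = 9500L, n_selected = 28L,
                     n_informative = 28L, effect_size = 3),
    lusc_like = list(n_pairs = 48L, n_features = 9262L, n_selected = 9L,
                     n_informative = 9L, effect_size = 3),
    thca_like = list(n_pairs = 49L, n_features = 9353L, n_selected = 38L,
                     n_informative = 38L, effect_size = 3)
  )
}

#' Materialise a preset as a (possibly down-scaled) synthetic dataset
#'
#' @param profile a preset name from [benchmark_profiles()] or a preset
#'   list.
#' @param n_features override the preset's feature count (the full
#'   ~9000-feature matrices are rarely needed for method checks).
#' @param effect_size,seed passed to [simulate_expression()].
#' @return an `ExpressionDataset` carrying the preset's `n_selected` as
#'   attribute `"n_selected"`.
#' @export
simulate_profile <- function(profile, n_features = NULL,
                             effect_size = NULL, seed = 1) {
  if (is.character(profile)) {
    profiles <- benchmark_profiles()
    if (!profile %in% names(profiles)) {
      stop(sprintf("unknown profile '%s'; available: %s", profile,
                   paste(names(profiles), collapse = ", ")))
    }
    profile <- profiles[[profile]]
  }
  nf <- n_features %||% profile$n_features
  ds <- simulate_expression(
    n_pairs = profile$n_pairs, n_features = nf,
    n_informative = min(profile$n_informative, nf),
    effect_size = effect_size %||% profile$effect_size,
    seed = seed)
  attr(ds, "n_selected") <- profile$n_selected
  ds
}
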