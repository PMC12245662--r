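#' Variance prefilter
#'
#' Keeps the `n_keep` features with the highest variance of
#' `log2(x + 1)`-transformed values, emulating the usual log-intensity
#' variation screen applied to expression matrices before model-based
#' feature selection. Ties are broken by ascending feature id.
#'
#' @param dataset an `ExpressionDataset`.
#' @param n_keep number of features to retain, in `1..n_features`.
#' @return an `ExpressionDataset` with `n_keep` features; samples
#'   unchanged. Feature order follows the original dataset.
#' @export
variance_prefilter <- function(dataset, n_keep) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  assert_scalar_count(n_keep, "n_keep")
  if (n_keep > n_features(dataset)) {
    stop(sprintf("`n_keep` = %d exceeds the %d available features",
                 n_keep, n_features(dataset)))
  }
  v <- apply(log2(dataset$values + 1), 2L, stats::var)
  ord <- order(-v, dataset$feature_ids)
  keep <- sort(ord[seq_len(n_keep)])
  subset_dataset(dataset, features = dataset$feature_ids[keep])
}

#' Rank features by combined impurity and permutation importance
#'
#' Fits the backend `n_repeats` times (different seeds), averages the
#' impurity (mean decrease in Gini) and permutation (mean decrease in
#' accuracy) importances over the repeats, converts each averaged measure
#' to rank positions (1 = most important, ties broken by ascending feature
#' id), and aggregates the two measures as the mean of their ranks.
#'
#' @param dataset an `ExpressionDataset`.
#' @param backend a `ForestBackend` or id; must support both importance
#'   modes.
#' @param n_repeats number of independent fits averaged (>= 1).
#' @param seed base seed; repeat `i` uses `seed + i - 1`.
#' @param ntree trees per fit; defaults to the backend's hyperparameter.
#' @return an object of class `ImportanceRanking`: a data.frame with
#'   columns `feature_id`, `impurity_score`, `permutation_score`,
#'   `aggregate_rank`, sorted by ascending `aggregate_rank`.
#' @export
rank_features <- function(dataset, backend, n_repeats = 5L, seed = 1L,
                          ntree = NULL) {
  if (is.character(backend)) backend <- get_backend(backend)
  assert_scalar_count(n_repeats, "n_repeats")
  if (!backend$supports_impurity_importance) {
    stop(sprintf("backend '%s' lacks impurity importance",
                 backend$backend_id))
  }
  if (!backend$supports_permutation_importance) {
    stop(sprintf("backend '%s' lacks permutation importance",
                 backend$backend_id))
  }
  ntree <- ntree %||% backend$hyperparameters$ntree %||% 500L
  pos <- dataset$positive_class
  neg <- setdiff(unique(dataset$labels), pos)
  y <- factor(dataset$labels, levels = c(neg, pos))
  ids <- dataset$feature_ids

  imp_g <- imp_p <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_len(n_repeats)) {
    imp <- backend$importance_fun(dataset$values, y, ntree,
                                  as.integer(seed + i - 1L))
    imp_g <- imp_g + imp$impurity[ids] / n_repeats
    imp_p <- imp_p + imp$permutation[ids] / n_repeats
  }
  rank_of <- function(score) {
    r <- integer(length(ids))
    r[order(-score, ids)] <- seq_along(ids)
    r
  }
  agg <- (rank_of(imp_g) + rank_of(imp_p)) / 2
  out <- data.frame(feature_id = ids, impurity_score = unname(imp_g),
                    permutation_score = unname(imp_p),
                    aggregate_rank = agg, stringsAsFactors = FALSE)
  out <- out[order(out$aggregate_rank, out$feature_id), ]
  rownames(out) <- NULL
  class(out) <- c("ImportanceRanking", "data.frame")
  out
}

#' Top features of a ranking
#' @param ranking an `ImportanceRanking`.
#' @param s how many features.
#' @return character vector of the s best feature ids.
#' @export
top_features <- function(ranking, s) utils::head(ranking$feature_id, s)

#' Kuncheva consistency index between two equal-size feature subsets
#'
#' The chance-corrected overlap
#' `(r - s^2/N) / (s - s^2/N)` where `r` is the intersection size, `s` the
#' common subset size and `N` the size of the feature universe. Ranges over
#' `[-1, 1]` and equals 1 only for identical subsets; 0 is the expectation
#' under random selection.
#'
#' @param subset_a,subset_b character vectors of feature ids, same length
#'   `s` with `0 < s < n_total`.
#' @param n_total size of the feature universe both subsets are drawn from.
#' @return a single numeric index.
#' @examples
#' kuncheva_index(c("a", "b", "c"), c("d", "e", "f"), 10)  # -0.4286
#' @export
kuncheva_index <- function(subset_a, subset_b, n_total) {
  subset_a <- unique(as.character(subset_a))
  subset_b <- unique(as.character(subset_b))
  s <- length(subset_a)
  if (length(subset_b) != s) {
    stop("subsets must have equal size")
  }
  if (s == 0L || s >= n_total) {
    stop("the index is undefined for empty or universe-sized subsets")
  }
  r <- length(intersect(subset_a, subset_b))
  expected <- s^2 / n_total
  (r - expected) / (s - expected)
}

#' Spearman correlation of two importance rankings
#'
#' @param ranking_a,ranking_b `ImportanceRanking` objects over the same
#'   feature universe.
#' @return Spearman rank correlation of the aggregate ranks, in `[-1, 1]`.
#' @export
spearman_rank_stability <- function(ranking_a, ranking_b) {
  ids <- sort(ranking_a$feature_id)
  if (!identical(ids, sort(ranking_b$feature_id))) {
    stop("rankings cover different feature universes")
  }
  a <- ranking_a$aggregate_rank[match(ids, ranking_a$feature_id)]
  b <- ranking_b$aggregate_rank[match(ids, ranking_b$feature_id)]
  stats::cor(a, b, method = "spearman")
}

#' Select the minimal stable signature size
#'
#' For each candidate size `s`, importance rankings are computed on
#' `n_resamples` balanced training partitions (rate `P`); the top-`s`
#' subsets are compared by mean pairwise Kuncheva index and the full
#' rankings by mean pairwise Spearman correlation. The selected size is the
#' smallest candidate whose two means both reach the configured floors. If
#' no size qualifies, the size with the greatest mean Kuncheva index is
#' returned with `met_floors = FALSE`.
#'
#' @param dataset an `ExpressionDataset` (typically after
#'   [variance_prefilter()]).
#' @param backend a `ForestBackend` or id supporting both importance modes.
#' @param candidate_sizes integer sizes to try, each `< n_features`.
#' @param n_resamples number of partitions the rankings are computed on.
#' @param P resampling rate for those partitions.
#' @param seed base seed.
#' @param kuncheva_floor,spearman_floor minimum acceptable mean stability.
#' @param n_repeats,ntree passed to [rank_features()].
#' @return list of class `SizeSelection`: `n_selected`, `met_floors`,
#'   `selected_features` (top features of the full-data ranking at the
#'   selected size), `curve` (data.frame size / mean_kuncheva /
#'   mean_spearman), `rankings`.
#' @export
select_stable_size <- function(dataset, backend, candidate_sizes,
                               n_resamples = 10L, P = 0.5, seed = 1L,
                               kuncheva_floor = 0.6, spearman_floor = 0.6,
                               n_repeats = 1L, ntree = NULL) {
  if (is.character(backend)) backend <- get_backend(backend)
  candidate_sizes <- sort(unique(as.integer(candidate_sizes)))
  if (length(candidate_sizes) == 0L) stop("`candidate_sizes` is empty")
  if (any(candidate_sizes < 1L) ||
      any(candidate_sizes >= n_features(dataset))) {
    stop("candidate sizes must lie in [1, n_features)")
  }
  parts <- make_partitions(dataset, P = P, k = n_resamples, seed = seed)
  rankings <- lapply(seq_len(n_resamples), function(n) {
    sub <- subset_dataset(dataset, samples = parts$train_indices[[n]])
    rank_features(sub, backend, n_repeats = n_repeats,
                  seed = as.integer(seed + 1000L * n), ntree = ntree)
  })
  pairs <- utils::combn(n_resamples, 2L)
  mean_spearman <- mean(apply(pairs, 2L, function(p) {
    spearman_rank_stability(rankings[[p[1]]], rankings[[p[2]]])
  }))
  nf <- n_features(dataset)
  curve <- data.frame(size = candidate_sizes,
                      mean_kuncheva = NA_real_,
                      mean_spearman = mean_spearman)
  for (i in seq_along(candidate_sizes)) {
    s <- candidate_sizes[i]
    tops <- lapply(rankings, top_features, s = s)
    curve$mean_kuncheva[i] <- mean(apply(pairs, 2L, function(p) {
      kuncheva_index(tops[[p[1]]], tops[[p[2]]], nf)
    }))
  }
  qualifies <- curve$mean_kuncheva >= kuncheva_floor &
    curve$mean_spearman >= spearman_floor
  if (any(qualifies)) {
    n_selected <- candidate_sizes[which(qualifies)[1L]]
    met <- TRUE
  } else {
    n_selected <- candidate_sizes[which.max(curve$mean_kuncheva)]
    met <- FALSE
  }
  full_ranking <- rank_features(dataset, backend, n_repeats = n_repeats,
                                seed = seed, ntree = ntree)
  structure(list(n_selected = n_selected, met_floors = met,
                 selected_features = top_features(full_ranking, n_selected),
                 curve = curve, rankings = rankings),
            class = "SizeSelection")
}

#' @export
print.SizeSelection <- function(x, ...) {
  cat(sprintf("SizeSelection: Nv' = %d%s\n", x$n_selected,
              if (x$met_floors) "" else " (no size met the stability floors)"))
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Write the size-stability curve / selected features
#' @param selection a `SizeSelection`.
#' @param curve_file,features_file output paths (either may be `NULL`).
#' @export
write_size_selection <- function(selection, curve_file = NULL,
                                 features_file = NULL) {
  if (!is.null(curve_file)) {
    utils::write.table(selection$curve, curve_file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(features_file)) {
    writeLines(selection$selected_features, features_file)
  }
  invisible(selection)
}
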