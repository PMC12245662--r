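#' Coefficient of variation of a replicate AUC set
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Returns exactly 0 when all values are bit-identical, so a zero CV means
#' literal AUC identity across replicates rather than agreement up to
#' rounding.
#'
#' @param values numeric vector of at least 2 values with positive mean.
#' @return a single non-negative numeric.
#' @examples
#' coefficient_of_variation(c(0.8, 0.9, 1.0))  # 0.1111...
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop("the coefficient of variation needs at least 2 values")
  }
  if (anyNA(values)) stop("`values` contains missing data")
  if (all(values == values[1L])) return(0)
  m <- mean(values)
  if (m <= 0) {
    stop("the coefficient of variation is undefined for a non-positive mean")
  }
  stats::sd(values) / m
}

#' Per-combination CV and binary stability matrix
#'
#' For each of the `S * k` signature/partition combinations, computes the
#' coefficient of variation of its `q` replicate AUCs and marks the
#' combination stable when `cv <= t`. At the hyper-stability threshold
#' `t = 0` a combination is stable iff all `q` AUCs are bit-identical.
#' Combinations whose replicate AUCs average to 0 cannot be scored; they
#' are flagged (CV set to `NA`) and counted unstable.
#'
#' @param grid an `AUCGrid` with `q >= 2`.
#' @param t stability threshold in `[0, 1]`; 0 scores hyper-stability,
#'   positive values relative stability.
#' @return list with `cv` (S x k matrix), `stable` (S x k logical),
#'   `threshold`, `flagged` (logical matrix of unscorable cells).
#' @export
stability_matrix <- function(grid, t = 0) {
  stopifnot(inherits(grid, "AUCGrid"))
  if (grid$q < 2L) stop("stability needs q >= 2 replicates per cell")
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1) {
    stop("`t` must be a single number in [0, 1]")
  }
  S <- grid$S; k <- grid$k
  cv <- matrix(NA_real_, S, k,
               dimnames = list(grid$signature_ids, grid$partition_ids))
  flagged <- matrix(FALSE, S, k)
  for (s in seq_len(S)) {
    for (n in seq_len(k)) {
      vals <- grid$auc[s, n, ]
      if (all(vals == vals[1L])) {
        cv[s, n] <- 0
      } else if (mean(vals) <= 0) {
        flagged[s, n] <- TRUE
      } else {
        cv[s, n] <- stats::sd(vals) / mean(vals)
      }
    }
  }
  stable <- !is.na(cv) & cv <= t
  list(cv = cv, stable = stable, threshold = t, flagged = flagged)
}

#' Per-resampling stable fraction
#'
#' `hr[n]` is the fraction of signatures whose replicate AUCs are stable on
#' partition `n` (S0 / S).
#'
#' @param stable S x k logical matrix.
#' @return numeric vector of length k, values in `[0, 1]`.
#' @export
hr_vector <- function(stable) {
  stopifnot(is.matrix(stable), nrow(stable) > 0, ncol(stable) > 0)
  colSums(stable) / nrow(stable)
}

#' Per-signature stable fraction
#'
#' `hs[s]` is the fraction of partitions on which signature `s` is stable
#' (k0 / k).
#'
#' @param stable S x k logical matrix.
#' @return numeric vector of length S, values in `[0, 1]`.
#' @export
hs_vector <- function(stable) {
  stopifnot(is.matrix(stable), nrow(stable) > 0, ncol(stable) > 0)
  rowSums(stable) / ncol(stable)
}

#' Aggregate HR/HS vectors into the two stability scores
#'
#' The resampling-sensitive score is the mean of the strictly positive HR
#' entries; the signature-sensitive score the mean of the strictly positive
#' HS entries. An all-false stability matrix (no stable combination at all)
#' yields 0 for both — total instability is the worst score, not an
#' undefined one. At threshold 0 these are the hyper-stability scores
#' HRS/HSS; at positive thresholds the relative-stability scores RRS/RSS.
#'
#' @param hr,hs vectors from [hr_vector()] / [hs_vector()] on the same
#'   matrix.
#' @return list with `resampling_score` and `signature_score`.
#' @export
aggregate_scores <- function(hr, hs) {
  pos_mean <- function(v) if (any(v > 0)) mean(v[v > 0]) else 0
  list(resampling_score = pos_mean(hr), signature_score = pos_mean(hs))
}

#' Classify the dot-matrix dependency pattern
#'
#' The S x k stability matrix ("dot matrix") is read for structure: an
#' implementation losing stability on particular signatures shows blank
#' rows (signature dependent, Type A); one losing stability on particular
#' resamplings shows blank columns (resampling dependent, Type B); mixed
#' patterns are Type C. Matrices with almost no stable cells carry no
#' pattern and are left unclassified.
#'
#' @param stable S x k logical matrix.
#' @param row_gap_frac fraction of fully blank rows that triggers Type A.
#' @param col_gap_frac fraction of fully blank columns that triggers
#'   Type B.
#' @param min_density minimum fraction of stable cells below which the
#'   matrix is unclassified.
#' @return one of `"signature_dependent"`, `"resampling_dependent"`,
#'   `"mixed"`, `"unclassified"`.
#' @export
classify_dependency <- function(stable, row_gap_frac = 0.2,
                                col_gap_frac = 0.2, min_density = 0.05) {
  stopifnot(is.matrix(stable))
  for (p in c(row_gap_frac, col_gap_frac, min_density)) {
    if (!is.numeric(p) || p <= 0 || p >= 1) {
      stop("classification thresholds must lie in (0, 1)")
    }
  }
  density <- mean(stable)
  if (density < min_density) return("unclassified")
  blank_rows <- mean(rowSums(stable) == 0L)
  blank_cols <- mean(colSums(stable) == 0L)
  if (blank_rows >= row_gap_frac && blank_cols < col_gap_frac) {
    "signature_dependent"
  } else if (blank_cols >= col_gap_frac && blank_rows < row_gap_frac) {
    "resampling_dependent"
  } else {
    "mixed"
  }
}

#' Full stability report for one backend's grid
#'
#' Bundles the CV matrix, the binary stability matrix at threshold `t`,
#' the HR/HS vectors, the aggregated stability scores, the grid's mean AUC
#' and mean runtime, and the dependency classification.
#'
#' @param grid an `AUCGrid`.
#' @param t stability threshold (0 = hyper-stability).
#' @param row_gap_frac,col_gap_frac,min_density passed to
#'   [classify_dependency()].
#' @return an object of class `StabilityReport`.
#' @export
stability_report <- function(grid, t = 0, row_gap_frac = 0.2,
                             col_gap_frac = 0.2, min_density = 0.05) {
  sm <- stability_matrix(grid, t)
  hr <- hr_vector(sm$stable)
  hs <- hs_vector(sm$stable)
  scores <- aggregate_scores(hr, hs)
  perf <- summarize_grid(grid)
  structure(
    list(backend_id = grid$backend_id, threshold = t,
         cv = sm$cv, stable = sm$stable, flagged = sm$flagged,
         hr = hr, hs = hs,
         resampling_score = scores$resampling_score,
         signature_score = scores$signature_score,
         mean_auc = perf$mean_auc,
         mean_runtime_seconds = perf$mean_runtime_seconds,
         dependency_class = classify_dependency(
           sm$stable, row_gap_frac, col_gap_frac, min_density),
         S = grid$S, k = grid$k, q = grid$q, ntree = grid$ntree),
    class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  score_names <- if (x$threshold == 0) c("HRS", "HSS") else c("RRS", "RSS")
  cat(sprintf("StabilityReport for '%s' at t = %g\n", x$backend_id,
              x$threshold))
  cat(sprintf("  %s = %.3f, %s = %.3f (%s)\n", score_names[1],
              x$resampling_score, score_names[2], x$signature_score,
              x$dependency_class))
  cat(sprintf("  mean AUC = %.4f over %d models; mean runtime = %.4g s\n",
              x$mean_auc, x$S * x$k * x$q, x$mean_runtime_seconds))
  cat(sprintf("  stable combinations: %d of %d\n", sum(x$stable),
              length(x$stable)))
  invisible(x)
}

#' Serialise a stability report
#'
#' The JSON carries scores, vectors and matrices; the dot-matrix TSV holds
#' the binary stability matrix (rows = signatures, columns = partitions,
#' 1 = stable), and the CV matrix can be written alongside.
#'
#' @param report a `StabilityReport`.
#' @param file output path.
#' @export
write_stability_report <- function(report, file) {
  obj <- list(
    backend_id = report$backend_id, threshold = report$threshold,
    resampling_score = report$resampling_score,
    signature_score = report$signature_score,
    mean_auc = report$mean_auc,
    mean_runtime_seconds = report$mean_runtime_seconds,
    dependency_class = report$dependency_class,
    S = report$S, k = report$k, q = report$q, ntree = report$ntree,
    hr = report$hr, hs = report$hs,
    cv = apply(report$cv, 1L, as.numeric, simplify = FALSE),
    stable = apply(report$stable, 1L, as.integer, simplify = FALSE))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(report)
}

#' @rdname write_stability_report
#' @param what `"stable"` for the dot matrix or `"cv"` for the CV matrix.
#' @export
write_dot_matrix <- function(report, file, what = c("stable", "cv")) {
  what <- match.arg(what)
  m <- if (what == "stable") report$stable * 1L else report$cv
  df <- data.frame(signature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(report)
}
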