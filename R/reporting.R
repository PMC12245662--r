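#' Run the full stability benchmark over one or more backends
#'
#' Ties the pipeline together: (optional) feature selection, signature
#' planning, balanced resampling, per-backend grid execution, and stability
#' scoring. Backends are compared on a common signature plan and common
#' partitions so differences in the scores reflect the implementations,
#' not the experimental design.
#'
#' All configuration problems are collected and reported before any model
#' is fitted.
#'
#' @param dataset an `ExpressionDataset`.
#' @param backends character vector of registered backend ids (>= 1).
#' @param selected_features optional character vector of pre-selected
#'   feature ids (the Nv' set). When `NULL`, features are ranked with the
#'   first backend and the top `n_selected` are taken.
#' @param n_selected number of features to select when
#'   `selected_features` is `NULL`; defaults to the dataset's
#'   `"n_selected"` attribute when present.
#' @param k,P number and rate of balanced partitions.
#' @param q replicate models per signature/partition cell (>= 2).
#' @param t stability threshold (0 = hyper-stability).
#' @param ntree trees per model.
#' @param seed base seed controlling feature ranking, planning,
#'   partitioning and every replicate stream.
#' @param pair_aware passed to [make_partitions()].
#' @param out_dir optional directory; when given, per-backend grid TSVs,
#'   report JSONs, dot-matrix TSVs and the combined ranking TSV are
#'   written there.
#' @return an object of class `BenchmarkResult`: list with `ranking`
#'   (data.frame, one row per backend, sorted best first), `reports`,
#'   `grids`, `plan`, `partitions`, `selected_features`, and the
#'   configuration used.
#' @export
run_benchmark <- function(dataset, backends, selected_features = NULL,
                          n_selected = NULL, k = 50L, q = 25L, P = 0.5,
                          t = 0, ntree = 500L, seed = 1L,
                          pair_aware = FALSE, out_dir = NULL) {
  problems <- character(0)
  if (!inherits(dataset, "ExpressionDataset")) {
    problems <- c(problems, "`dataset` is not an ExpressionDataset")
  } else {
    problems <- c(problems, validate_dataset(dataset))
  }
  if (length(backends) < 1L) problems <- c(problems, "no backend configured")
  unknown <- setdiff(backends, list_backends())
  if (length(unknown) > 0) {
    problems <- c(problems, sprintf("unknown backends: %s",
                                    paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(q) || length(q) != 1L || q < 2L) {
    problems <- c(problems,
                  "`q` must be >= 2 (the coefficient of variation needs at least 2 values)")
  }
  if (!is.numeric(t) || t < 0 || t > 1) {
    problems <- c(problems, "`t` must be in [0, 1]")
  }
  if (!is.numeric(P) || P <= 0 || P >= 1) {
    problems <- c(problems, "`P` must be in (0, 1)")
  }
  if (is.null(selected_features)) {
    n_selected <- n_selected %||% attr(dataset, "n_selected")
    if (is.null(n_selected)) {
      problems <- c(problems,
                    "either `selected_features` or `n_selected` is required")
    }
  }
  if (length(problems) > 0) {
    stop(paste(c("invalid benchmark configuration:", problems),
               collapse = "\n  "), call. = FALSE)
  }

  if (is.null(selected_features)) {
    ranking <- rank_features(dataset, backends[[1L]], n_repeats = 1L,
                             seed = seed, ntree = ntree)
    selected_features <- top_features(ranking, n_selected)
  }
  plan <- plan_signatures(selected_features, seed = seed)
  partitions <- make_partitions(dataset, P = P, k = k, seed = seed,
                                pair_aware = pair_aware)

  grids <- list()
  reports <- list()
  for (id in backends) {
    grid <- run_grid(id, dataset, plan, partitions, q = q, ntree = ntree,
                     seed = seed)
    grids[[id]] <- grid
    reports[[id]] <- stability_report(grid, t = t)
  }
  ranking_df <- ranking_table(reports)

  result <- structure(
    list(ranking = ranking_df, reports = reports, grids = grids,
         plan = plan, partitions = partitions,
         selected_features = selected_features,
         config = list(backends = backends, k = k, q = q, P = P, t = t,
                       ntree = ntree, seed = seed,
                       pair_aware = pair_aware)),
    class = "BenchmarkResult")
  if (!is.null(out_dir)) write_benchmark_result(result, out_dir)
  result
}

#' Combined cross-backend ranking table
#'
#' One row per backend: stability scores, mean AUC, mean runtime and
#' dependency class, sorted by combined stability score
#' (signature + resampling) descending with mean runtime ascending as the
#' tie-break — runtime discriminates implementations of equal stability
#' but never enters the scores themselves.
#'
#' @param reports list of `StabilityReport`s.
#' @return a data.frame.
#' @export
ranking_table <- function(reports) {
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(backend_id = r$backend_id,
               resampling_score = r$resampling_score,
               signature_score = r$signature_score,
               combined_score = r$resampling_score + r$signature_score,
               mean_auc = r$mean_auc,
               mean_runtime_seconds = r$mean_runtime_seconds,
               dependency_class = r$dependency_class,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$combined_score, df$mean_runtime_seconds), ]
  rownames(df) <- NULL
  df
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("BenchmarkResult: %d backend(s), S=%d signatures, k=%d partitions, q=%d replicates, t=%g\n",
              length(x$reports), length(x$plan$signatures),
              x$partitions$k, cfg$q, cfg$t))
  print(x$ranking, digits = 4)
  invisible(x)
}

#' Write all benchmark artifacts to a directory
#'
#' @param result a `BenchmarkResult`.
#' @param out_dir directory (created if needed).
#' @export
write_benchmark_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  for (id in names(result$reports)) {
    write_auc_grid(result$grids[[id]],
                   file.path(out_dir, paste0("grid_", id, ".tsv")))
    write_stability_report(result$reports[[id]],
                           file.path(out_dir, paste0("report_", id, ".json")))
    write_dot_matrix(result$reports[[id]],
                     file.path(out_dir, paste0("dotmatrix_", id, ".tsv")))
  }
  write_signature_plan(result$plan, file.path(out_dir, "signature_plan.json"))
  ranking_file <- file.path(out_dir, "ranking.tsv")
  con <- file(ranking_file, "w")
  on.exit(close(con))
  writeLines(sprintf("#seed=%d k=%d q=%d P=%g t=%g ntree=%d",
                     cfg$seed, cfg$k, cfg$q, cfg$P, cfg$t, cfg$ntree), con)
  utils::write.table(result$ranking, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(result)
}

#' Re-score a persisted AUC grid at a new threshold
#'
#' Reads a flat grid TSV written by [write_auc_grid()] and recomputes the
#' stability report at threshold `t` without re-fitting any model. This is
#' how a threshold sweep (e.g. t in {0, 0.002, 0.004, 0.008}) is run
#' cheaply over an existing benchmark.
#'
#' @param grid_tsv path to the grid file.
#' @param t stability threshold.
#' @param ... passed to [stability_report()].
#' @return a `StabilityReport`.
#' @export
score_grid_file <- function(grid_tsv, t = 0, ...) {
  stability_report(read_auc_grid(grid_tsv), t = t, ...)
}

#' Read a benchmark configuration file
#'
#' YAML (or JSON) with keys: `dataset` (either `profile`/`n_features` for a
#' synthetic preset or `matrix_file`/`labels_file` for delimited input),
#' `backends`, and optional `k`, `q`, `P`, `t`, `ntree`, `seed`,
#' `selected_features`, `n_selected`, `pair_aware`, `out_dir`.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_benchmark_config <- function(path) {
  if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  }
}

#' Run a benchmark from a configuration list or file
#'
#' @param config a list from [read_benchmark_config()] or a path.
#' @return a `BenchmarkResult`.
#' @export
run_benchmark_config <- function(config) {
  if (is.character(config)) config <- read_benchmark_config(config)
  ds_cfg <- config$dataset
  if (is.null(ds_cfg)) stop("config lacks a `dataset` entry")
  dataset <- if (!is.null(ds_cfg$profile)) {
    simulate_profile(ds_cfg$profile,
                     n_features = ds_cfg$n_features,
                     effect_size = ds_cfg$effect_size,
                     seed = ds_cfg$seed %||% config$seed %||% 1L)
  } else if (!is.null(ds_cfg$matrix_file)) {
    read_expression_dataset(ds_cfg$matrix_file, ds_cfg$labels_file)
  } else {
    stop("config dataset must give either `profile` or `matrix_file`")
  }
  run_benchmark(dataset,
                backends = unlist(config$backends),
                selected_features = config$selected_features,
                n_selected = config$n_selected,
                k = config$k %||% 50L, q = config$q %||% 25L,
                P = config$P %||% 0.5, t = config$t %||% 0,
                ntree = config$ntree %||% 500L,
                seed = config$seed %||% 1L,
                pair_aware = isTRUE(config$pair_aware),
                out_dir = config$out_dir)
}
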