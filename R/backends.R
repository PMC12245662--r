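#' Forest backend contract
#'
#' A backend bundles an ensemble-classifier implementation behind a uniform
#' interface so that feature ranking, tree-count tuning and the benchmark
#' grid can treat implementations interchangeably. A backend declares its
#' capabilities (out-of-bag error, impurity importance, permutation
#' importance) and supplies closures:
#'
#' * `fit_fun(x_train, y_train, x_valid, ntree, mtry, seed)` returning a
#'   list with `score` (probability of the positive class, one value per
#'   validation row; `y_train` is a factor whose second level is positive)
#'   and `oob_error` (`NA` when unsupported).
#' * `importance_fun(x, y, ntree, seed)` returning a list with named
#'   numeric vectors `impurity` and `permutation` (may be `NULL` when the
#'   backend supports neither importance mode).
#'
#' @param backend_id unique identifier string.
#' @param algorithm free-text taxonomy label, e.g. `"orthogonal"` or
#'   `"oblique"` split strategy.
#' @param fit_fun,importance_fun closures as described above.
#' @param supports_oob,supports_impurity_importance,
#'   supports_permutation_importance capability flags.
#' @param hyperparameters named list of defaults; `ntree` and `mtry`
#'   analogues at minimum (`mtry = NULL` lets the implementation choose).
#' @param deterministic when `TRUE`, replicate models of the same
#'   signature/partition cell share one random stream, so they are exact
#'   re-fits; used to model implementations with no internal randomness.
#' @return an object of class `ForestBackend`.
#' @export
forest_backend <- function(backend_id, algorithm, fit_fun,
                           importance_fun = NULL,
                           supports_oob = FALSE,
                           supports_impurity_importance = FALSE,
                           supports_permutation_importance = FALSE,
                           hyperparameters = list(ntree = 500L, mtry = NULL),
                           deterministic = FALSE) {
  stopifnot(is.character(backend_id), length(backend_id) == 1L,
            is.function(fit_fun))
  structure(
    list(backend_id = backend_id, algorithm = algorithm,
         fit_fun = fit_fun, importance_fun = importance_fun,
         supports_oob = isTRUE(supports_oob),
         supports_impurity_importance = isTRUE(supports_impurity_importance),
         supports_permutation_importance =
           isTRUE(supports_permutation_importance),
         hyperparameters = hyperparameters,
         deterministic = isTRUE(deterministic)),
    class = "ForestBackend")
}

#' @export
print.ForestBackend <- function(x, ...) {
  cat(sprintf("ForestBackend '%s' (%s splits)%s\n", x$backend_id,
              x$algorithm, if (x$deterministic) ", deterministic" else ""))
  cat(sprintf("  oob: %s, impurity importance: %s, permutation importance: %s\n",
              x$supports_oob, x$supports_impurity_importance,
              x$supports_permutation_importance))
  invisible(x)
}

the_registry <- new.env(parent = emptyenv())

#' Backend registry
#'
#' Backends are addressed by id string on the command line and in
#' configuration files. Two reference backends ship with the package:
#' `"randomForest"` (Breiman-style orthogonal splits, bagging, via the
#' randomForest package) and `"extraTrees"` (extremely randomized split
#' points via ranger's extratrees rule). Each also has a `<id>_fixed`
#' variant whose replicate models share a random stream, emulating a fully
#' deterministic implementation.
#'
#' @param backend a `ForestBackend` to register.
#' @param backend_id an id string to resolve.
#' @return `get_backend()` returns the `ForestBackend`; `list_backends()`
#'   the registered id strings.
#' @export
register_backend <- function(backend) {
  stopifnot(inherits(backend, "ForestBackend"))
  if (backend$backend_id %in% ls(the_registry)) {
    stop(sprintf("backend '%s' is already registered", backend$backend_id))
  }
  assign(backend$backend_id, backend, envir = the_registry)
  invisible(backend)
}

#' @rdname register_backend
#' @export
get_backend <- function(backend_id) {
  if (!backend_id %in% ls(the_registry)) {
    stop(sprintf("unknown backend '%s'; registered: %s", backend_id,
                 paste(list_backends(), collapse = ", ")))
  }
  get(backend_id, envir = the_registry)
}

#' @rdname register_backend
#' @export
list_backends <- function() ls(the_registry)

#' Deterministic variant of a backend
#'
#' Returns a copy whose replicate models reuse a single random stream per
#' signature/partition cell, so all q replicates are identical fits. Useful
#' as a positive control: such a backend is hyper-stable by construction.
#'
#' @param backend a `ForestBackend`.
#' @param backend_id id for the variant; defaults to `<id>_fixed`.
#' @return a `ForestBackend`.
#' @export
deterministic_backend <- function(backend,
                                  backend_id = paste0(backend$backend_id,
                                                      "_fixed")) {
  backend$backend_id <- backend_id
  backend$deterministic <- TRUE
  backend
}

backend_random_forest <- function() {
  forest_backend(
    backend_id = "randomForest", algorithm = "orthogonal",
    supports_oob = TRUE,
    supports_impurity_importance = TRUE,
    supports_permutation_importance = TRUE,
    fit_fun = function(x_train, y_train, x_valid, ntree, mtry, seed) {
      set.seed(seed)
      if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x_train))))
      fit <- randomForest::randomForest(x = x_train, y = y_train,
                                        ntree = ntree, mtry = mtry)
      pos <- levels(y_train)[2L]
      score <- stats::predict(fit, newdata = x_valid,
                              type = "prob")[, pos]
      list(score = as.numeric(score),
           oob_error = as.numeric(fit$err.rate[ntree, "OOB"]))
    },
    importance_fun = function(x, y, ntree, seed) {
      set.seed(seed)
      fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                        importance = TRUE)
      imp <- randomForest::importance(fit)
      list(impurity = imp[, "MeanDecreaseGini"],
           permutation = imp[, "MeanDecreaseAccuracy"])
    })
}

backend_extra_trees <- function() {
  fit_ranger <- function(x, y, ntree, mtry, seed, importance = "none") {
    ranger::ranger(x = x, y = y, num.trees = ntree,
                   mtry = if (is.null(mtry)) NULL else mtry,
                   splitrule = "extratrees", probability = TRUE,
                   min.node.size = 1L, importance = importance,
                   seed = seed, num.threads = 1L)
  }
  forest_backend(
    backend_id = "extraTrees", algorithm = "orthogonal",
    supports_oob = TRUE,
    supports_impurity_importance = TRUE,
    supports_permutation_importance = TRUE,
    fit_fun = function(x_train, y_train, x_valid, ntree, mtry, seed) {
      fit <- fit_ranger(x_train, y_train, ntree, mtry, seed)
      pos <- levels(y_train)[2L]
      score <- stats::predict(fit, data = x_valid,
                              num.threads = 1L)$predictions[, pos]
      list(score = as.numeric(score),
           oob_error = as.numeric(fit$prediction.error))
    },
    importance_fun = function(x, y, ntree, seed) {
      imp_g <- fit_ranger(x, y, ntree, NULL, seed,
                          importance = "impurity")$variable.importance
      imp_p <- fit_ranger(x, y, ntree, NULL, seed + 1L,
                          importance = "permutation")$variable.importance
      list(impurity = imp_g, permutation = imp_p)
    })
}

register_reference_backends <- function() {
  for (mk in list(backend_random_forest, backend_extra_trees)) {
    b <- mk()
    if (!b$backend_id %in% ls(the_registry)) {
      register_backend(b)
      register_backend(deterministic_backend(b))
    }
  }
}

.onLoad <- function(libname, pkgname) {
  register_reference_backends()
}

#' Fit one model and score it on the validation side
#'
#' Trains the backend on the training samples restricted to the signature's
#' feature columns, scores the held-out validation samples, and returns the
#' ROC AUC with respect to the dataset's declared positive class, the wall
#' time of the fit+predict, and the out-of-bag error when the backend
#' supports it.
#'
#' @param backend a `ForestBackend` or id string.
#' @param dataset an `ExpressionDataset`.
#' @param signature character vector of feature ids.
#' @param train integer indices of training samples; the complement is the
#'   validation set.
#' @param seed integer random seed passed to the backend.
#' @param ntree,mtry hyperparameters; default to the backend's.
#' @return list with `auc`, `runtime_seconds`, `oob_error` (`NA` when
#'   unsupported).
#' @export
fit_predict_auc <- function(backend, dataset, signature, train, seed,
                            ntree = NULL, mtry = NULL) {
  if (is.character(backend)) backend <- get_backend(backend)
  missing <- setdiff(signature, dataset$feature_ids)
  if (length(missing) > 0) {
    stop(sprintf("signature features not in dataset: %s",
                 paste(missing, collapse = ", ")))
  }
  train <- as.integer(train)
  n <- n_samples(dataset)
  if (any(train < 1L | train > n)) stop("training indices out of range")
  valid <- setdiff(seq_len(n), train)
  if (length(valid) == 0L) stop("validation side is empty")
  ntree <- ntree %||% backend$hyperparameters$ntree %||% 500L
  mtry <- mtry %||% backend$hyperparameters$mtry

  pos <- dataset$positive_class
  neg <- setdiff(unique(dataset$labels), pos)
  y <- factor(dataset$labels, levels = c(neg, pos))
  x <- dataset$values[, signature, drop = FALSE]

  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(
    backend$fit_fun(x[train, , drop = FALSE], y[train],
                    x[valid, , drop = FALSE], ntree, mtry, seed),
    error = function(e) {
      stop(sprintf("backend '%s' failed: %s", backend$backend_id,
                   conditionMessage(e)), call. = FALSE)
    })
  runtime <- proc.time()[["elapsed"]] - t0

  roc <- pROC::roc(response = y[valid], predictor = res$score,
                   levels = c(neg, pos), direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)),
       runtime_seconds = runtime,
       oob_error = if (backend$supports_oob)
         as.numeric(res$oob_error %||% NA_real_) else NA_real_)
}

#' Default tree-count grid
#'
#' A coarsened version of the dense 10..1200-by-10 grid: steps of 10 up to
#' 100 trees where out-of-bag error moves fastest, then steps of 50. The
#' dense grid is available via `ntree_grid(step = 10)`.
#'
#' @param step grid step for `ntree_grid()`.
#' @return ascending integer vector.
#' @export
default_ntree_grid <- function() {
  as.integer(c(seq(10L, 100L, by = 10L), seq(150L, 1200L, by = 50L)))
}

#' @rdname default_ntree_grid
#' @export
ntree_grid <- function(step = 10L) as.integer(seq(10L, 1200L, by = step))

#' Tune the tree count from out-of-bag error
#'
#' For each grid value, fits `q` models on each of `k` balanced partitions
#' at resampling rate `P` (so `k * q` out-of-bag errors per grid point) and
#' averages them. The selected tree count is the smallest grid value whose
#' mean error is within `plateau_tolerance` (absolute) of the grid minimum
#' and remains within tolerance at every larger grid value — the smallest
#' stabilised value of the error curve.
#'
#' @param backend a `ForestBackend` or id string; must support OOB.
#' @param dataset an `ExpressionDataset`.
#' @param grid ascending integer tree counts (see [default_ntree_grid()]).
#' @param k,P number and rate of balanced partitions.
#' @param q models per partition per grid point.
#' @param seed base seed.
#' @param plateau_tolerance absolute error band defining the plateau.
#' @param mtry optional backend hyperparameter override.
#' @return an object of class `TuningCurve` with fields `grid`,
#'   `mean_oob_error`, `selected_ntree`, `backend_id`, `n_models_per_point`.
#' @export
tune_ntree <- function(backend, dataset, grid = default_ntree_grid(),
                       k = 50L, q = 25L, P = 0.9, seed = 1L,
                       plateau_tolerance = 0.005, mtry = NULL) {
  if (is.character(backend)) backend <- get_backend(backend)
  if (!backend$supports_oob) {
    stop(sprintf("backend '%s' does not support out-of-bag error",
                 backend$backend_id))
  }
  grid <- as.integer(grid)
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be a non-empty strictly increasing integer vector")
  }
  k <- assert_scalar_count(k, "k")
  q <- assert_scalar_count(q, "q")
  parts <- make_partitions(dataset, P = P, k = k, seed = seed)
  pos <- dataset$positive_class
  neg <- setdiff(unique(dataset$labels), pos)
  y <- factor(dataset$labels, levels = c(neg, pos))
  x <- dataset$values

  mean_err <- vapply(grid, function(nt) {
    errs <- numeric(0)
    for (n in seq_len(k)) {
      train <- parts$train_indices[[n]]
      for (m in seq_len(q)) {
        s <- replicate_seed(seed, backend$backend_id, "ntree_tuning",
                            n, m, backend$deterministic)
        res <- backend$fit_fun(x[train, , drop = FALSE], y[train],
                               x[train[1L], , drop = FALSE], nt, mtry, s)
        errs <- c(errs, as.numeric(res$oob_error))
      }
    }
    mean(errs)
  }, numeric(1))

  ok <- mean_err <= min(mean_err) + plateau_tolerance
  stabilised <- rev(cumprod(rev(ok))) == 1  # ok from here to the end
  selected <- grid[which(stabilised)[1L]]

  structure(list(grid = grid, mean_oob_error = mean_err,
                 selected_ntree = selected,
                 backend_id = backend$backend_id,
                 n_models_per_point = k * q,
                 k = k, q = q, P = P, seed = seed,
                 plateau_tolerance = plateau_tolerance),
            class = "TuningCurve")
}

#' @export
print.TuningCurve <- function(x, ...) {
  cat(sprintf("TuningCurve for '%s': %d grid points, %d models each\n",
              x$backend_id, length(x$grid), x$n_models_per_point))
  cat(sprintf("  selected ntree = %d (plateau tolerance %.4g)\n",
              x$selected_ntree, x$plateau_tolerance))
  invisible(x)
}

#' Write a tuning curve as TSV
#' @param curve a `TuningCurve`.
#' @param file output path.
#' @export
write_tuning_curve <- function(curve, file) {
  utils::write.table(
    data.frame(ntree = curve$grid, mean_oob_error = curve$mean_oob_error),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(curve)
}
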