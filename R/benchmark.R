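#' Construct an AUC grid
#'
#' The S x k x q tensor of validation AUCs plus per-model runtimes for one
#' backend. Usually produced by [run_grid()]; the constructor validates
#' shape and ranges so grids read back from disk obey the same contract.
#'
#' @param auc numeric array of dim `c(S, k, q)`, values in `[0, 1]`.
#' @param runtime_seconds same-shaped non-negative array.
#' @param backend_id backend identifier.
#' @param ntree tree count the models were fitted with.
#' @param signature_ids,partition_ids optional dimension labels.
#' @return an object of class `AUCGrid`.
#' @export
auc_grid <- function(auc, runtime_seconds, backend_id, ntree,
                     signature_ids = NULL, partition_ids = NULL) {
  if (length(dim(auc)) != 3L) stop("`auc` must be a 3-d array (S x k x q)")
  if (!identical(dim(auc), dim(runtime_seconds))) {
    stop("`runtime_seconds` must have the same shape as `auc`")
  }
  if (anyNA(auc) || any(auc < 0 | auc > 1)) {
    stop("AUC values must be in [0, 1] with no holes")
  }
  if (anyNA(runtime_seconds) || any(runtime_seconds < 0)) {
    stop("runtimes must be non-negative with no holes")
  }
  d <- dim(auc)
  signature_ids <- signature_ids %||% sprintf("sig%03d", seq_len(d[1]))
  partition_ids <- partition_ids %||% seq_len(d[2])
  if (length(signature_ids) != d[1]) {
    stop(sprintf("expected %d signature ids, got %d", d[1],
                 length(signature_ids)))
  }
  if (length(partition_ids) != d[2]) {
    stop(sprintf("expected %d partition ids, got %d", d[2],
                 length(partition_ids)))
  }
  dimnames(auc) <- dimnames(runtime_seconds) <-
    list(signature_ids, partition_ids, NULL)
  structure(list(auc = auc, runtime_seconds = runtime_seconds,
                 S = d[1], k = d[2], q = d[3],
                 backend_id = backend_id, ntree = as.integer(ntree),
                 signature_ids = as.character(signature_ids),
                 partition_ids = as.character(partition_ids)),
            class = "AUCGrid")
}

#' @export
print.AUCGrid <- function(x, ...) {
  cat(sprintf("AUCGrid for '%s': S=%d signatures x k=%d partitions x q=%d replicates (%d models, ntree=%d)\n",
              x$backend_id, x$S, x$k, x$q, x$S * x$k * x$q, x$ntree))
  cat(sprintf("  mean AUC %.4f, mean runtime %.4g s\n",
              mean(x$auc), mean(x$runtime_seconds)))
  invisible(x)
}

#' Execute the full signature x partition x replicate model grid
#'
#' Runs one [fit_predict_auc()] call per cell: every signature of the plan,
#' on every partition, `q` independent replicate models. Replicate `m` of
#' cell (signature, partition) uses the seed stream
#' `replicate_seed(seed, backend_id, signature_id, partition, m)`, so
#' replicates differ only by the backend's internal randomisation and the
#' whole tensor is reproducible from `seed`. Any cell failure aborts the
#' run naming the offending cell; partial grids are never returned.
#'
#' @param backend a `ForestBackend` or id string.
#' @param dataset an `ExpressionDataset`.
#' @param plan a `SignaturePlan` over features present in the dataset.
#' @param partitions a `PartitionSet` for the dataset.
#' @param q replicate models per signature/partition cell (>= 2; the
#'   downstream coefficient of variation needs at least two values).
#' @param ntree tree count; defaults to the backend's hyperparameter.
#' @param seed base seed for the replicate streams.
#' @param cell_order optional permutation of cell execution order (used to
#'   verify order independence); the tensor layout is unaffected.
#' @return an `AUCGrid`.
#' @export
run_grid <- function(backend, dataset, plan, partitions, q, ntree = NULL,
                     seed = 1L, cell_order = NULL) {
  if (is.character(backend)) backend <- get_backend(backend)
  stopifnot(inherits(plan, "SignaturePlan"),
            inherits(partitions, "PartitionSet"))
  assert_scalar_count(q, "q", min = 2L)
  if (partitions$n_samples != n_samples(dataset)) {
    stop("`partitions` was built for a dataset of a different size")
  }
  missing <- setdiff(unique(unlist(plan$signatures)), dataset$feature_ids)
  if (length(missing) > 0) {
    stop(sprintf("plan uses features absent from the dataset: %s",
                 paste(missing, collapse = ", ")))
  }
  ntree <- ntree %||% backend$hyperparameters$ntree %||% 500L
  S <- length(plan$signatures)
  k <- partitions$k
  auc <- array(NA_real_, dim = c(S, k, q))
  rt <- array(NA_real_, dim = c(S, k, q))

  cells <- expand.grid(s = seq_len(S), n = seq_len(k), m = seq_len(q))
  order_idx <- cell_order %||% seq_len(nrow(cells))
  for (i in order_idx) {
    s <- cells$s[i]; n <- cells$n[i]; m <- cells$m[i]
    sig_id <- names(plan$signatures)[s]
    cell_seed <- replicate_seed(seed, backend$backend_id, sig_id, n, m,
                                backend$deterministic)
    res <- tryCatch(
      fit_predict_auc(backend, dataset, plan$signatures[[s]],
                      partitions$train_indices[[n]], cell_seed,
                      ntree = ntree),
      error = function(e) {
        stop(sprintf("grid cell (signature %s, partition %d, replicate %d) failed: %s",
                     sig_id, n, m, conditionMessage(e)), call. = FALSE)
      })
    auc[s, n, m] <- res$auc
    rt[s, n, m] <- res$runtime_seconds
  }
  auc_grid(auc, rt, backend$backend_id, ntree,
           signature_ids = names(plan$signatures))
}

#' Mean AUC and mean runtime of a grid
#'
#' Arithmetic means over all `S * k * q` cells; the two headline
#' performance numbers reported next to the stability scores.
#'
#' @param grid an `AUCGrid`.
#' @return list with `mean_auc` and `mean_runtime_seconds`.
#' @export
summarize_grid <- function(grid) {
  stopifnot(inherits(grid, "AUCGrid"))
  list(mean_auc = mean(grid$auc),
       mean_runtime_seconds = mean(grid$runtime_seconds))
}

#' Persist / restore an AUC grid as flat TSV
#'
#' One row per model: backend_id, signature_id, partition, replicate, auc,
#' runtime_seconds. Scoring can then be re-run at any stability threshold
#' without re-fitting a single model.
#'
#' @param grid an `AUCGrid`.
#' @param file path to the TSV.
#' @return `read_auc_grid()` returns an `AUCGrid`.
#' @export
write_auc_grid <- function(grid, file) {
  cells <- expand.grid(s = seq_len(grid$S), n = seq_len(grid$k),
                       m = seq_len(grid$q))
  df <- data.frame(backend_id = grid$backend_id,
                   signature_id = grid$signature_ids[cells$s],
                   partition = cells$n, replicate = cells$m,
                   auc = grid$auc[as.matrix(cells)],
                   runtime_seconds = grid$runtime_seconds[as.matrix(cells)])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("#ntree=%d", grid$ntree), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(grid)
}

#' @rdname write_auc_grid
#' @export
read_auc_grid <- function(file) {
  lines <- readLines(file)
  ntree <- 500L
  hdr <- grep("^#ntree=", lines)
  if (length(hdr) > 0) ntree <- as.integer(sub("^#ntree=", "", lines[hdr[1]]))
  body <- lines[!startsWith(lines, "#")]
  df <- tryCatch(
    utils::read.table(text = body, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("malformed grid file '%s': %s", file,
                                     conditionMessage(e)), call. = FALSE))
  required <- c("backend_id", "signature_id", "partition", "replicate",
                "auc", "runtime_seconds")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(sprintf("grid file '%s' lacks columns: %s", file,
                 paste(miss, collapse = ", ")))
  }
  sig_ids <- unique(df$signature_id)
  part_ids <- sort(unique(df$partition))
  reps <- sort(unique(df$replicate))
  S <- length(sig_ids); k <- length(part_ids); q <- length(reps)
  if (nrow(df) != S * k * q) {
    stop(sprintf("grid file '%s' is incomplete: %d rows, expected %d (S=%d, k=%d, q=%d)",
                 file, nrow(df), S * k * q, S, k, q))
  }
  auc <- array(NA_real_, dim = c(S, k, q))
  rt <- array(NA_real_, dim = c(S, k, q))
  idx <- cbind(match(df$signature_id, sig_ids),
               match(df$partition, part_ids),
               match(df$replicate, reps))
  if (anyDuplicated(idx)) {
    stop(sprintf("grid file '%s' contains duplicate cells", file))
  }
  auc[idx] <- df$auc
  rt[idx] <- df$runtime_seconds
  auc_grid(auc, rt, df$backend_id[1L], ntree,
           signature_ids = sig_ids, partition_ids = part_ids)
}
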